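# Univariable family-clustered association models: random-intercept linear
# models for the deviance-residual outcomes and a random-effects probit for
# the binary AUD-resistance outcome.  Each predictor enters its own model to
# avoid multicollinearity; continuous predictors and outcomes are
# standardized so coefficients are on the reported effect-size scale, while
# binary predictors stay on the 0/1 scale.

is_binaryish <- function(x) length(unique(stats::na.omit(x))) <= 2L

std01 <- function(x) (x - mean(x)) / stats::sd(x)

#' Family random-intercept linear model for a single predictor
#'
#' ML fit of `outcome ~ predictor + (1 | family)`.  The outcome is
#' standardized; the predictor is standardized unless binary (left 0/1).
#' When the between-family variance collapses to zero the fit coincides with
#' OLS and a note is recorded.
#'
#' @param outcome numeric outcome (deviance residuals).
#' @param predictor numeric predictor.
#' @param family_id cluster identifier.
#' @param predictor_name label for reporting.
#' @param alpha two-sided significance level for the Wald CI.
#' @return object of class `assoc_result`: `beta_std`, `se`, `ci95`,
#'   `n_used`, `significant`, `note`.
#' @export
fit_family_lm <- function(outcome, predictor, family_id,
                          predictor_name = deparse(substitute(predictor)),
                          alpha = 0.05) {
  ok <- stats::complete.cases(outcome, predictor, family_id)
  y <- outcome[ok]; x <- predictor[ok]; f <- factor(family_id[ok])
  if (length(unique(f)) < 2L) stop("need at least 2 families")
  if (stats::sd(y) <= 0) stop("outcome has zero variance")
  y <- std01(y)
  if (!is_binaryish(x)) x <- std01(x)
  d <- data.frame(y = y, x = x, f = f)
  fit <- suppressMessages(lme4::lmer(y ~ x + (1 | f), data = d, REML = FALSE))
  note <- NULL
  if (lme4::isSingular(fit, tol = 1e-5))
    note <- "between-family variance estimated at 0; equivalent to OLS"
  beta <- lme4::fixef(fit)[["x"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2L]
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(beta - z * se, beta + z * se)
  structure(list(
    predictor_name = predictor_name, outcome = "deviance_residual",
    beta_std = unname(beta), se = unname(se), ci95 = unname(ci),
    n_used = length(y), significant = ci[1] > 0 || ci[2] < 0,
    note = note, model = fit
  ), class = "assoc_result")
}

# Gauss-Hermite nodes/weights for integrals against the standard normal
# density (Golub-Welsch on the Hermite Jacobi matrix)
gauss_hermite_normal <- function(n) {
  if (n == 1L) return(list(x = 0, w = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = sqrt(2) * e$values, w = e$vectors[1L, ]^2)
}

re_probit_loglik <- function(theta, y, Xmat, fam_idx, gh) {
  k <- ncol(Xmat)
  beta <- theta[seq_len(k)]
  sigma <- exp(theta[k + 1L])
  eta <- drop(Xmat %*% beta)
  q <- 2 * y - 1
  # per family: log sum_k w_k exp( sum_i log Phi(q_i * (eta_i + sigma u_k)) )
  lp <- vapply(seq_along(gh$x), function(j)
    stats::pnorm(q * (eta + sigma * gh$x[j]), log.p = TRUE), numeric(length(y)))
  fam_ll <- rowsum(lp, fam_idx)              # families x nodes
  m <- apply(fam_ll, 1L, max)
  sum(m + log(drop(exp(sweep(fam_ll, 1L, m)) %*% gh$w)))
}

#' Family random-intercept probit model
#'
#' ML probit with a Gaussian family random intercept, the likelihood
#' integrated by Gauss-Hermite quadrature.  Coefficients are on the latent
#' probit z scale.  The focal predictor is standardized unless binary; any
#' covariates enter as supplied.
#'
#' @param outcome 0/1 outcome (both classes required).
#' @param predictor focal predictor.
#' @param covariates optional data.frame/matrix of adjustment covariates.
#' @param family_id cluster identifier.
#' @param predictor_name label for reporting.
#' @param nodes number of quadrature nodes (default 15).
#' @param re_sd `NULL` to estimate the random-effect SD, or a fixed
#'   non-negative value (0 gives the ordinary probit MLE).
#' @param alpha two-sided significance level.
#' @return object of class `assoc_result` with additionally `re_sd`,
#'   `loglik`, `coefficients`.
#' @export
fit_family_probit <- function(outcome, predictor, covariates = NULL,
                              family_id,
                              predictor_name = deparse(substitute(predictor)),
                              nodes = 15L, re_sd = NULL, alpha = 0.05) {
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- stats::complete.cases(outcome, predictor, family_id)
  if (!is.null(cov_df)) ok <- ok & stats::complete.cases(cov_df)
  y <- as.integer(outcome[ok]); x <- predictor[ok]
  f <- factor(family_id[ok])
  if (length(unique(y)) < 2L) stop("outcome does not have both classes")
  if (!is_binaryish(x)) x <- std01(x)
  # complete-separation check on the focal predictor
  if (min(x[y == 1]) > max(x[y == 0]) || max(x[y == 1]) < min(x[y == 0]))
    stop("complete separation on predictor '", predictor_name, "'")
  Xmat <- cbind(`(Intercept)` = 1, predictor = x)
  if (!is.null(cov_df)) {
    Xc <- as.matrix(cov_df[ok, , drop = FALSE])
    keep <- apply(Xc, 2L, function(v) stats::sd(v) > 1e-12)
    Xmat <- cbind(Xmat, Xc[, keep, drop = FALSE])
  }
  gh <- gauss_hermite_normal(nodes)
  fam_idx <- as.integer(f)
  glm0 <- suppressWarnings(stats::glm.fit(Xmat, y,
                                          family = stats::binomial("probit")))
  estimate_re <- is.null(re_sd)
  if (estimate_re) {
    nll <- function(th) {
      v <- -re_probit_loglik(th, y, Xmat, fam_idx, gh)
      if (!is.finite(v)) 1e10 else v
    }
    start <- c(glm0$coefficients, log(0.5))
    opt <- stats::nlminb(start, nll, control = list(iter.max = 500L))
    if (opt$convergence != 0 && opt$objective >= 1e10)
      stop("random-effects probit failed to converge: ", opt$message)
    theta <- opt$par
    ll <- -opt$objective
    H <- stats::optimHess(theta, nll)
    V <- tryCatch(solve(H), error = function(e)
      stop("random-effects probit information matrix is singular ",
           "(possible non-convergence)"))
    k <- ncol(Xmat)
    beta <- theta[seq_len(k)]
    se <- sqrt(pmax(diag(V)[seq_len(k)], 0))
    sigma <- exp(theta[k + 1L])
  } else {
    # fixed random-effect SD (0 reduces to the ordinary probit MLE)
    k <- ncol(Xmat)
    nll <- function(b) {
      v <- -re_probit_loglik(c(b, log(max(re_sd, 1e-12))), y, Xmat, fam_idx, gh)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- stats::nlminb(glm0$coefficients, nll, control = list(iter.max = 500L))
    beta <- opt$par
    ll <- -opt$objective
    H <- stats::optimHess(beta, nll)
    se <- sqrt(pmax(diag(solve(H)), 0))
    sigma <- re_sd
  }
  names(beta) <- names(se) <- colnames(Xmat)
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(beta[["predictor"]] - z * se[["predictor"]],
          beta[["predictor"]] + z * se[["predictor"]])
  structure(list(
    predictor_name = predictor_name, outcome = "aud_resistance",
    beta_std = beta[["predictor"]], se = se[["predictor"]], ci95 = ci,
    n_used = length(y), significant = ci[1] > 0 || ci[2] < 0,
    re_sd = sigma, loglik = ll, coefficients = beta, coef_se = se,
    nodes = nodes, note = NULL
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s -> %s: beta = %.3f [%.3f, %.3f]%s (n = %d)\n",
              x$predictor_name, x$outcome, x$beta_std, x$ci95[1], x$ci95[2],
              if (x$significant) " *" else "", x$n_used))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Run the full univariable association table
#'
#' One model per predictor x outcome: linear random-intercept models for the
#' initiation and heavy-episodic-drinking deviance residuals, random-effects
#' probit (with covariates) for the AUD-resistance code.
#'
#' @param analysis data.frame with predictors (`fc_rq`, `mc_rq`,
#'   `monitoring`, `peer`, `partner`, `soccomp`), outcomes
#'   (`res_initiation`, `res_hed`, `aud_resistance`), `family_id` and the
#'   probit covariates (`baseline_age`, `sex`, `ancestry_num`,
#'   `has_mother_data`, `has_father_data`).
#' @param predictors character vector of predictor columns.
#' @param nodes quadrature nodes for the probit models.
#' @return data.frame mirroring the univariable table: predictor x outcome
#'   with `beta`, `ci_lower`, `ci_upper`, `n`, `significant`.
#' @export
run_univariable <- function(analysis,
                            predictors = c("fc_rq", "mc_rq", "monitoring",
                                           "peer", "partner", "soccomp"),
                            nodes = 15L) {
  out <- list()
  probit_cov <- analysis[c("baseline_age", "sex", "ancestry_num",
                           "has_mother_data", "has_father_data")]
  for (p in predictors) {
    for (oc in c("res_initiation", "res_hed", "aud_resistance")) {
      r <- tryCatch({
        if (oc == "aud_resistance") {
          fit_family_probit(analysis[[oc]], analysis[[p]],
                            covariates = probit_cov,
                            family_id = analysis$family_id,
                            predictor_name = p, nodes = nodes)
        } else {
          fit_family_lm(analysis[[oc]], analysis[[p]],
                        family_id = analysis$family_id, predictor_name = p)
        }
      }, error = function(e) e)
      out[[length(out) + 1L]] <- if (inherits(r, "error")) {
        data.frame(predictor = p, outcome = oc, beta = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_, n = 0L,
                   significant = NA, note = conditionMessage(r))
      } else {
        data.frame(predictor = p, outcome = oc, beta = r$beta_std,
                   ci_lower = r$ci95[1], ci_upper = r$ci95[2], n = r$n_used,
                   significant = r$significant,
                   note = if (is.null(r$note)) "" else r$note)
      }
    }
  }
  do.call(rbind, out)
}
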
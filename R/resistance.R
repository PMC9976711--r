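# Realized-resistance phenotypes: deviance residuals from family-clustered
# Cox proportional-hazards models of alcohol-initiation and
# heavy-episodic-drinking onset, and the rule-based AUD-resistance code.
#
# Sign convention (fixed): positive deviance residual = onset sooner than
# expected given genetic risk = LOWER resistance.

#' Fit a family-clustered Cox proportional-hazards model
#'
#' `cluster_mode = "gamma_frailty"` adds a family-shared gamma frailty via
#' the penalized partial likelihood; `"robust"` fits an ordinary Cox model
#' with a family-clustered sandwich variance.  Ties are handled with the
#' Breslow approximation (`ties = "efron"` optional), and the baseline
#' cumulative hazard is the Breslow estimator evaluated on the uncentered
#' linear predictor (including the estimated log-frailty in frailty mode).
#'
#' @param time positive event/censoring times (years).
#' @param event 0/1 event indicator (at least one event required).
#' @param X covariate matrix or data.frame; constant columns are dropped
#'   with a note.
#' @param family_id cluster identifier.
#' @param cluster_mode `"gamma_frailty"` or `"robust"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `cox_fit`: `beta`, `se`, `hr_ci` (HR with 95% CI),
#'   `frailty_variance`, `log_frailty` (per family), `baseline_cumhaz`
#'   (step function as a data.frame), `eta`, `loglik`, `martingale`,
#'   `deviance`, `dropped` (constant columns).
#' @export
fit_clustered_cox <- function(time, event, X, family_id,
                              cluster_mode = c("gamma_frailty", "robust"),
                              ties = c("breslow", "efron")) {
  cluster_mode <- match.arg(cluster_mode)
  ties <- match.arg(ties)
  if (any(time <= 0)) stop("all times must be positive")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events: cannot fit a Cox model")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  keep <- apply(X, 2L, function(v) stats::sd(v) > 1e-12)
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) stop("no non-constant covariates remain")
  qr_rank <- qr(cbind(1, X))$rank
  if (qr_rank < ncol(X) + 1L) stop("covariate matrix is rank deficient")
  fam <- as.factor(family_id)
  dat <- data.frame(time = time, event = event, fam = fam)
  dat <- cbind(dat, as.data.frame(X))
  xnames <- colnames(X)
  rhs <- paste(xnames, collapse = " + ")
  if (cluster_mode == "gamma_frailty") {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs,
                                   "+ survival::frailty(fam, distribution = 'gamma')"))
    fit <- survival::coxph(fml, data = dat, ties = ties)
    beta <- fit$coefficients[xnames]
    se <- sqrt(diag(as.matrix(fit$var))[seq_along(xnames)])
    theta <- fit$history[[1]]$theta
    logfrail <- fit$frail
    names(logfrail) <- levels(fam)
  } else {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
    fit <- survival::coxph(fml, data = dat, ties = ties, cluster = fam,
                           robust = TRUE)
    beta <- fit$coefficients[xnames]
    se <- sqrt(diag(as.matrix(fit$var)))
    theta <- 0
    logfrail <- stats::setNames(rep(0, nlevels(fam)), levels(fam))
  }
  eta <- drop(X %*% beta) + logfrail[as.character(fam)]
  base <- breslow_cumhaz(time, event, eta)
  hr_ci <- data.frame(
    term = xnames, hr = exp(beta),
    lower = exp(beta - 1.959964 * se), upper = exp(beta + 1.959964 * se),
    row.names = NULL)
  out <- structure(list(
    beta = beta, se = se, hr_ci = hr_ci, cluster_mode = cluster_mode,
    ties = ties, frailty_variance = theta, log_frailty = logfrail,
    baseline_cumhaz = base, eta = unname(eta), time = time, event = event,
    family = fam, loglik = fit$loglik, dropped = dropped, coxph = fit
  ), class = "cox_fit")
  res <- cox_residuals(out)
  out$martingale <- res$martingale
  out$deviance <- res$deviance
  out
}

# Breslow estimator of the baseline cumulative hazard on the raw linear
# predictor scale: Lambda0(t) = sum_{event times s <= t} d_s / sum_{i at
# risk at s} exp(eta_i)
breslow_cumhaz <- function(time, event, eta) {
  et <- sort(unique(time[event == 1L]))
  r <- exp(eta)
  denom <- vapply(et, function(s) sum(r[time >= s]), numeric(1))
  d <- vapply(et, function(s) sum(event[time == s]), numeric(1))
  data.frame(time = et, hazard = d / denom, cumhaz = cumsum(d / denom))
}

eval_cumhaz <- function(base, t) {
  idx <- findInterval(t, base$time)
  c(0, base$cumhaz)[idx + 1L]
}

#' Martingale and deviance residuals of a clustered Cox fit
#'
#' `M_i = delta_i - Lambda0(t_i) * exp(eta_i)` and
#' `D_i = sign(M_i) * sqrt(-2 * (M_i + delta_i * log(delta_i - M_i)))`,
#' with the log term vanishing for censored subjects.  In frailty mode the
#' linear predictor includes the estimated log-frailty by default
#' (`conditional = FALSE` sets the frailty to 1).
#'
#' Positive deviance = the event occurred sooner than the model expected =
#' lower resistance; right-censored subjects always have `D <= 0`.
#'
#' @param fit a [fit_clustered_cox()] result.
#' @param conditional include the estimated log-frailty in the linear
#'   predictor (default `TRUE`).
#' @return list with `martingale` and `deviance` vectors.
#' @export
cox_residuals <- function(fit, conditional = TRUE) {
  eta <- fit$eta
  base <- fit$baseline_cumhaz
  if (!conditional && fit$cluster_mode == "gamma_frailty") {
    eta <- eta - fit$log_frailty[as.character(fit$family)]
    base <- breslow_cumhaz(fit$time, fit$event, eta)
  }
  expected <- eval_cumhaz(base, fit$time) * exp(eta)
  M <- fit$event - expected
  if (any(fit$event - M < -1e-12))
    stop("martingale residual exceeds the event indicator; numerically impossible")
  logterm <- ifelse(fit$event == 1L, log(pmax(fit$event - M, .Machine$double.xmin)), 0)
  D <- sign(M) * sqrt(pmax(-2 * (M + fit$event * logterm), 0))
  list(martingale = unname(M), deviance = unname(D))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Family-clustered Cox model (", x$cluster_mode, ", ties = ", x$ties,
      "): ", sum(x$event), " events / ", length(x$event), " subjects\n", sep = "")
  if (x$cluster_mode == "gamma_frailty")
    cat(sprintf("  gamma frailty variance: %.4f\n", x$frailty_variance))
  print(transform(x$hr_ci, hr = round(hr, 3), lower = round(lower, 3),
                  upper = round(upper, 3)))
  invisible(x)
}

#' Code AUD resistance
#'
#' Affected (0): diagnosed with AUD at age 15 or older.  Resistant (1):
#' drinkers assessed through age 23 who never met criteria.  Everyone else
#' (non-drinkers, or drinkers not followed through 23 without a diagnosis) is
#' missing.
#'
#' @param subjects data.frame with `aud_diagnosed`, `drinker` and
#'   `last_assessment_age` (and `subject_id`).
#' @return data.frame: `subject_id`, `aud_resistance` in {0, 1, NA}.
#' @export
code_aud_resistance <- function(subjects) {
  code <- rep(NA_integer_, nrow(subjects))
  affected <- subjects$aud_diagnosed == 1L & subjects$last_assessment_age >= 15
  resistant <- subjects$drinker == 1L & subjects$aud_diagnosed == 0L &
    subjects$last_assessment_age >= 23
  code[affected] <- 0L
  code[resistant & !affected] <- 1L
  data.frame(subject_id = subjects$subject_id, aud_resistance = code,
             stringsAsFactors = FALSE)
}

#' Build the three analysis subsamples
#'
#' Initiation: subjects not yet initiated at baseline.  Heavy episodic
#' drinking: subjects without heavy episodic drinking at baseline.  AUD:
#' high-genetic-risk subjects with a non-missing AUD-resistance code.
#'
#' @param subjects subject data.frame with `baseline_initiated` and
#'   `baseline_hed`.
#' @param high_risk logical vector aligned with `subjects`.
#' @param aud_code integer vector (0/1/NA) aligned with `subjects`.
#' @return list of integer row indices: `initiation`, `hed`, `aud`.
#' @export
build_analysis_subsamples <- function(subjects, high_risk, aud_code) {
  list(
    initiation = which(subjects$baseline_initiated == 0L),
    hed = which(subjects$baseline_hed == 0L),
    aud = which(high_risk & !is.na(aud_code))
  )
}

#' Derive the resistance phenotypes for a cohort
#'
#' Fits the two family-clustered Cox models (initiation and heavy episodic
#' drinking) with family history density and the standardized polygenic
#' score as predictors and baseline age, sex, nuisance covariates and
#' parental-data indicators as covariates, separately within each ancestry
#' group; pools the deviance residuals; and applies the AUD-resistance code.
#'
#' @param subjects subject data.frame.
#' @param genrisk output of [compute_genetic_risk()] aligned by subject_id.
#' @param cluster_mode,ties passed to [fit_clustered_cox()].
#' @param conditional passed to [cox_residuals()].
#' @param stratify_by_ancestry fit models separately per ancestry group
#'   (default) and pool residuals.
#' @return list: `resistance` (long data.frame subject_id x phenotype x
#'   value), `fits` (per ancestry x process `cox_fit`), `subsamples`.
#' @export
derive_resistance <- function(subjects, genrisk,
                              cluster_mode = "gamma_frailty",
                              ties = "breslow", conditional = TRUE,
                              stratify_by_ancestry = TRUE) {
  stopifnot(identical(subjects$subject_id, genrisk$subject_id))
  aud <- code_aud_resistance(subjects)
  sub <- build_analysis_subsamples(subjects, genrisk$high_risk,
                                   aud$aud_resistance)
  covnames <- c("fhd", "prs_z", "baseline_age", "sex",
                grep("^pc[0-9]+$", names(subjects), value = TRUE),
                "has_mother_data", "has_father_data")
  dat <- cbind(subjects, genrisk[c("fhd", "prs_z")])
  fits <- list()
  res_rows <- list()
  for (process in c("initiation", "hed")) {
    idx <- sub[[process]]
    d <- dat[idx, , drop = FALSE]
    tcol <- paste0("time_", process)
    ecol <- paste0("event_", process)
    groups <- if (stratify_by_ancestry) unique(d$ancestry_group) else "pooled"
    for (g in groups) {
      gi <- if (stratify_by_ancestry) d$ancestry_group == g else rep(TRUE, nrow(d))
      dg <- d[gi, , drop = FALSE]
      ok <- stats::complete.cases(dg[c(tcol, ecol, covnames)])
      dg <- dg[ok, , drop = FALSE]
      fit <- fit_clustered_cox(dg[[tcol]], dg[[ecol]],
                               as.matrix(dg[covnames]), dg$family_id,
                               cluster_mode = cluster_mode, ties = ties)
      res <- cox_residuals(fit, conditional = conditional)
      fits[[paste(process, g, sep = ".")]] <- fit
      res_rows[[paste(process, g, sep = ".")]] <- data.frame(
        subject_id = dg$subject_id, phenotype = process,
        value = res$deviance, stringsAsFactors = FALSE)
    }
  }
  res_rows$aud <- data.frame(
    subject_id = subjects$subject_id[sub$aud], phenotype = "aud",
    value = as.numeric(aud$aud_resistance[sub$aud]), stringsAsFactors = FALSE)
  list(resistance = do.call(rbind, c(res_rows, list(make.row.names = FALSE))),
       fits = fits, subsamples = sub, aud_code = aud)
}
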
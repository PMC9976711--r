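# One-factor confirmatory factor analysis for the parent-child
# relationship-quality constructs, built on the FIML SEM engine.

#' Fit a one-factor confirmatory factor model
#'
#' Maximum-likelihood one-factor model with the factor variance fixed to 1
#' (standardized loadings reported directly).  Estimation is casewise FIML,
#' so partially observed indicator vectors contribute their observed
#' coordinates.  Chi-square is measured against the saturated Gaussian fit;
#' CFI against the independence baseline; SRMR is the root-mean-square
#' standardized covariance residual.  Factor scores use the regression
#' method, applied to each case's observed indicators via the
#' conditional-normal formula.
#'
#' @param indicators data.frame or matrix of indicator columns (>= 3; the
#'   parent-quality models use 4).
#' @param ... passed to [fit_sem()].
#' @return object of class `cfa_fit` with standardized `loadings`,
#'   `residual_variances`, `chi_square`, `df`, `cfi`, `srmr`,
#'   `factor_scores`, `determinacy`, `heywood` flag and the underlying
#'   `sem_fit`.
#' @export
fit_one_factor_cfa <- function(indicators, ...) {
  indicators <- as.data.frame(indicators)
  p <- ncol(indicators)
  if (p < 3L) stop("a one-factor model needs at least 3 indicators")
  vn <- colnames(indicators)
  syntax <- paste("rq =~", paste(vn, collapse = " + "))
  fit <- fit_sem(sem_model(syntax, indicators), ...)
  est <- fit$estimates
  lam_raw <- est$est[est$role == "loading"]
  theta <- est$est[est$role == "variance"]
  names(lam_raw) <- names(theta) <- vn
  im <- fit$implied[[1]]
  sdv <- sqrt(diag(im$Sigma))
  std <- standardized_solution(fit)
  lam_std <- std$std[std$role == "loading"]
  lam_ci <- std[std$role == "loading", c("std_ci_lower", "std_ci_upper")]
  names(lam_std) <- vn

  # regression-method factor scores: cov(f, x) = lambda (phi = 1)
  Y <- as.matrix(indicators)
  scores <- rep(NA_real_, nrow(Y))
  key <- apply(!is.na(Y), 1L, paste, collapse = "")
  for (idx in split(seq_len(nrow(Y)), key)) {
    o <- which(!is.na(Y[idx[1], ]))
    if (length(o) == 0L) next
    w <- solve(im$Sigma[o, o, drop = FALSE], lam_raw[o])
    scores[idx] <- sweep(Y[idx, o, drop = FALSE], 2L, im$mu[o]) %*% w
  }
  determinacy <- sqrt(drop(t(lam_raw) %*% solve(im$Sigma, lam_raw)))

  structure(list(
    loadings = lam_std, loadings_raw = lam_raw, loadings_ci = lam_ci,
    residual_variances = theta,
    chi_square = fit$chi_square, df = fit$df, cfi = fit$cfi, srmr = fit$srmr,
    p_value = stats::pchisq(fit$chi_square, fit$df, lower.tail = FALSE),
    factor_scores = scores, determinacy = determinacy,
    heywood = fit$heywood, fit = fit, n = fit$n_per_group[[1]]
  ), class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("One-factor CFA (n = %d): chi-square(%d) = %.2f, CFI = %.3f, SRMR = %.3f\n",
              x$n, x$df, x$chi_square, x$cfi, x$srmr))
  cat("standardized loadings:\n")
  print(round(x$loadings, 3))
  if (x$heywood) cat("WARNING: Heywood case (negative residual variance)\n")
  invisible(x)
}

#' Fit both parent relationship-quality measurement models
#'
#' One-factor CFAs of bonding, closeness, communication and involvement for
#' the father and the mother, returning factor scores merged with the scale
#' scores.
#'
#' @param scores output of [score_subjects()].
#' @param ... passed to [fit_one_factor_cfa()].
#' @return list with `father` and `mother` (`cfa_fit`) and `scores` (the
#'   input with `fc_rq` and `mc_rq` factor-score columns added).
#' @export
fit_parent_cfas <- function(scores, ...) {
  fa <- fit_one_factor_cfa(scores[c("fc_bond", "fc_close", "fc_comm", "fc_inv")], ...)
  mo <- fit_one_factor_cfa(scores[c("mc_bond", "mc_close", "mc_comm", "mc_inv")], ...)
  scores$fc_rq <- fa$factor_scores
  scores$mc_rq <- mo$factor_scores
  list(father = fa, mother = mo, scores = scores)
}
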
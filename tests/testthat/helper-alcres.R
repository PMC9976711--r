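# shared fixtures: small seeded cohorts and oracle helpers

small_cfg <- function(n_families = 200L, seed = 42L, ...) {
  sim_config(n_families = n_families, seed = seed, ...)
}

# negative log Breslow partial likelihood written out directly from its
# definition; independent oracle for the Cox fitter
neg_log_partial_lik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (j in which(event == 1L)) {
    risk <- time >= time[j]
    ll <- ll + eta[j] - log(sum(exp(eta[risk])))
  }
  -ll
}

# hand-rolled Breslow baseline cumulative hazard evaluated at each time
breslow_by_hand <- function(time, event, eta) {
  vapply(time, function(t) {
    s <- 0
    for (u in sort(unique(time[event == 1L & time <= t]))) {
      d <- sum(event[time == u])
      s <- s + d / sum(exp(eta[time >= u]))
    }
    s
  }, numeric(1))
}

# complete-data Gaussian log-likelihood from explicit per-case densities
gaussian_loglik_by_hand <- function(Y, mu, Sigma) {
  p <- ncol(Y)
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  s <- 0
  for (i in seq_len(nrow(Y))) {
    d <- as.numeric(Y[i, ]) - mu
    s <- s - 0.5 * (p * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }
  as.numeric(s)
}
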
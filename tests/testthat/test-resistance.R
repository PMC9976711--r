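# Cox fitting, residual formulas, AUD coding and subsample construction

test_that("Cox beta matches a brute-force maximizer of the partial likelihood", {
  # fabricated 6-subject data (exposure interleaved so the MLE is finite)
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  oracle <- optimize(neg_log_partial_lik, c(-5, 5), time = time,
                     event = event, x = x, tol = 1e-10)$minimum
  fit <- fit_clustered_cox(time, event, cbind(x = x), family_id = 1:6,
                           cluster_mode = "robust")
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-6)
})

test_that("martingale and deviance residuals match their closed forms", {
  # hand-made fit object exercises the residual formulas directly
  base <- data.frame(time = c(2, 4), hazard = c(0.5, 0.5), cumhaz = c(0.5, 1))
  fake <- structure(list(
    eta = rep(0, 4), baseline_cumhaz = base,
    time = c(1, 2, 4, 4), event = c(0L, 0L, 1L, 0L),
    cluster_mode = "robust", family = factor(1:4),
    log_frailty = setNames(rep(0, 4), 1:4)), class = "cox_fit")
  r <- cox_residuals(fake)
  # censored before any event time: expected hazard 0 -> M = 0, D = 0
  expect_equal(r$martingale[1], 0)
  expect_equal(r$deviance[1], 0)
  # censored with cumulative hazard 0.5 -> M = -0.5, D = -1.0
  expect_equal(r$martingale[2], -0.5)
  expect_equal(r$deviance[2], -1.0)
  # event exactly as expected (cumhaz 1) -> M = 0, D = 0
  expect_equal(r$martingale[3], 0)
  expect_equal(r$deviance[3], 0)
  # censored at cumhaz 1 -> M = -1, D = -sqrt(2)
  expect_equal(r$deviance[4], -sqrt(2))
})

test_that("fitted residuals agree with hand-rolled Breslow evaluation and survival", {
  set.seed(10)
  n <- 120
  fam <- rep(1:40, each = 3)
  x <- rnorm(n)
  t0 <- rexp(n, exp(0.5 * x))
  cens <- runif(n, 0.3, 2.5)
  time <- pmin(t0, cens); event <- as.integer(t0 <= cens)
  fit <- fit_clustered_cox(time, event, cbind(x = x), fam,
                           cluster_mode = "robust")
  eta <- fit$beta[["x"]] * x
  Lam <- breslow_by_hand(time, event, eta)
  M_hand <- event - Lam * exp(eta)
  expect_equal(fit$martingale, M_hand, tolerance = 1e-6)
  D_hand <- sign(M_hand) * sqrt(-2 * (M_hand + event * log(event - M_hand)))
  D_hand[event == 0L] <- sign(M_hand[event == 0L]) *
    sqrt(-2 * M_hand[event == 0L])
  expect_equal(fit$deviance, D_hand, tolerance = 1e-6)

  # independent oracle: survival's own residuals for the same model
  sv <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  expect_equal(fit$martingale, unname(residuals(sv, type = "martingale")),
               tolerance = 1e-5)

  # score equation: martingale residuals sum to ~0 at the MLE
  expect_lt(abs(sum(fit$martingale)), 1e-6 * n)
  # censored subjects always have non-positive deviance; signs agree
  expect_true(all(fit$deviance[event == 0L] <= 0))
  expect_true(all(sign(fit$deviance) == sign(fit$martingale) |
                    fit$martingale == 0))
})

test_that("degenerate inputs are rejected or dropped as specified", {
  time <- 1:6; event <- c(1, 1, 0, 1, 0, 0); x <- c(1, 0, 1, 0, 1, 0)
  expect_error(fit_clustered_cox(c(0, 2:6), event, cbind(x = x), 1:6),
               "positive")
  expect_error(fit_clustered_cox(time, rep(0L, 6), cbind(x = x), 1:6),
               "no events")
  expect_message(
    fit <- fit_clustered_cox(time, event, cbind(x = x, z = rep(0, 6)), 1:6,
                             cluster_mode = "robust"),
    "constant covariate")
  expect_identical(fit$dropped, "z")
  expect_false("z" %in% names(fit$beta))
})

test_that("frailty and robust modes agree closely when frailty is weak", {
  cfg <- small_cfg(n_families = 400L, seed = 53L, h2_liability = 0.2,
                   log_hr = list(initiation = c(true_liability = 0.3),
                                 hed = numeric(0)))
  s <- simulate_onsets(generate_families(cfg)$subjects, cfg)
  X <- cbind(prs = s$prs, age = s$baseline_age, sex = s$sex)
  f1 <- fit_clustered_cox(s$time_initiation, s$event_initiation, X,
                          s$family_id, cluster_mode = "gamma_frailty")
  f2 <- fit_clustered_cox(s$time_initiation, s$event_initiation, X,
                          s$family_id, cluster_mode = "robust")
  expect_gte(f1$frailty_variance, 0)
  expect_gt(cor(f1$deviance, f2$deviance), 0.9)
})

test_that("deviance residuals capture environmentally early onset (sign convention)", {
  # null genetics: hazard driven only by a family environmental frailty;
  # positive D must track the environmental log-frailty (sooner than expected
  # given genetic covariates = lower resistance)
  set.seed(11)
  nf <- 700; size <- 3; n <- nf * size
  fam <- rep(seq_len(nf), each = size)
  logfr <- rep(rnorm(nf, 0, 0.7), each = size)
  prs <- rnorm(n)                       # unrelated to hazard
  t0 <- (-log(runif(n)) / exp(logfr))^(1 / 2) * 18
  cens <- runif(n, 15, 26)
  time <- pmin(t0, cens); event <- as.integer(t0 <= cens)
  fit <- fit_clustered_cox(time, event, cbind(prs = prs), fam,
                           cluster_mode = "robust")
  sl <- summary(lm(fit$deviance ~ logfr))$coefficients["logfr", ]
  expect_gt(sl["Estimate"], 0)
  expect_lt(sl["Pr(>|t|)"], 0.01)
})

test_that("AUD resistance coding implements the age-15/age-23 rule", {
  subjects <- data.frame(
    subject_id = paste0("S", 1:6),
    aud_diagnosed    = c(1L, 0L, 0L, 0L, 1L, 0L),
    drinker          = c(1L, 1L, 1L, 0L, 1L, 1L),
    last_assessment_age = c(16, 24, 21, 25, 14.5, 23))
  code <- code_aud_resistance(subjects)$aud_resistance
  expect_identical(code[1], 0L)        # diagnosed at >= 15 -> affected
  expect_identical(code[2], 1L)        # drinker through 23, never diagnosed
  expect_true(is.na(code[3]))          # not assessed through 23 -> missing
  expect_true(is.na(code[4]))          # non-drinker -> missing
  expect_true(is.na(code[5]))          # diagnosed before 15 only -> missing
  expect_identical(code[6], 1L)        # assessed exactly through 23
})

test_that("subsample filters reproduce a hand count on a 10-row toy panel", {
  toy <- data.frame(
    subject_id = paste0("S", 1:10),
    baseline_initiated = c(0, 1, 0, 0, 1, 0, 0, 0, 1, 0),
    baseline_hed       = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0))
  high_risk <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  aud_code  <- c(1L, 0L, 1L, NA, 1L, NA, 0L, 1L, 0L, 1L)
  sub <- build_analysis_subsamples(toy, high_risk, aud_code)
  expect_identical(sub$initiation, which(toy$baseline_initiated == 0))  # 7 rows
  expect_length(sub$initiation, 7L)
  expect_length(sub$hed, 8L)
  # AUD subsample: high risk AND coded: subjects 1,2,5,8,9
  expect_identical(sub$aud, c(1L, 2L, 5L, 8L, 9L))
})

test_that("derive_resistance pools per-ancestry fits and covers all phenotypes", {
  sim <- simulate_cohort(small_cfg(n_families = 400L, seed = 59L))
  gr <- compute_genetic_risk(sim$subjects, sim$relatives)
  rs <- derive_resistance(sim$subjects, gr, cluster_mode = "robust")
  expect_setequal(unique(rs$resistance$phenotype), c("initiation", "hed", "aud"))
  expect_true(all(c("initiation.EA", "initiation.AA", "hed.EA", "hed.AA") %in%
                    names(rs$fits)))
  expect_true(all(is.finite(rs$resistance$value)))
  expect_true(all(rs$resistance$value[rs$resistance$phenotype == "aud"] %in% 0:1))
  # initiation residuals cover exactly the baseline-naive subjects
  init <- rs$resistance[rs$resistance$phenotype == "initiation", ]
  expect_setequal(init$subject_id,
                  sim$subjects$subject_id[sim$subjects$baseline_initiated == 0L])
})
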
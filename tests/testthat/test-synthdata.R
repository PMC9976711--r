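test_that("generator is seed-deterministic and handles the empty case", {
  empty <- generate_families(small_cfg(n_families = 0L))
  expect_equal(nrow(empty$subjects), 0L)
  expect_equal(nrow(empty$relatives), 0L)

  cfg <- small_cfg(n_families = 50L, seed = 7L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$relatives, b$relatives)

  c2 <- simulate_cohort(small_cfg(n_families = 50L, seed = 8L))
  expect_false(identical(a$subjects$true_liability, c2$subjects$true_liability))
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(h2_liability = 1.2), "h2_liability")
  expect_error(sim_config(missing_rate_per_stage = 1), "missing_rate_per_stage")
  expect_error(sim_config(loadings = list(father = c(1.2, .5, .5, .5),
                                          mother = rep(.5, 4))), "loadings")
  expect_error(sim_config(hazard_shape = c(initiation = -1, hed = 2)),
               "hazard_shape")
  expect_error(sim_config(log_hr = list(initiation = c(true_liability = Inf),
                                        hed = c(true_liability = 0))),
               "finite")
  # structural block too strong for unit variances -> named configuration error
  expect_error(sim_config(resist_paths = c(fq = .9, mq = .9, monitoring = .9,
                                           peer = .9, partner = .9, soccomp = .9)),
               "resistance block")
  expect_error(sim_config(exog_cor = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "exog_cor")
})

test_that("liability, PRS and family sharing match the generative law", {
  cfg <- small_cfg(n_families = 2000L, seed = 11L, h2_liability = 0.5,
                   prs_r2 = 0.1, mean_family_size = 2)
  fam <- generate_families(cfg)
  s <- fam$subjects

  # PRS is a noisy proxy calibrated to prs_r2 (checked at n ~ 4000-5000)
  expect_lt(abs(cor(s$prs, s$true_liability)^2 - cfg$prs_r2), 0.05)

  # within-family correlation strictly positive (one-sided, alpha = .01)
  fams <- split(s$true_liability, s$family_id)
  pairs <- do.call(rbind, lapply(fams[lengths(fams) >= 2L], function(v)
    cbind(v[1], v[2])))
  ct <- cor.test(pairs[, 1], pairs[, 2], alternative = "greater")
  expect_lt(ct$p.value, 0.01)

  # family-mean vs offspring liability correlation matches a brute-force
  # Monte-Carlo oracle using the same generative equations at n = 1e5
  fam_mean <- ave(s$true_liability, s$family_id)
  obs <- cor(fam_mean, s$true_liability)
  set.seed(99)
  k <- 2L                           # oracle uses fixed sibship size 2
  nf <- 5e4L
  a <- rnorm(nf, 0, sqrt(0.5))
  b1 <- rnorm(nf, 0, sqrt(0.5)); b2 <- rnorm(nf, 0, sqrt(0.5))
  l1 <- a + b1; l2 <- a + b2
  fm <- (l1 + l2) / 2
  oracle <- cor(c(fm, fm), c(l1, l2))
  # generated families vary in size around 2, so compare within +/- 0.05
  expect_lt(abs(obs - oracle), 0.05)
})

test_that("onset ages follow the Weibull proportional-hazards law", {
  # no covariate effects, shape 1 -> exponential onsets; KM median = scale*ln 2
  cfg <- small_cfg(n_families = 5000L, seed = 13L, mean_family_size = 1,
                   hazard_shape = c(initiation = 1, hed = 1),
                   hazard_scale = c(initiation = 20, hed = 30),
                   log_hr = list(initiation = numeric(0), hed = numeric(0)),
                   censor_age_range = c(40, 80))
  s <- simulate_onsets(generate_families(cfg)$subjects, cfg)
  km <- survival::survfit(survival::Surv(time_initiation, event_initiation) ~ 1,
                          data = s)
  med <- unname(summary(km)$table["median"])
  expect_lt(abs(med - 20 * log(2)), 0.75)   # MC error at n = 5000

  # HED never precedes initiation
  both <- s$event_initiation == 1L & s$event_hed == 1L
  expect_true(all(s$onset_age_hed[both] >= s$onset_age_initiation[both]))

  # event flags consistent with censoring ages
  expect_true(all(is.na(s$onset_age_initiation[s$event_initiation == 0L])))
  expect_true(all(s$time_initiation <= s$last_assessment_age + 1e-12))
})

test_that("a doubled hazard is recovered by the downstream Cox fit", {
  cfg <- small_cfg(n_families = 1500L, seed = 17L,
                   log_hr = list(initiation = c(exposed = log(2)),
                                 hed = numeric(0)),
                   censor_age_range = c(15, 30))
  fam <- generate_families(cfg)
  s <- fam$subjects
  set.seed(18)
  s$exposed <- rbinom(nrow(s), 1L, 0.5)
  s <- simulate_onsets(s, cfg)
  fit <- fit_clustered_cox(s$time_initiation, s$event_initiation,
                           cbind(exposed = s$exposed), s$family_id,
                           cluster_mode = "robust")
  expect_lt(abs(fit$beta[["exposed"]] - log(2)), 3 * fit$se[[1]])
})

test_that("social block honours the path structure", {
  # null structure: parenting factors uncorrelated with mediators
  cfg0 <- small_cfg(n_families = 2000L, seed = 19L, mean_family_size = 1,
                    path_matrix = matrix(0, 3, 3,
                                         dimnames = list(c("peer", "partner", "soccomp"),
                                                         NULL)),
                    resist_paths = rep(0, 6))
  s0 <- simulate_social_block(generate_families(cfg0)$subjects, cfg0)
  for (lat in c("true_fq", "true_mq", "true_mon"))
    for (med in c("true_peer", "true_partner", "true_soccomp"))
      expect_lt(abs(cor(s0[[lat]], s0[[med]])), 0.05)

  # mediators and resistance have (near) unit variance by construction
  cfg <- small_cfg(n_families = 2000L, seed = 23L, mean_family_size = 1)
  s <- simulate_social_block(generate_families(cfg)$subjects, cfg)
  for (v in c("true_peer", "true_partner", "true_soccomp", "true_resist"))
    expect_lt(abs(sd(s[[v]]) - 1), 0.05)

  # parent absence blanks that parent's items only
  nofa <- s$has_father_data == 0L
  expect_true(all(is.na(s$fb_1[nofa])))
  expect_false(anyNA(s$mon_1))
})

test_that("follow-up missingness is MCAR, seeded and baseline-preserving", {
  cfg0 <- small_cfg(n_families = 100L, seed = 29L, missing_rate_per_stage = 0)
  s0 <- simulate_cohort(cfg0)$subjects
  expect_false(anyNA(s0$peer))

  cfg <- small_cfg(n_families = 1000L, seed = 31L,
                   missing_rate_per_stage = 0.38, mean_family_size = 2)
  s <- simulate_cohort(cfg)$subjects
  n <- nrow(s)
  frac <- mean(!is.na(s$peer))
  ci <- 0.62 + c(-1, 1) * qnorm(0.995) * sqrt(0.62 * 0.38 / n)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  # baseline block untouched; masks reproducible
  expect_false(anyNA(s$mon_1))
  s2 <- simulate_cohort(cfg)$subjects
  expect_identical(is.na(s$peer), is.na(s2$peer))
})

test_that("cohort writer round-trips through CSV", {
  sim <- simulate_cohort(small_cfg(n_families = 20L, seed = 37L))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("subjects.csv", "relatives.csv",
                                               "manifest.yaml",
                                               "data_dictionary.txt")))))
  back <- read_cohort(dir)
  expect_equal(nrow(back$subjects), nrow(sim$subjects))
  expect_equal(back$subjects$true_liability, sim$subjects$true_liability)
})
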
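# FIML SEM engine: likelihood identities, recovery, multi-group constraints

test_that("FIML equals the complete-data Gaussian ML log-likelihood", {
  d <- simulate_sem_dataset(300, seed = 20)
  m <- sem_model(resistance_model_syntax(), d)
  fit <- fit_sem(m, starts = 1, se = FALSE)
  im <- fit$implied[[1]]
  ll_hand <- gaussian_loglik_by_hand(as.matrix(d[fit$model$observed]),
                                     im$mu, im$Sigma)
  expect_equal(fit$loglik, ll_hand, tolerance = 1e-8 * abs(ll_hand))
})

test_that("FIML handles complementary missing halves per the analytic formula", {
  # diagonal model, three cases: (a1, a2), (b1, NA), (NA, c2)
  d <- data.frame(x1 = c(1.2, 0.4, NA), x2 = c(-0.5, NA, 2.0))
  m <- sem_model("x1 ~~ x1\nx2 ~~ x2", d)
  # parameters: var(x1), var(x2), mean(x1), mean(x2) -- set explicitly
  key <- m$per_group[[1]]$table$key
  par <- numeric(m$nfree)
  par[m$per_group[[1]]$ids[key == "x1~~x1"]] <- 0.8
  par[m$per_group[[1]]$ids[key == "x2~~x2"]] <- 1.5
  par[m$per_group[[1]]$ids[key == "x1~1"]] <- 0.1
  par[m$per_group[[1]]$ids[key == "x2~1"]] <- -0.2
  ll <- fiml_loglik(m, par)
  ll_hand <- sum(dnorm(c(1.2, 0.4), 0.1, sqrt(0.8), log = TRUE)) +
    sum(dnorm(c(-0.5, 2.0), -0.2, sqrt(1.5), log = TRUE))
  expect_equal(ll, ll_hand, tolerance = 1e-10)

  # permuting case order changes nothing
  m2 <- sem_model("x1 ~~ x1\nx2 ~~ x2", d[c(3, 1, 2), ])
  expect_equal(fiml_loglik(m2, par), ll, tolerance = 1e-12)
})

test_that("the analytic gradient matches finite differences", {
  d <- simulate_sem_dataset(200, seed = 21)
  set.seed(22)
  d$peer[runif(200) < 0.2] <- NA
  d$fc_bond[runif(200) < 0.15] <- NA
  m <- sem_model(resistance_model_syntax(), d)
  p <- m$start
  g_a <- alcres:::fiml_gradient(m, p)
  g_n <- vapply(seq_along(p), function(i) {
    h <- 1e-6 * max(1, abs(p[i]))
    up <- p; up[i] <- up[i] + h
    dn <- p; dn[i] <- dn[i] - h
    (fiml_loglik(m, up) - fiml_loglik(m, dn)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_a - g_n) / pmax(abs(g_n), 1)), 1e-5)
})

test_that("refitting from the solution is a fixed point", {
  d <- simulate_sem_dataset(500, seed = 23)
  m <- sem_model(resistance_model_syntax(), d)
  fit <- fit_sem(m, starts = 1, se = FALSE)
  m$start <- fit$par
  fit2 <- fit_sem(m, starts = 1, se = FALSE)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("standardized paths follow beta * sd(x)/sd(y) from implied moments", {
  d <- simulate_sem_dataset(800, seed = 24)
  fit <- fit_sem(sem_model(resistance_model_syntax(), d), starts = 1)
  std <- standardized_solution(fit)
  im <- fit$implied[[1]]
  sdv <- sqrt(diag(im$V)); names(sdv) <- fit$model$vars
  reg <- std[std$role == "regression", ]
  expect_equal(reg$std,
               reg$est * sdv[reg$col] / sdv[reg$row],
               tolerance = 1e-10, ignore_attr = TRUE)
  # covariances standardize to correlations
  cv <- std[std$key == "fq~~mq", ]
  expect_equal(cv$std, cv$est / (sdv[["fq"]] * sdv[["mq"]]), tolerance = 1e-10)
})

test_that("known standardized paths are recovered at n = 5000 within 0.05", {
  cfg <- sim_config()
  d <- simulate_sem_dataset(5000, cfg, seed = 25)
  fit <- fit_sem(sem_model(resistance_model_syntax(), d), starts = 1)
  std <- standardized_solution(fit)
  truth <- c(
    `peer~fq` = -0.03, `peer~mq` = -0.17, `peer~monitoring` = -0.08,
    `partner~fq` = -0.13, `partner~mq` = -0.04, `partner~monitoring` = -0.07,
    `soccomp~fq` = -0.10, `soccomp~mq` = 0.07, `soccomp~monitoring` = 0.24,
    `resist~fq` = -0.19, `resist~mq` = 0.16, `resist~monitoring` = -0.08,
    `resist~peer` = -0.01, `resist~partner` = 0.00, `resist~soccomp` = -0.04)
  est <- setNames(std$std[std$role == "regression"],
                  std$key[std$role == "regression"])
  expect_true(all(abs(est[names(truth)] - truth) < 0.05))
  lam <- setNames(std$std[std$role == "loading"],
                  std$key[std$role == "loading"])
  expect_true(all(abs(lam[paste0("fq=~", c("fc_bond", "fc_close", "fc_comm", "fc_inv"))] -
                        cfg$loadings$father) < 0.05))
})

test_that("multi-group machinery: empty constraints, nesting, df bookkeeping", {
  d <- simulate_sem_dataset(600, seed = 26)
  d$grp <- rep(c("g1", "g2"), 300)
  syn <- resistance_model_syntax()

  # empty constraint set: constrained fit equals the free fit
  mg0 <- fit_multigroup(syn, d, "grp", constraints = character(0),
                        starts = 1, se = FALSE)
  expect_equal(mg0$constrained$loglik, mg0$free$loglik, tolerance = 1e-6)
  expect_identical(lrt(mg0$free, mg0$constrained)$df, 0L)

  # constraining all 15 structural regressions: df = 15, loglik never higher
  mg <- fit_multigroup(syn, d, "grp", constraints = "regressions",
                       starts = 1, se = FALSE)
  lr <- lrt(mg$free, mg$constrained)
  expect_identical(lr$df, 15L)
  expect_lte(mg$constrained$loglik, mg$free$loglik + 1e-6)
  expect_gte(lr$stat, 0)
  expect_true(lr$p >= 0 && lr$p <= 1)

  # a single constrained path: df = 1; nested under the free model
  mg1 <- fit_multigroup(syn, d, "grp", constraints = "soccomp~mq",
                        starts = 1, se = FALSE)
  expect_identical(lrt(mg1$free, mg1$constrained)$df, 1L)
  expect_lte(mg1$constrained$loglik, mg$free$loglik + 1e-6)
  expect_gte(mg1$constrained$loglik, mg$constrained$loglik - 1e-6)

  expect_error(fit_multigroup(syn, d, "grp", constraints = "not~apath"),
               "unknown parameter")
})

test_that("a moderated path is detected by the single-path constraint test", {
  # group 2's mother->social-competence path differs by 0.4
  cfg1 <- sim_config()
  cfg2 <- sim_config(path_matrix = rbind(peer    = c(-0.03, -0.17, -0.08),
                                         partner = c(-0.13, -0.04, -0.07),
                                         soccomp = c(-0.10,  0.47,  0.24)))
  d1 <- simulate_sem_dataset(1000, cfg1, seed = 27)
  d2 <- simulate_sem_dataset(1000, cfg2, seed = 28)
  d <- rbind(d1, d2); d$grp <- rep(c("g1", "g2"), each = 1000)
  mg <- fit_multigroup(resistance_model_syntax(), d, "grp",
                       constraints = "soccomp~mq", starts = 1, se = FALSE)
  lr <- lrt(mg$free, mg$constrained)
  expect_identical(lr$df, 1L)
  expect_lt(lr$p, 0.05)
})

test_that("model syntax and spec errors are caught", {
  d <- simulate_sem_dataset(100, seed = 29)
  expect_error(sem_model("peer ~", d), "parse")
  expect_error(sem_model("peer ~ + fq", d), "empty variable")
  expect_error(sem_model("peer ~ nosuchvar", d), "lacks model variables")
  expect_error(sem_model(resistance_model_syntax(), d, group = "grp"),
               "not in data")
  m <- sem_model("peer ~ monitoring", d)
  expect_identical(lrt(list(loglik = 0, npar = 3L),
                       list(loglik = 0, npar = 3L))$p, 1)
  expect_error(lrt(list(loglik = 0, npar = 3L), list(loglik = 1, npar = 2L)),
               "exceeds")
})
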
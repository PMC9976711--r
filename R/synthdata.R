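# Synthetic family-panel generator.
#
# Emulates the statistical structure the downstream analyses assume: families
# of related adolescents sharing a latent liability, a polygenic score that is
# a noisy proxy of liability, pedigree relatives whose AUD symptom counts are
# driven by the shared family component, a parenting -> {peer drinking,
# partner drinking, social competence} -> resistance path structure with
# user-set standardized effects, Weibull proportional-hazards onset ages with
# uniform right censoring, and a binary AUD diagnosis subject to the
# age-15/age-23 observability rules.  Every stage is seeded from the config.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort.  Defaults
#' are the generator's stated world: the structural paths, factor loadings and
#' exogenous correlations default to the resistance-to-initiation column of
#' the fitted path model, cohort size and ages to the source cohort
#' (adolescents 11-17 at baseline, ~49.9% female, ~36.5% African-ancestry
#' families, ~62% completing a follow-up).
#'
#' @param n_families number of families.
#' @param mean_family_size expected adolescents per family (1 + Poisson).
#' @param relatedness_mix named proportions `c(first=, second=)` of
#'   first/second-degree pedigree relatives.
#' @param n_relatives pedigree relatives generated per family.
#' @param h2_liability variance share of the family-shared liability
#'   component, in [0,1]; total liability variance is 1.
#' @param prs_r2 squared correlation between the polygenic score and
#'   liability, in [0,1].
#' @param loadings list with `father` and `mother`, each 4 standardized
#'   loadings in (0,1) for bonding, closeness, communication, involvement.
#' @param path_matrix 3x3 matrix of standardized paths: rows peer, partner,
#'   soccomp; columns fq, mq, monitoring.
#' @param resist_paths 6 standardized paths of the resistance outcome on
#'   fq, mq, monitoring, peer, partner, soccomp.
#' @param exog_cor 3x3 correlation matrix of (fq, mq, monitoring).
#' @param dist_cor 3x3 correlation matrix of the mediator disturbances.
#' @param item_fidelity correlation between an item's latent and its scale's
#'   continuous indicator (controls attenuation of item-scored scales).
#' @param hazard_shape,hazard_scale named vectors (`initiation`, `hed`):
#'   Weibull shape (>0) and scale in years.
#' @param log_hr named list (`initiation`, `hed`) of named log hazard ratios;
#'   names must be subject columns (e.g. `true_liability`, `true_resist`).
#' @param censor_age_range `[min,max]` years of the uniform last-assessment
#'   (censoring) age.
#' @param aud_prev_target target AUD prevalence among drinkers.
#' @param aud_liability_slope probit slope of diagnosis on liability.
#' @param symptom_intercept,symptom_slope log-linear Poisson model of a
#'   relative's maximum AUD symptom count on their liability.
#' @param missing_rate_per_stage probability, in [0,1), that a subject misses
#'   the follow-up assessment (peer, partner, social competence).
#' @param p_father_data,p_mother_data probability that father/mother items
#'   are available.
#' @param ancestry_mix named proportions of family ancestry labels.
#' @param baseline_age_range uniform range of baseline ages (years).
#' @param p_female probability a subject is female.
#' @param seed integer seed; fully determines the generated data.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 900L,
                       mean_family_size = 2,
                       relatedness_mix = c(first = 0.5, second = 0.5),
                       n_relatives = 5L,
                       h2_liability = 0.5,
                       prs_r2 = 0.1,
                       loadings = list(father = c(0.82, 0.70, 0.60, 0.62),
                                       mother = c(0.70, 0.64, 0.45, 0.52)),
                       path_matrix = rbind(peer    = c(-0.03, -0.17, -0.08),
                                           partner = c(-0.13, -0.04, -0.07),
                                           soccomp = c(-0.10,  0.07,  0.24)),
                       resist_paths = c(fq = -0.19, mq = 0.16, monitoring = -0.08,
                                        peer = -0.01, partner = 0.00, soccomp = -0.04),
                       exog_cor = matrix(c(1, 0.63, 0.52,
                                           0.63, 1, 0.50,
                                           0.52, 0.50, 1), 3, 3),
                       dist_cor = matrix(c(1, 0.37, 0.04,
                                           0.37, 1, 0.04,
                                           0.04, 0.04, 1), 3, 3),
                       item_fidelity = 0.9,
                       hazard_shape = c(initiation = 4, hed = 4.5),
                       hazard_scale = c(initiation = 17, hed = 21),
                       log_hr = list(initiation = c(true_liability = 0.35,
                                                    true_resist = 0.30),
                                     hed = c(true_liability = 0.45,
                                             true_resist = 0.30)),
                       censor_age_range = c(17, 26),
                       aud_prev_target = 0.10,
                       aud_liability_slope = 0.5,
                       symptom_intercept = -0.4,
                       symptom_slope = 0.8,
                       missing_rate_per_stage = 0.38,
                       p_father_data = 0.80,
                       p_mother_data = 0.97,
                       ancestry_mix = c(EA = 0.635, AA = 0.365),
                       baseline_age_range = c(11, 17),
                       p_female = 0.499,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_families >= 0, cfg$mean_family_size >= 1, cfg$n_relatives >= 0)
  in01 <- function(x) all(x >= 0 & x <= 1)
  if (!in01(cfg$h2_liability) || !in01(cfg$prs_r2))
    stop("h2_liability and prs_r2 must lie in [0,1]")
  if (cfg$missing_rate_per_stage < 0 || cfg$missing_rate_per_stage >= 1)
    stop("missing_rate_per_stage must lie in [0,1)")
  if (!in01(cfg$relatedness_mix) || abs(sum(cfg$relatedness_mix) - 1) > 1e-8)
    stop("relatedness_mix must be proportions summing to 1")
  for (p in c("father", "mother")) {
    l <- cfg$loadings[[p]]
    if (length(l) != 4L || any(l <= 0 | l >= 1))
      stop("loadings$", p, " must be 4 values in (0,1)")
  }
  if (any(cfg$hazard_shape <= 0) || any(cfg$hazard_scale <= 0))
    stop("hazard_shape and hazard_scale must be positive")
  for (h in cfg$log_hr) if (any(!is.finite(h)))
    stop("log_hr values must be finite")
  if (diff(cfg$censor_age_range) < 0) stop("censor_age_range must be increasing")
  if (!isTRUE(all(eigen(cfg$exog_cor, symmetric = TRUE,
                        only.values = TRUE)$values > 1e-10)))
    stop("configuration error: exog_cor block is not positive definite")
  if (!isTRUE(all(eigen(cfg$dist_cor, symmetric = TRUE,
                        only.values = TRUE)$values > 1e-10)))
    stop("configuration error: dist_cor block is not positive definite")
  sv <- structural_variances(cfg)
  if (any(sv$dist_var <= 0))
    stop("configuration error: mediator block implies non-positive disturbance ",
         "variance (path_matrix too strong for exog_cor)")
  if (sv$resist_var <= 0)
    stop("configuration error: resistance block implies non-positive residual ",
         "variance (resist_paths too strong)")
  invisible(cfg)
}

# residual variances that give every structural variable unit total variance
structural_variances <- function(cfg) {
  B <- cfg$path_matrix
  R <- cfg$exog_cor
  expl <- diag(B %*% R %*% t(B))            # explained variance per mediator
  dist_var <- 1 - expl
  if (any(dist_var <= 0)) return(list(dist_var = dist_var, resist_var = NA_real_))
  # covariance of (fq, mq, mon, peer, partner, soccomp) with unit variances
  D <- diag(sqrt(dist_var)) %*% cfg$dist_cor %*% diag(sqrt(dist_var))
  top <- cbind(R, R %*% t(B))
  bottom <- cbind(B %*% R, B %*% R %*% t(B) + D)
  V6 <- rbind(top, bottom)
  b <- cfg$resist_paths
  resist_var <- 1 - drop(t(b) %*% V6 %*% b)
  list(dist_var = dist_var, resist_var = resist_var, V6 = V6)
}

rmvn_chol <- function(n, R) {
  matrix(stats::rnorm(n * ncol(R)), n) %*% chol(R)
}

# equal-probability (or custom-probability) discretization of a standard
# normal latent into 1..K
discretize <- function(z, k, probs = NULL) {
  if (is.null(probs)) probs <- rep(1 / k, k)
  cuts <- stats::qnorm(cumsum(probs)[-k])
  findInterval(z, cuts) + 1L
}

#' Generate families, liabilities and pedigree relatives
#'
#' Liability is the sum of a family-shared Gaussian component (variance
#' `h2_liability`) and an individual component (variance `1 - h2_liability`).
#' The polygenic score is a scaled copy of liability plus noise calibrated so
#' that its squared correlation with liability equals `prs_r2`.  Relatives
#' share the family component (attenuated by half for second-degree
#' relatives) and their maximum AUD symptom counts are Poisson with a
#' log-mean linear in their own liability.
#'
#' @param cfg a [sim_config()].
#' @return list with data.frames `subjects` and `relatives`.
#' @export
generate_families <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  nf <- cfg$n_families
  if (nf == 0L) {
    return(list(subjects = data.frame(), relatives = data.frame()))
  }
  fam_sizes <- 1L + stats::rpois(nf, cfg$mean_family_size - 1)
  n <- sum(fam_sizes)
  fam_id <- rep(seq_len(nf), fam_sizes)
  a_f <- stats::rnorm(nf, 0, sqrt(cfg$h2_liability))
  liab <- a_f[fam_id] + stats::rnorm(n, 0, sqrt(1 - cfg$h2_liability))
  prs <- sqrt(cfg$prs_r2) * liab + stats::rnorm(n, 0, sqrt(1 - cfg$prs_r2))
  fam_ancestry <- sample(names(cfg$ancestry_mix), nf, replace = TRUE,
                         prob = cfg$ancestry_mix)
  subjects <- data.frame(
    family_id = fam_id,
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = stats::rbinom(n, 1L, cfg$p_female),
    baseline_age = stats::runif(n, cfg$baseline_age_range[1],
                                cfg$baseline_age_range[2]),
    ancestry_group = fam_ancestry[fam_id],
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
    prs = prs,
    has_mother_data = stats::rbinom(n, 1L, cfg$p_mother_data),
    has_father_data = stats::rbinom(n, 1L, cfg$p_father_data),
    true_family_component = a_f[fam_id],
    true_liability = liab,
    stringsAsFactors = FALSE
  )
  # pedigree relatives: first-degree share the family component fully,
  # second-degree at half weight; total liability variance kept at 1
  nr <- cfg$n_relatives * nf
  relatives <- data.frame()
  if (nr > 0L) {
    rfam <- rep(seq_len(nf), each = cfg$n_relatives)
    degree <- ifelse(stats::runif(nr) < cfg$relatedness_mix[["first"]], 1L, 2L)
    lab1 <- c("father", "mother", "full sibling")
    lab2 <- c("grandparent", "parental sibling", "half sibling")
    relation <- ifelse(degree == 1L, sample(lab1, nr, replace = TRUE),
                       sample(lab2, nr, replace = TRUE))
    share <- ifelse(degree == 1L, 1, 0.5)
    rliab <- share * a_f[rfam] +
      stats::rnorm(nr, 0, sqrt(pmax(1 - share^2 * cfg$h2_liability, 1e-8)))
    sympt <- stats::rpois(nr, exp(cfg$symptom_intercept + cfg$symptom_slope * rliab))
    relatives <- data.frame(
      family_id = rfam,
      relative_id = sprintf("R%06d", seq_len(nr)),
      degree = degree,
      relation_label = relation,
      aud_max_symptoms = sympt,
      stringsAsFactors = FALSE
    )
  }
  list(subjects = subjects, relatives = relatives)
}

#' Populate social-relationship latents, item responses and mediators
#'
#' Draws the exogenous parenting latents (father quality, mother quality,
#' monitoring) from `exog_cor`, generates the mediators from the structural
#' equations in `path_matrix` with correlated disturbances, and the
#' continuous resistance propensity from `resist_paths`.  Item responses are
#' produced by discretizing item-level latents tied to each scale's
#' continuous indicator at equal-probability Gaussian thresholds, so scales
#' scored from items are mildly attenuated versions of the continuous
#' indicators.
#'
#' @param subjects data.frame from [generate_families()].
#' @param cfg a [sim_config()].
#' @return subjects with item, mediator and `true_*` latent columns added.
#' @export
simulate_social_block <- function(subjects, cfg) {
  validate_sim_config(cfg)
  if (nrow(subjects) == 0L) return(subjects)
  set.seed(cfg$seed + 1L)
  n <- nrow(subjects)
  ex <- rmvn_chol(n, cfg$exog_cor)
  fq <- ex[, 1]; mq <- ex[, 2]; mon <- ex[, 3]
  sv <- structural_variances(cfg)
  dist <- rmvn_chol(n, cfg$dist_cor) %*% diag(sqrt(sv$dist_var))
  med <- ex %*% t(cfg$path_matrix) + dist
  resist <- drop(cbind(ex, med) %*% cfg$resist_paths) +
    stats::rnorm(n, 0, sqrt(sv$resist_var))
  subjects$true_fq <- fq
  subjects$true_mq <- mq
  subjects$true_mon <- mon
  subjects$true_peer <- med[, 1]
  subjects$true_partner <- med[, 2]
  subjects$true_soccomp <- med[, 3]
  subjects$true_resist <- resist

  rho <- cfg$item_fidelity
  item_block <- function(latent, lambda, n_items, k, probs = NULL,
                         reverse = FALSE) {
    y <- lambda * latent + sqrt(1 - lambda^2) * stats::rnorm(n)
    sapply(seq_len(n_items), function(j) {
      u <- rho * y + sqrt(1 - rho^2) * stats::rnorm(n)
      if (reverse) u <- -u
      discretize(u, k, probs)
    })
  }
  lf <- cfg$loadings$father; lm_ <- cfg$loadings$mother
  subjects[paste0("fb_", 1:12)] <- item_block(fq, lf[1], 12L, 4L)
  subjects[["fcl_1"]] <- discretize(rho * (lf[2] * fq + sqrt(1 - lf[2]^2) * stats::rnorm(n)) +
                                      sqrt(1 - rho^2) * stats::rnorm(n), 4L)
  subjects[["fcl_2"]] <- discretize(rho * (lf[2] * fq + sqrt(1 - lf[2]^2) * stats::rnorm(n)) +
                                      sqrt(1 - rho^2) * stats::rnorm(n), 3L)
  subjects[paste0("fcm_", 1:3)] <- item_block(fq, lf[3], 3L, 2L,
                                              probs = c(0.33, 0.67)) - 1L
  subjects[paste0("fin_", 1:6)] <- item_block(fq, lf[4], 6L, 2L,
                                              probs = c(0.38, 0.62)) - 1L
  subjects[paste0("mb_", 1:12)] <- item_block(mq, lm_[1], 12L, 4L)
  subjects[["mcl_1"]] <- discretize(rho * (lm_[2] * mq + sqrt(1 - lm_[2]^2) * stats::rnorm(n)) +
                                      sqrt(1 - rho^2) * stats::rnorm(n), 4L)
  subjects[["mcl_2"]] <- discretize(rho * (lm_[2] * mq + sqrt(1 - lm_[2]^2) * stats::rnorm(n)) +
                                      sqrt(1 - rho^2) * stats::rnorm(n), 3L)
  subjects[paste0("mcm_", 1:3)] <- item_block(mq, lm_[3], 3L, 2L,
                                              probs = c(0.33, 0.67)) - 1L
  subjects[paste0("min_", 1:6)] <- item_block(mq, lm_[4], 6L, 2L,
                                              probs = c(0.38, 0.62)) - 1L
  # monitoring items are reverse-keyed (1 = always); high monitoring gives
  # low raw responses, recovered by the scorer's reverse coding
  subjects[paste0("mon_", 1:3)] <- item_block(mon, 0.85, 3L, 4L, reverse = TRUE)
  # follow-up measures
  subjects$peer <- discretize(subjects$true_peer, 4L,
                              probs = c(0.62, 0.25, 0.09, 0.04))
  subjects$partner <- as.integer(subjects$true_partner >
                                   stats::qnorm(0.65))
  subjects$soccomp <- pmin(pmax(round(8.3 + 2.4 * subjects$true_soccomp, 1), 0), 12)
  # parent absence blanks that parent's items
  fcols <- grep("^(fb|fcl|fcm|fin)_", names(subjects))
  mcols <- grep("^(mb|mcl|mcm|min)_", names(subjects))
  subjects[subjects$has_father_data == 0L, fcols] <- NA
  subjects[subjects$has_mother_data == 0L, mcols] <- NA
  subjects
}

#' Simulate onset ages, censoring, and AUD diagnosis
#'
#' Onset ages follow a Weibull proportional-hazards law:
#' `T = scale * (-log U / exp(eta))^(1/shape)` with `eta = sum(log_hr * x)`.
#' Heavy-episodic-drinking onset is constrained not to precede initiation.
#' The censoring (last assessment) age is uniform on `censor_age_range`;
#' events are observed iff onset <= censoring age.  AUD diagnosis is a probit
#' function of liability among subjects who ever initiated drinking.
#'
#' @param subjects data.frame with liability (and any columns named in
#'   `log_hr`) populated.
#' @param cfg a [sim_config()].
#' @return subjects with onset/censoring/event/diagnosis columns added.
#' @export
simulate_onsets <- function(subjects, cfg) {
  validate_sim_config(cfg)
  if (nrow(subjects) == 0L) return(subjects)
  set.seed(cfg$seed + 2L)
  n <- nrow(subjects)
  eta_of <- function(h) {
    if (length(h) == 0L) return(numeric(n))
    miss <- setdiff(names(h), names(subjects))
    if (length(miss)) stop("log_hr names not found in subjects: ",
                           paste(miss, collapse = ", "))
    drop(as.matrix(subjects[names(h)]) %*% h)
  }
  draw <- function(process) {
    eta <- eta_of(cfg$log_hr[[process]])
    shp <- cfg$hazard_shape[[process]]
    scl <- cfg$hazard_scale[[process]]
    scl * (-log(stats::runif(n)) / exp(eta))^(1 / shp)
  }
  t_init <- draw("initiation")
  t_hed <- pmax(draw("hed"), t_init)
  cens <- stats::runif(n, cfg$censor_age_range[1], cfg$censor_age_range[2])
  subjects$last_assessment_age <- cens
  subjects$event_initiation <- as.integer(t_init <= cens)
  subjects$event_hed <- as.integer(t_hed <= cens)
  subjects$onset_age_initiation <- ifelse(t_init <= cens, t_init, NA_real_)
  subjects$onset_age_hed <- ifelse(t_hed <= cens, t_hed, NA_real_)
  subjects$time_initiation <- pmin(t_init, cens)
  subjects$time_hed <- pmin(t_hed, cens)
  subjects$baseline_initiated <- as.integer(t_init <= subjects$baseline_age)
  subjects$baseline_hed <- as.integer(t_hed <= subjects$baseline_age)
  subjects$drinker <- subjects$event_initiation
  p_diag <- stats::pnorm(stats::qnorm(cfg$aud_prev_target) +
                           cfg$aud_liability_slope * subjects$true_liability)
  subjects$aud_diagnosed <- as.integer(subjects$drinker == 1L &
                                         stats::runif(n) < p_diag)
  subjects
}

#' Apply missing-completely-at-random follow-up attrition
#'
#' Masks the follow-up block (peer drinking, partner drinking, social
#' competence) for a seeded random subset of subjects; baseline measures are
#' untouched.
#'
#' @param subjects data.frame with follow-up columns populated.
#' @param cfg a [sim_config()].
#' @return subjects with follow-up values masked for attrited subjects.
#' @export
apply_missingness <- function(subjects, cfg) {
  validate_sim_config(cfg)
  if (nrow(subjects) == 0L || cfg$missing_rate_per_stage == 0) return(subjects)
  set.seed(cfg$seed + 3L)
  drop_fu <- stats::runif(nrow(subjects)) < cfg$missing_rate_per_stage
  subjects[drop_fu, c("peer", "partner", "soccomp")] <- NA
  subjects
}

#' Simulate a complete cohort
#'
#' Runs [generate_families()], [simulate_social_block()],
#' [simulate_onsets()] and [apply_missingness()] in order.
#'
#' @param cfg a [sim_config()].
#' @return list with `subjects`, `relatives` and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  fam <- generate_families(cfg)
  s <- fam$subjects
  if (nrow(s) > 0L) {
    s <- simulate_social_block(s, cfg)
    s <- simulate_onsets(s, cfg)
    s <- apply_missingness(s, cfg)
  }
  list(subjects = s, relatives = fam$relatives, config = cfg)
}

#' Simulate indicator-level data straight from the path model
#'
#' Generates the 13 analysis columns (8 continuous parent-quality indicators,
#' monitoring, the 3 mediators and the resistance outcome) exactly from the
#' Gaussian path model, without item discretization, censoring or survival
#' machinery.  Used for parameter-recovery and coverage checks of the SEM
#' stage, where the generating values must be the estimands.
#'
#' @param n number of cases.
#' @param cfg a [sim_config()] supplying loadings, paths and correlations.
#' @param seed integer seed.
#' @return data.frame with 13 columns matching
#'   [resistance_model_syntax()]; true latents stored in
#'   `attr(, "latents")`.
#' @export
simulate_sem_dataset <- function(n, cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  set.seed(seed)
  ex <- rmvn_chol(n, cfg$exog_cor)
  sv <- structural_variances(cfg)
  dist <- rmvn_chol(n, cfg$dist_cor) %*% diag(sqrt(sv$dist_var))
  med <- ex %*% t(cfg$path_matrix) + dist
  resist <- drop(cbind(ex, med) %*% cfg$resist_paths) +
    stats::rnorm(n, 0, sqrt(sv$resist_var))
  ind <- function(latent, lambda) lambda * latent + sqrt(1 - lambda^2) * stats::rnorm(n)
  lf <- cfg$loadings$father; lm_ <- cfg$loadings$mother
  d <- data.frame(
    fc_bond = ind(ex[, 1], lf[1]), fc_close = ind(ex[, 1], lf[2]),
    fc_comm = ind(ex[, 1], lf[3]), fc_inv = ind(ex[, 1], lf[4]),
    mc_bond = ind(ex[, 2], lm_[1]), mc_close = ind(ex[, 2], lm_[2]),
    mc_comm = ind(ex[, 2], lm_[3]), mc_inv = ind(ex[, 2], lm_[4]),
    monitoring = ex[, 3],
    peer = med[, 1], partner = med[, 2], soccomp = med[, 3],
    resist = resist)
  attr(d, "latents") <- data.frame(fq = ex[, 1], mq = ex[, 2], mon = ex[, 3])
  d
}

#' Write a simulated cohort to CSV
#'
#' Emits `subjects.csv`, `relatives.csv`, a YAML `manifest.yaml` recording the
#' configuration and seed, and a plain-text `data_dictionary.txt`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(sim$relatives, file.path(dir, "relatives.csv"), row.names = FALSE)
  cfg <- sim$config
  cfg_plain <- lapply(unclass(cfg), function(x) if (is.matrix(x)) as.data.frame(x) else x)
  yaml::write_yaml(list(generator = "alcres::simulate_cohort",
                        seed = cfg$seed, config = cfg_plain),
                   file.path(dir, "manifest.yaml"))
  dict <- c(
    "subjects.csv: one row per adolescent subject",
    "  family_id, subject_id          identifiers (family clusters outcomes)",
    "  sex                            0 = male, 1 = female",
    "  baseline_age                   years at the baseline assessment",
    "  ancestry_group                 family-level ancestry label",
    "  pc1..pc3                       synthetic nuisance covariates (stand-ins for ancestry PCs)",
    "  prs                            polygenic score (noisy proxy of liability)",
    "  has_mother_data/has_father_data 1 if that parent's items were collected",
    "  fb_*/fcl_*/fcm_*/fin_*         father bonding (12, 1-4), closeness (4/3-pt),",
    "                                 communication (3, 0/1), involvement (6, 0/1)",
    "  mb_*/mcl_*/mcm_*/min_*         same blocks for the mother",
    "  mon_1..mon_3                   monitoring items, 1-4, reverse keyed (1 = always)",
    "  peer                           peer drinking, ordinal 1-4 (follow-up)",
    "  partner                        romantic partner drinking, 0/1 (follow-up)",
    "  soccomp                        social competence score (follow-up)",
    "  time_/onset_age_/event_*       onset ages, censoring times and event flags",
    "  baseline_initiated/baseline_hed 1 if milestone predates baseline",
    "  drinker, aud_diagnosed, last_assessment_age   AUD coding inputs",
    "  true_*                         simulation-only latents; never used by analyses",
    "relatives.csv: one row per pedigree relative",
    "  family_id, relative_id, degree (1/2), relation_label, aud_max_symptoms")
  writeLines(dict, file.path(dir, "data_dictionary.txt"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `subjects.csv` and `relatives.csv`.
#' @return list with `subjects` and `relatives`.
#' @export
read_cohort <- function(dir) {
  list(subjects = utils::read.csv(file.path(dir, "subjects.csv"),
                                  stringsAsFactors = FALSE),
       relatives = utils::read.csv(file.path(dir, "relatives.csv"),
                                   stringsAsFactors = FALSE))
}
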
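# End-to-end pipeline: simulate -> score -> risk -> resist -> assoc -> sem,
# with a YAML config, per-stage outputs, a run manifest, and a small CLI.

#' Default pipeline configuration
#'
#' Nested list mirroring the analysis choices: the simulation block (passed
#' to [sim_config()]), analysis options (cluster mode, family-history-density
#' form, quadrature nodes, optimizer starts, alpha = .05 two-tailed) and
#' paths.  Options that no published analysis pins down are tagged
#' "assumption" in the rendered manifest.
#'
#' @param seed integer master seed.
#' @param outdir output directory.
#' @return config list.
#' @export
default_config <- function(seed = 1L, outdir = "alcres_out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = TRUE,
    input_dir = NULL,                      # used when simulate = FALSE
    sim = list(n_families = 900L),
    analysis = list(
      cluster_mode = "gamma_frailty",      # assumption: frailty family unstated
      conditional_residuals = TRUE,        # assumption
      fhd_form = "weighted_mean",          # assumption: normalization unstated
      ties = "breslow",
      nodes = 15L,
      starts = 3L,
      alpha = 0.05
    )
  )
}

validate_config <- function(config) {
  a <- config$analysis
  if (a$alpha <= 0 || a$alpha >= 1) stop("alpha must lie in (0,1)")
  if (!a$cluster_mode %in% c("gamma_frailty", "robust"))
    stop("cluster_mode must be 'gamma_frailty' or 'robust'")
  if (!a$fhd_form %in% c("weighted_mean", "weighted_sum"))
    stop("fhd_form must be 'weighted_mean' or 'weighted_sum'")
  if (a$nodes < 2L) stop("quadrature nodes must be >= 2")
  if (!isTRUE(config$simulate)) {
    if (is.null(config$input_dir) ||
        !file.exists(file.path(config$input_dir, "subjects.csv")))
      stop("simulate = FALSE but input_dir does not contain subjects.csv")
  }
  invisible(config)
}

pipeline_log <- function(level, ...) {
  if (identical(getOption("alcres.log_level", "info"), "quiet")) return(invisible())
  message(sprintf("[alcres] %s", paste0(...)))
}

# assemble the per-subsample analysis table used by assoc and sem stages
assemble_analysis <- function(subjects, scores, resistance) {
  wide <- merge(subjects[c("subject_id", "family_id", "baseline_age", "sex",
                           "ancestry_group", "has_mother_data",
                           "has_father_data", "peer", "partner", "soccomp")],
                scores, by = "subject_id", sort = FALSE)
  for (ph in unique(resistance$phenotype)) {
    r <- resistance[resistance$phenotype == ph, c("subject_id", "value")]
    names(r)[2] <- paste0("res_", ph)
    wide <- merge(wide, r, by = "subject_id", all.x = TRUE, sort = FALSE)
  }
  names(wide)[names(wide) == "res_aud"] <- "aud_resistance"
  wide$ancestry_num <- as.integer(factor(wide$ancestry_group))
  wide
}

sem_stage_data <- function(analysis, outcome_col) {
  d <- analysis[c("fc_bond", "fc_close", "fc_comm", "fc_inv",
                  "mc_bond", "mc_close", "mc_comm", "mc_inv",
                  "monitoring", "peer", "partner", "soccomp")]
  d$resist <- analysis[[outcome_col]]
  d <- d[!is.na(d$resist), , drop = FALSE]
  d
}

sem_table <- function(fit, outcome_label) {
  std <- standardized_solution(fit)
  keep <- std$role %in% c("loading", "regression") |
    (std$role == "covariance" &
       std$row %in% c("fq", "mq", "monitoring", "peer", "partner", "soccomp") &
       std$col %in% c("fq", "mq", "monitoring", "peer", "partner", "soccomp"))
  std <- std[keep, ]
  data.frame(outcome = outcome_label, group = std$group, parameter = std$key,
             role = std$role, est_std = std$std, ci_lower = std$std_ci_lower,
             ci_upper = std$std_ci_upper,
             significant = std$std_ci_lower > 0 | std$std_ci_upper < 0)
}

#' Run the full pipeline
#'
#' Executes simulate -> score -> risk -> resist -> assoc -> sem, writing each
#' stage's CSV outputs plus a YAML run manifest under `config$outdir`.  Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [default_config()]-shaped list, or a path to a YAML file.
#' @param stages subset of stages to run (default all).
#' @return (invisibly) a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "score", "risk", "resist",
                                    "assoc", "sem")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  config <- utils::modifyList(base, config)
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  a <- config$analysis
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list(config = config)

  # --- simulate ------------------------------------------------------------
  if ("simulate" %in% stages && isTRUE(config$simulate)) {
    out$sim <- run_stage("simulate", {
      cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      sim <- simulate_cohort(cfg)
      write_cohort(sim, outdir)
      pipeline_log("info", "simulate: ", nrow(sim$subjects), " subjects in ",
                   cfg$n_families, " families")
      sim
    })
    subjects <- out$sim$subjects
    relatives <- out$sim$relatives
  } else {
    src <- if (isTRUE(config$simulate)) outdir else config$input_dir
    coh <- read_cohort(src)
    subjects <- coh$subjects
    relatives <- coh$relatives
  }

  # --- score ---------------------------------------------------------------
  if ("score" %in% stages) {
    out$scores <- run_stage("score", {
      sc <- score_subjects(subjects)
      cf <- fit_parent_cfas(sc, starts = a$starts)
      utils::write.csv(cf$scores, file.path(outdir, "scores.csv"),
                       row.names = FALSE)
      fitrep <- data.frame(
        model = c("father", "mother"),
        chi_square = c(cf$father$chi_square, cf$mother$chi_square),
        df = c(cf$father$df, cf$mother$df),
        cfi = c(cf$father$cfi, cf$mother$cfi),
        srmr = c(cf$father$srmr, cf$mother$srmr))
      utils::write.csv(fitrep, file.path(outdir, "cfa_fit.csv"),
                       row.names = FALSE)
      pipeline_log("info", sprintf(
        "score: father CFA chi2(%d)=%.2f CFI=%.3f SRMR=%.3f; mother chi2(%d)=%.2f CFI=%.3f SRMR=%.3f",
        cf$father$df, cf$father$chi_square, cf$father$cfi, cf$father$srmr,
        cf$mother$df, cf$mother$chi_square, cf$mother$cfi, cf$mother$srmr))
      cf
    })
  }

  # --- risk ----------------------------------------------------------------
  if ("risk" %in% stages) {
    out$genrisk <- run_stage("risk", {
      gr <- compute_genetic_risk(subjects, relatives, fhd_form = a$fhd_form)
      utils::write.csv(gr, file.path(outdir, "genrisk.csv"), row.names = FALSE)
      pipeline_log("info", "risk: ", sum(gr$high_risk), " of ", nrow(gr),
                   " subjects flagged high genetic risk")
      gr
    })
  }

  # --- resist --------------------------------------------------------------
  if ("resist" %in% stages) {
    out$resist <- run_stage("resist", {
      rs <- derive_resistance(subjects, out$genrisk,
                              cluster_mode = a$cluster_mode, ties = a$ties,
                              conditional = a$conditional_residuals)
      utils::write.csv(rs$resistance, file.path(outdir, "resistance.csv"),
                       row.names = FALSE)
      hr <- do.call(rbind, lapply(names(rs$fits), function(nm)
        cbind(model = nm, rs$fits[[nm]]$hr_ci)))
      utils::write.csv(hr, file.path(outdir, "cox_report.csv"),
                       row.names = FALSE)
      pipeline_log("info", "resist: subsample n = ",
                   length(rs$subsamples$initiation), " (initiation), ",
                   length(rs$subsamples$hed), " (HED), ",
                   length(rs$subsamples$aud), " (AUD)")
      rs
    })
  }

  # --- assoc ---------------------------------------------------------------
  if ("assoc" %in% stages) {
    out$assoc <- run_stage("assoc", {
      analysis <- assemble_analysis(subjects, out$scores$scores,
                                    out$resist$resistance)
      tab <- run_univariable(analysis, nodes = a$nodes)
      utils::write.csv(tab, file.path(outdir, "assoc_results.csv"),
                       row.names = FALSE)
      pipeline_log("info", "assoc: ", nrow(tab), " univariable models")
      list(table = tab, analysis = analysis)
    })
  }

  # --- sem -----------------------------------------------------------------
  if ("sem" %in% stages) {
    out$sem <- run_stage("sem", {
      analysis <- out$assoc$analysis
      syn <- resistance_model_syntax()
      fits <- list()
      tabs <- list()
      for (oc in c("res_initiation", "res_hed", "aud_resistance")) {
        d <- sem_stage_data(analysis, oc)
        fit <- fit_sem(sem_model(syn, d), starts = a$starts)
        fits[[oc]] <- fit
        tabs[[oc]] <- sem_table(fit, oc)
      }
      tab <- do.call(rbind, tabs)
      utils::write.csv(tab, file.path(outdir, "sem_results.csv"),
                       row.names = FALSE)
      pipeline_log("info", "sem: 3 outcome models fitted")
      list(fits = fits, table = tab)
    })
  }

  manifest <- list(
    package = "alcres",
    version = as.character(utils::packageVersion("alcres")),
    seed = config$seed,
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    assumptions = c(
      "cluster_mode/frailty distribution: assumption (unstated in source analyses)",
      "fhd_form normalization and log base: assumption",
      "conditional (frailty-included) residuals: assumption",
      "all synthetic-data generative distributions: assumption"))
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))
  invisible(out)
}

#' Render a human-readable report
#'
#' Formats the univariable and structural-model tables; estimates whose 95%
#' CI excludes 0 are marked significant (`*`), the significance rule used
#' throughout.
#'
#' @param outputs result of [run_pipeline()], or a directory of stage CSVs.
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(outputs) {
  if (is.character(outputs)) {
    outputs <- list(
      assoc = list(table = utils::read.csv(file.path(outputs, "assoc_results.csv"))),
      sem = list(table = utils::read.csv(file.path(outputs, "sem_results.csv"))))
  }
  fmt_row <- function(label, b, lo, hi, sig) {
    sprintf("  %-28s %s%6.2f [%5.2f, %5.2f]%s", label,
            if (isTRUE(sig)) "**" else "  ", b, lo, hi,
            if (isTRUE(sig)) "**" else "")
  }
  lines <- c("Univariable associations (beta [95% CI]; ** = 0 outside CI)")
  at <- outputs$assoc$table
  if (!is.null(at) && nrow(at)) {
    for (i in seq_len(nrow(at))) {
      if (is.na(at$beta[i])) next
      lines <- c(lines, fmt_row(paste(at$predictor[i], "->", at$outcome[i]),
                                at$beta[i], at$ci_lower[i], at$ci_upper[i],
                                at$significant[i]))
    }
  } else lines <- c(lines, "  (no results)")
  lines <- c(lines, "", "Structural model standardized estimates")
  st <- outputs$sem$table
  if (!is.null(st) && nrow(st)) {
    for (i in seq_len(nrow(st))) {
      lines <- c(lines, fmt_row(paste0(st$parameter[i], " (", st$outcome[i], ")"),
                                st$est_std[i], st$ci_lower[i], st$ci_upper[i],
                                st$significant[i]))
    }
  } else lines <- c(lines, "  (no results)")
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `score`, `risk`, `resist`, `assoc`, `sem`, `all`.
#' Flags: `--config <yaml>`, `--seed <int>`, `--outdir <dir>`,
#' `--log-level <info|quiet>`.  Example:
#' `Rscript -e 'alcres::cli_main()' all --seed 7 --outdir out/`
#'
#' @param args character vector (defaults to the command line).
#' @return exit status 0 invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  verbs <- c("simulate", "score", "risk", "resist", "assoc", "sem", "all")
  if (length(args) == 0L || !args[1] %in% verbs)
    stop("usage: <verb> [--config f.yaml] [--seed n] [--outdir d] [--log-level l]\n",
         "  verbs: ", paste(verbs, collapse = ", "))
  verb <- args[1]
  get_flag <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else NULL
  }
  config <- if (!is.null(get_flag("--config")))
    yaml::read_yaml(get_flag("--config")) else default_config()
  if (!is.null(get_flag("--seed"))) config$seed <- as.integer(get_flag("--seed"))
  if (!is.null(get_flag("--outdir"))) config$outdir <- get_flag("--outdir")
  if (!is.null(get_flag("--log-level")))
    options(alcres.log_level = get_flag("--log-level"))
  stages <- if (verb == "all") c("simulate", "score", "risk", "resist",
                                 "assoc", "sem")
            else switch(verb,
                        simulate = "simulate",
                        score = c("simulate", "score"),
                        risk = c("simulate", "score", "risk"),
                        resist = c("simulate", "score", "risk", "resist"),
                        assoc = c("simulate", "score", "risk", "resist", "assoc"),
                        sem = c("simulate", "score", "risk", "resist", "assoc", "sem"))
  out <- run_pipeline(config, stages = stages)
  if (all(c("assoc", "sem") %in% stages) && !is.null(out$sem)) make_report(out)
  invisible(0L)
}
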
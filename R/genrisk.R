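# Genetic-risk indices: family history density, polygenic-score
# standardization, and the high-genetic-risk subsetting rule.

FHD_WEIGHTS <- c(`1` = 0.5, `2` = 0.25)

#' Family history density
#'
#' Relatedness-weighted aggregate of log-transformed maximum AUD symptom
#' counts over first- and second-degree relatives:
#' `sum(w(degree) * log(1 + symptoms))`, with `w(1) = 0.5`, `w(2) = 0.25`.
#' The default form divides by the total weight of assessed relatives
#' (a weighted mean); `form = "weighted_sum"` returns the raw weighted sum.
#'
#' @param degree integer vector of degrees of relatedness (1 or 2).
#' @param symptoms non-negative integer vector of maximum AUD symptom counts.
#' @param form `"weighted_mean"` (default) or `"weighted_sum"`.
#' @param log_base base of the log transform (default natural).
#' @return scalar density (0 when no relatives).
#' @export
family_history_density <- function(degree, symptoms,
                                   form = c("weighted_mean", "weighted_sum"),
                                   log_base = exp(1)) {
  form <- match.arg(form)
  if (length(degree) == 0L) return(0)
  if (any(!degree %in% c(1L, 2L))) stop("unknown degree of relatedness: ",
                                        paste(setdiff(degree, 1:2), collapse = ", "))
  if (any(symptoms < 0)) stop("symptom counts must be non-negative")
  w <- FHD_WEIGHTS[as.character(degree)]
  num <- sum(w * log(1 + symptoms, base = log_base))
  if (form == "weighted_sum") num else num / sum(w)
}

#' Top-quartile flag
#'
#' Flags values at or above the sample 75th percentile (linear-interpolation
#' quantile; ties at the cut are included).  Missing values stay missing.
#'
#' @param x numeric vector (>= 4 non-missing values required).
#' @return logical vector.
#' @export
top_quartile_flag <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) stop("all values missing; cannot define a top quartile")
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  cut <- stats::quantile(x[ok], 0.75, type = 7, names = FALSE)
  out <- rep(NA, length(x))
  out[ok] <- x[ok] >= cut
  out
}

#' Compute genetic-risk indices for a cohort
#'
#' Family history density per family (shared by its subjects), the polygenic
#' score standardized within ancestry group (to avoid population
#' stratification) and then pooled, and the high-genetic-risk flag:
#' non-zero family history density OR top quartile of the standardized
#' polygenic score.  Subjects with a missing polygenic score are assessed on
#' the family-history criterion only.
#'
#' @param subjects subject data.frame with `subject_id`, `family_id`, `prs`,
#'   `ancestry_group`.
#' @param relatives relatives data.frame with `family_id`, `degree`,
#'   `aud_max_symptoms`.
#' @param fhd_form,log_base passed to [family_history_density()].
#' @return data.frame: `subject_id`, `fhd`, `prs_z`, `high_risk`.
#' @export
compute_genetic_risk <- function(subjects, relatives,
                                 fhd_form = "weighted_mean",
                                 log_base = exp(1)) {
  fam_fhd <- vapply(split(relatives, relatives$family_id), function(r)
    family_history_density(r$degree, r$aud_max_symptoms,
                           form = fhd_form, log_base = log_base), numeric(1))
  fhd <- fam_fhd[as.character(subjects$family_id)]
  fhd[is.na(fhd)] <- 0                       # families with no assessed relatives
  prs_z <- rep(NA_real_, nrow(subjects))
  for (g in unique(subjects$ancestry_group)) {
    i <- subjects$ancestry_group == g
    v <- subjects$prs[i]
    prs_z[i] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  topq <- top_quartile_flag(prs_z)
  high_risk <- fhd > 0 | (!is.na(topq) & topq)
  data.frame(subject_id = subjects$subject_id, fhd = unname(fhd),
             prs_z = prs_z, high_risk = high_risk, stringsAsFactors = FALSE)
}
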
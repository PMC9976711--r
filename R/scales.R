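# Scoring rules for the parenting, monitoring and follow-up instruments.
#
# bonding:       12 items, 1-4, summed (range 12-48)
# closeness:     2 items on different response formats (4-point, 3-point);
#                each item standardized in the analysis sample, then averaged
# communication: 3 yes/no items coded 0/1, summed (0-3)
# involvement:   6 yes/no items coded 0/1, summed (0-6)
# monitoring:    3 items, 1-4 reverse keyed (1 = always); reverse coded
#                (1<->4, 2<->3) then summed (3-12)

SCALE_DEFS <- list(
  bonding       = list(n_items = 12L, lo = 1, hi = 4, type = "sum"),
  closeness     = list(n_items = 2L,  lo = c(1, 1), hi = c(4, 3), type = "std_mean"),
  communication = list(n_items = 3L,  lo = 0, hi = 1, type = "sum"),
  involvement   = list(n_items = 6L,  lo = 0, hi = 1, type = "sum"),
  monitoring    = list(n_items = 3L,  lo = 1, hi = 4, type = "reverse_sum")
)

#' Score a social-relationship scale
#'
#' Applies the instrument's scoring rule to an item-response matrix.  Sum
#' scales require all items answered (otherwise the score is missing);
#' closeness standardizes each item using the supplied (or in-sample) mean
#' and SD before averaging over the answered items.
#'
#' @param items numeric matrix or data.frame, subjects x items (a vector is
#'   treated as a single subject).
#' @param scale_name one of `"bonding"`, `"closeness"`, `"communication"`,
#'   `"involvement"`, `"monitoring"`.
#' @param item_stats optional list with `mean` and `sd` vectors used to
#'   standardize closeness items (defaults to the supplied sample's moments).
#' @return data.frame with `value` and `n_items_answered`.
#' @export
score_scale <- function(items, scale_name, item_stats = NULL) {
  def <- SCALE_DEFS[[scale_name]]
  if (is.null(def)) stop("unknown scale: ", scale_name)
  if (is.null(dim(items))) items <- matrix(items, nrow = 1L)
  items <- as.matrix(items)
  if (ncol(items) != def$n_items)
    stop(scale_name, " expects ", def$n_items, " items, got ", ncol(items))
  lo <- rep(def$lo, length.out = def$n_items)
  hi <- rep(def$hi, length.out = def$n_items)
  for (j in seq_len(ncol(items))) {
    bad <- which(!is.na(items[, j]) & (items[, j] < lo[j] | items[, j] > hi[j]))
    if (length(bad))
      stop(scale_name, " item ", j, ": response out of range [", lo[j], ",",
           hi[j], "] for row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  n_ans <- rowSums(!is.na(items))
  value <- switch(def$type,
    sum = {
      v <- rowSums(items)            # NA unless all items answered
      v
    },
    reverse_sum = rowSums((lo + hi) - items),
    std_mean = {
      if (is.null(item_stats)) {
        item_stats <- list(mean = colMeans(items, na.rm = TRUE),
                           sd = apply(items, 2L, stats::sd, na.rm = TRUE))
      }
      z <- sweep(sweep(items, 2L, item_stats$mean), 2L,
                 pmax(item_stats$sd, 1e-12), `/`)
      rowMeans(z, na.rm = TRUE)
    })
  value[n_ans == 0L] <- NA_real_
  data.frame(value = value, n_items_answered = n_ans)
}

#' Score all instruments for a subject table
#'
#' Maps the generator's item columns to the five instruments for each parent
#' and returns one row per subject with the scored scales.  Closeness
#' standardization uses the full analysis sample.
#'
#' @param subjects subject data.frame with item columns (`fb_*`, `fcl_*`,
#'   `fcm_*`, `fin_*`, `mb_*`, `mcl_*`, `mcm_*`, `min_*`, `mon_*`).
#' @return data.frame: `subject_id`, `fc_bond`, `fc_close`, `fc_comm`,
#'   `fc_inv`, `mc_bond`, `mc_close`, `mc_comm`, `mc_inv`, `monitoring`.
#' @export
score_subjects <- function(subjects) {
  g <- function(prefix, k) as.matrix(subjects[paste0(prefix, "_", seq_len(k))])
  data.frame(
    subject_id = subjects$subject_id,
    fc_bond  = score_scale(g("fb", 12L), "bonding")$value,
    fc_close = score_scale(cbind(subjects$fcl_1, subjects$fcl_2), "closeness")$value,
    fc_comm  = score_scale(g("fcm", 3L), "communication")$value,
    fc_inv   = score_scale(g("fin", 6L), "involvement")$value,
    mc_bond  = score_scale(g("mb", 12L), "bonding")$value,
    mc_close = score_scale(cbind(subjects$mcl_1, subjects$mcl_2), "closeness")$value,
    mc_comm  = score_scale(g("mcm", 3L), "communication")$value,
    mc_inv   = score_scale(g("min", 6L), "involvement")$value,
    monitoring = score_scale(g("mon", 3L), "monitoring")$value,
    stringsAsFactors = FALSE
  )
}
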
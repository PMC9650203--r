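# Streamline weights: scanner-batch harmonization and interhemispheric
# asymmetry ratios.

#' Harmonize streamline weights across scanner batches
#'
#' Location-scale batch adjustment: within each feature (tract x
#' hemisphere label), every batch is standardized to the feature's pooled
#' mean and standard deviation across batches. Removes additive and
#' multiplicative batch offsets while preserving each subject's rank
#' within its batch. Small weights may become negative after
#' harmonization; they are deliberately not clamped, since downstream
#' asymmetry ratios and tree cutoffs can legitimately be negative.
#'
#' @param streams Long-format data frame with columns `subject_id`,
#'   `group`, `tract`, `hemisphere`, `weight`, `batch` (see
#'   [streamline_table()]). Raw weights must be nonnegative.
#' @return The same data frame with `weight` replaced by harmonized
#'   values.
#' @export
harmonize_batches <- function(streams) {
  need <- c("subject_id", "tract", "hemisphere", "weight", "batch")
  if (!all(need %in% names(streams))) {
    stop_mw("invalid_argument", sprintf(
      "streamline table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(streams$weight < 0)) {
    stop_mw("invalid_input", "raw streamline weights must be nonnegative")
  }
  out <- streams
  feat <- interaction(streams$tract, streams$hemisphere, drop = TRUE)
  for (f in levels(feat)) {
    idx <- which(feat == f)
    w <- streams$weight[idx]
    b <- streams$batch[idx]
    if (length(unique(b)) < 2L) next  # single batch: nothing to harmonize
    mp <- mean(w); sp <- sd(w)
    for (bb in unique(b)) {
      i <- idx[b == bb]
      if (length(i) < 2L) {
        stop_mw("degenerate_batch", sprintf(
          "batch '%s' has fewer than 2 records for feature '%s'", bb, f))
      }
      sb <- sd(streams$weight[i])
      if (sb == 0) {
        stop_mw("degenerate_batch", sprintf(
          "batch '%s' has zero variance for feature '%s'", bb, f))
      }
      z <- (streams$weight[i] - mean(streams$weight[i])) / sb
      out$weight[i] <- z * sp + mp
    }
  }
  out
}

#' Interhemispheric asymmetry ratio
#'
#' Ratio of streamline weights between hemispheres: lesioned over
#' non-lesioned for stroke survivors, right over left for healthy
#' controls. A value of 1 indicates equal streamline weight in both
#' hemispheres; values below 1 indicate fewer streamlines on the
#' lesioned (or right) side.
#'
#' @param numerator,denominator Streamline weights (lesioned/right and
#'   nonlesioned/left respectively).
#' @return The ratio.
#' @export
asymmetry_ratio <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    stop_mw("undefined_ratio",
            "zero denominator: asymmetry ratio undefined")
  }
  numerator / denominator
}

#' Per-subject asymmetry ratios for CST and CRP
#'
#' Computes the interhemispheric asymmetry ratio per subject and tract
#' from a long-format streamline table (typically after
#' [harmonize_batches()]). Subjects with a zero denominator are flagged
#' (`excluded = TRUE`, ratio `NA`) with a warning and should be dropped
#' from correlations.
#'
#' @param streams Long-format streamline table (see
#'   [streamline_table()]).
#' @return Data frame with columns `subject_id`, `group`, `asymm_cst`,
#'   `asymm_crp`, `excluded`.
#' @export
asymmetry_ratios <- function(streams) {
  num_lab <- c("lesioned", "right")
  den_lab <- c("nonlesioned", "left")
  ids <- unique(streams$subject_id)
  one <- function(id, tract) {
    s <- streams[streams$subject_id == id & streams$tract == tract, ]
    num <- s$weight[s$hemisphere %in% num_lab]
    den <- s$weight[s$hemisphere %in% den_lab]
    if (length(num) != 1L || length(den) != 1L) {
      stop_mw("invalid_argument", sprintf(
        "subject %s, tract %s: expected one weight per hemisphere", id, tract))
    }
    if (den == 0) return(NA_real_)
    num / den
  }
  res <- data.frame(
    subject_id = ids,
    group = streams$group[match(ids, streams$subject_id)],
    asymm_cst = vapply(ids, one, numeric(1), tract = "cst"),
    asymm_crp = vapply(ids, one, numeric(1), tract = "crp"),
    stringsAsFactors = FALSE)
  res$excluded <- !is.finite(res$asymm_cst) | !is.finite(res$asymm_crp)
  if (any(res$excluded)) {
    warning(sprintf(
      "%d subject(s) with zero-denominator asymmetry flagged for exclusion",
      sum(res$excluded)))
  }
  rownames(res) <- NULL
  res
}
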
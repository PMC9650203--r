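# End-to-end per-subject processing and cohort table assembly.

#' Run the module pipeline on one recording
#'
#' Chains the per-subject stages: envelope extraction, cycle segmentation
#' and averaging, six-bin summary, amplitude normalization by the highest
#' bin mean, and module-count selection by NNMF with the VAF rule.
#'
#' @param emg Raw [emg_recording()].
#' @param events [gait_events()] for the recording (from the generator or
#'   [detect_gait_events()]).
#' @param seed Seed for the NNMF restarts.
#' @param restarts NNMF restarts per candidate module count.
#' @param ... Passed to [select_module_number()].
#' @return List with `envelope` (averaged cycles), `bins`, `normalized`
#'   (NNMF input), `decision` ([select_module_number()] result).
#' @export
#' @examples
#' cfg <- subject_config(true_n_modules = 2, n_cycles = 20, seed = 3)
#' sub <- generate_emg(cfg, make_truth_templates(2, seed = 3))
#' res <- module_analysis(sub$emg, sub$events, seed = 3, restarts = 5)
#' res$decision
module_analysis <- function(emg, events, seed = 1, restarts = 50, ...) {
  env <- emg_envelope(emg)
  cyc <- segment_and_normalize(env, events)
  bins <- bin_average(cyc, events)
  norm <- normalize_amplitude(cyc, bins)
  decision <- select_module_number(norm$matrix, bins$bin_edges_pct,
                                   seed = seed, restarts = restarts, ...)
  list(envelope = cyc, bins = bins, normalized = norm, decision = decision)
}

#' Assemble the per-subject analysis table for a cohort
#'
#' Joins, per subject: module count and pattern class (ground truth by
#' default, or recomputed from EMG when available and `measured = TRUE`),
#' harmonized CST/CRP asymmetry ratios, clinical scores, and propulsion /
#' step-ratio metrics (measured from GRF when present, otherwise the
#' generative targets). This is the unit of all cohort statistics.
#'
#' @param cohort An `mw_cohort` from [generate_cohort()].
#' @param harmonize Apply [harmonize_batches()] before computing
#'   asymmetry ratios (default TRUE, the conventional order).
#' @param measured Recompute module counts from EMG and propulsion from
#'   GRF where those signals exist (slower); otherwise use the retained
#'   ground truth.
#' @param seed Seed for NNMF when `measured = TRUE`.
#' @param restarts NNMF restarts when `measured = TRUE`.
#' @return Data frame with one row per subject.
#' @export
build_subject_table <- function(cohort, harmonize = TRUE, measured = FALSE,
                                seed = 1, restarts = 50) {
  stopifnot(inherits(cohort, "mw_cohort"))
  streams <- streamline_table(cohort)
  if (harmonize) streams <- harmonize_batches(streams)
  asym <- asymmetry_ratios(streams)
  tab <- cohort$table
  out <- merge(tab, asym[, c("subject_id", "asymm_cst", "asymm_crp",
                             "excluded")], by = "subject_id", sort = FALSE)
  out$k_selected <- out$true_k
  out$pp <- out$pp_true
  out$psr <- out$psr_true
  if (measured) {
    for (i in seq_along(cohort$subjects)) {
      s <- cohort$subjects[[i]]
      row <- which(out$subject_id == s$subject_id)
      if (!is.null(s$emg)) {
        res <- module_analysis(s$emg, s$events, seed = seed,
                               restarts = restarts)
        out$k_selected[row] <- res$decision$k_selected
      }
      if (!is.null(s$grf)) {
        pm <- propulsion_metrics(s$grf, s$step_lengths)
        out$pp[row] <- pm$pp
        out$psr[row] <- pm$psr
      }
    }
  }
  out$pattern_class <- ifelse(is.na(out$k_selected), NA_character_,
                              ifelse(out$k_selected <= 2, "two_modules",
                                     "more_than_two"))
  out$pp_deviation <- ifelse(is.na(out$pp), NA_real_, abs(out$pp - 0.5))
  out$psr_deviation <- ifelse(is.na(out$psr), NA_real_, abs(out$psr - 0.5))
  out
}
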
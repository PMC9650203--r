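# Synthetic cohorts. The "paper-like" scenario reproduces the group
# structure of a hemiparetic treadmill cohort: three stroke subgroups
# defined by their eventual classification-tree fate plus a small set of
# multi-module subjects with low asymmetry, and healthy controls with
# near-symmetric streamline counts. Subgroup streamline means follow the
# printed post-hoc group means (ipsilesional CST 4.1/5.5/0.5, ipsilesional
# CRP 8.6/10.7/3.3, contralesional CRP 13.2/11.5/16.8); contralesional CST
# means are chosen so CST asymmetry separates the severe subgroup less
# cleanly than CRP asymmetry.

cohort_subgroups_ <- function() {
  data.frame(
    subgroup = c("A", "B", "C", "X"),
    share = c(28, 6, 7, 2) / 43,
    cst_ipsi = c(4.1, 5.5, 0.5, 1.0),
    cst_contra = c(6.0, 5.0, 4.0, 4.5),
    crp_ipsi = c(8.6, 10.7, 3.3, 4.0),
    crp_contra = c(13.2, 11.5, 16.8, 15.0),
    two_module = c(FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# largest-remainder apportionment of n subjects over subgroup shares
apportion_ <- function(n, shares) {
  raw <- n * shares
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# scanner-batch effect applied to raw counts (removed by harmonization)
batch_effect_ <- function(w, batch) {
  ifelse(batch == "B", w * 1.15 + 1.5, w)
}

#' Generate a synthetic cohort
#'
#' Draws `n_stroke` stroke survivors and `n_healthy` controls under the
#' `"paper-like"` scenario: stroke subjects fall into subgroups with
#' Poisson streamline counts around fixed per-subgroup means, two-module
#' subjects carry low CRP and/or CST asymmetry and impaired clinical
#' scores, multi-module subjects higher ratios, and healthy controls
#' near-symmetric counts. Clinical scores and propulsion targets are
#' linear in the subject's raw asymmetry ratios plus Gaussian noise (see
#' [default_clinical_coupling()]). Ground-truth labels (subgroup, true
#' module count, generative parameters) are retained on every subject.
#'
#' @param n_stroke,n_healthy Numbers of stroke and healthy subjects (>= 0).
#' @param scenario Scenario label; only `"paper-like"` is defined.
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @param include_grf Generate GRF traces and step lengths per stroke
#'   subject (needed for measured propulsion metrics).
#' @param include_emg Generate raw EMG per stroke subject (needed to run
#'   the full module pipeline; slower).
#' @return An object of class `mw_cohort`: a list with `subjects` (list of
#'   per-subject records) and `table` (one-row-per-subject data frame of
#'   generative ground truth).
#' @export
#' @examples
#' coh <- generate_cohort(n_stroke = 10, n_healthy = 4, seed = 1)
#' head(coh$table)
generate_cohort <- function(n_stroke, n_healthy, scenario = "paper-like",
                            seed = 1, include_grf = FALSE,
                            include_emg = FALSE) {
  if (!identical(scenario, "paper-like")) {
    stop_mw("invalid_argument",
            sprintf("unknown scenario '%s' (only \"paper-like\" is defined)",
                    scenario))
  }
  if (n_stroke < 0 || n_healthy < 0) {
    stop_mw("invalid_argument", "`n_stroke` and `n_healthy` must be >= 0")
  }
  sg <- cohort_subgroups_()
  cc <- default_clinical_coupling()
  with_seed_(seed, {
    counts <- apportion_(n_stroke, sg$share)
    subgroup <- rep(sg$subgroup, counts)
    subseeds <- sample.int(.Machine$integer.max - 1L,
                           n_stroke + n_healthy)
    subjects <- vector("list", n_stroke + n_healthy)
    rows <- vector("list", n_stroke + n_healthy)
    for (i in seq_len(n_stroke)) {
      g <- sg[sg$subgroup == subgroup[i], ]
      k <- if (g$two_module) 2L else sample(c(3L, 4L), 1L)
      batch <- sample(c("A", "B"), 1L)
      raw <- c(cst_lesioned = rpois(1, g$cst_ipsi),
               cst_nonlesioned = rpois(1, g$cst_contra),
               crp_lesioned = rpois(1, g$crp_ipsi),
               crp_nonlesioned = rpois(1, g$crp_contra))
      a_cst <- raw[["cst_lesioned"]] / max(raw[["cst_nonlesioned"]], 1)
      a_crp <- raw[["crp_lesioned"]] / max(raw[["crp_nonlesioned"]], 1)
      fma <- clip_(cc$fma_intercept + cc$fma_crp * a_crp +
                     cc$fma_cst * a_cst + rnorm(1, 0, cc$fma_sd), 0, 34)
      ppdev <- clip_(cc$ppdev_intercept + cc$ppdev_crp * a_crp +
                       cc$ppdev_cst * a_cst + rnorm(1, 0, cc$ppdev_sd),
                     0.01, 0.45)
      clin <- list(
        fma_le = fma,
        fma_le_synergy = clip_(round(fma * 22 / 34), 0, 22),
        dgi = clip_(cc$dgi_intercept + cc$dgi_crp * a_crp +
                      rnorm(1, 0, cc$dgi_sd), 0, 24),
        smwt_m = pmax(cc$smwt_intercept + cc$smwt_crp * a_crp +
                        rnorm(1, 0, cc$smwt_sd), 10),
        bbs = clip_(cc$bbs_intercept + cc$bbs_crp * a_crp +
                      rnorm(1, 0, cc$bbs_sd), 0, 56),
        ss_speed_m_s = pmax(cc$speed_intercept + cc$speed_crp * a_crp +
                              rnorm(1, 0, cc$speed_sd), 0.1))
      cfg <- subject_config(
        true_n_modules = k, pp_true = 0.5 - ppdev,
        psr_true = clip_(rnorm(1, 0.5, 0.04), 0.35, 0.65),
        cst_lesioned = raw[["cst_lesioned"]],
        cst_nonlesioned = raw[["cst_nonlesioned"]],
        crp_lesioned = raw[["crp_lesioned"]],
        crp_nonlesioned = raw[["crp_nonlesioned"]],
        scanner_batch = batch, seed = subseeds[i])
      truth <- make_truth_templates(k, seed = subseeds[i])
      subj <- list(subject_id = sprintf("S%03d", i), group = "stroke",
                   subgroup = subgroup[i], config = cfg, truth = truth,
                   clinical = clin, raw_streamlines = raw, batch = batch)
      if (include_grf) {
        g2 <- generate_grf(cfg)
        subj$grf <- g2$grf
        subj$step_lengths <- g2$step_lengths
      }
      if (include_emg) {
        e <- generate_emg(cfg, truth)
        subj$emg <- e$emg
        subj$events <- e$events
      }
      subjects[[i]] <- subj
      rows[[i]] <- data.frame(
        subject_id = subj$subject_id, group = "stroke",
        subgroup = subgroup[i], true_k = k, scanner_batch = batch,
        cst_lesioned = batch_effect_(raw[["cst_lesioned"]], batch),
        cst_nonlesioned = batch_effect_(raw[["cst_nonlesioned"]], batch),
        crp_lesioned = batch_effect_(raw[["crp_lesioned"]], batch),
        crp_nonlesioned = batch_effect_(raw[["crp_nonlesioned"]], batch),
        crp_contra_raw = raw[["crp_nonlesioned"]],
        pp_true = cfg$pp_true, psr_true = cfg$psr_true,
        fma_le = clin$fma_le, fma_le_synergy = clin$fma_le_synergy,
        dgi = clin$dgi, smwt_m = clin$smwt_m, bbs = clin$bbs,
        ss_speed_m_s = clin$ss_speed_m_s,
        stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_healthy)) {
      i <- n_stroke + j
      batch <- sample(c("A", "B"), 1L)
      raw <- c(cst_right = rpois(1, 5.0), cst_left = rpois(1, 5.2),
               crp_right = rpois(1, 14.9), crp_left = rpois(1, 16.4))
      subj <- list(subject_id = sprintf("H%03d", j), group = "healthy",
                   subgroup = NA_character_, raw_streamlines = raw,
                   batch = batch, seed = subseeds[i])
      subjects[[i]] <- subj
      rows[[i]] <- data.frame(
        subject_id = subj$subject_id, group = "healthy",
        subgroup = NA_character_, true_k = NA_integer_,
        scanner_batch = batch,
        cst_lesioned = batch_effect_(raw[["cst_right"]], batch),
        cst_nonlesioned = batch_effect_(raw[["cst_left"]], batch),
        crp_lesioned = batch_effect_(raw[["crp_right"]], batch),
        crp_nonlesioned = batch_effect_(raw[["crp_left"]], batch),
        crp_contra_raw = raw[["crp_left"]],
        pp_true = NA_real_, psr_true = NA_real_,
        fma_le = NA_real_, fma_le_synergy = NA_real_, dgi = NA_real_,
        smwt_m = NA_real_, bbs = NA_real_, ss_speed_m_s = NA_real_,
        stringsAsFactors = FALSE)
    }
    structure(list(subjects = subjects,
                   table = do.call(rbind, rows),
                   scenario = scenario, seed = seed),
              class = "mw_cohort")
  })
}

#' @export
print.mw_cohort <- function(x, ...) {
  tab <- table(x$table$group)
  cat(sprintf("<mw_cohort> scenario '%s': %s\n", x$scenario,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' Long-format streamline table for a cohort
#'
#' Reshapes the cohort's streamline weights into one row per subject,
#' tract and hemisphere, the layout consumed by [harmonize_batches()] and
#' [asymmetry_ratios()]. For stroke subjects the hemisphere labels are
#' `lesioned`/`nonlesioned`; for healthy controls `right`/`left`.
#'
#' @param cohort An `mw_cohort`.
#' @return Data frame with columns `subject_id`, `group`, `tract`,
#'   `hemisphere`, `weight`, `batch`.
#' @export
streamline_table <- function(cohort) {
  stopifnot(inherits(cohort, "mw_cohort"))
  tab <- cohort$table
  stroke <- tab$group == "stroke"
  hemi_num <- ifelse(stroke, "lesioned", "right")
  hemi_den <- ifelse(stroke, "nonlesioned", "left")
  out <- rbind(
    data.frame(subject_id = tab$subject_id, group = tab$group,
               tract = "cst", hemisphere = hemi_num,
               weight = tab$cst_lesioned, batch = tab$scanner_batch),
    data.frame(subject_id = tab$subject_id, group = tab$group,
               tract = "cst", hemisphere = hemi_den,
               weight = tab$cst_nonlesioned, batch = tab$scanner_batch),
    data.frame(subject_id = tab$subject_id, group = tab$group,
               tract = "crp", hemisphere = hemi_num,
               weight = tab$crp_lesioned, batch = tab$scanner_batch),
    data.frame(subject_id = tab$subject_id, group = tab$group,
               tract = "crp", hemisphere = hemi_den,
               weight = tab$crp_nonlesioned, batch = tab$scanner_batch))
  rownames(out) <- NULL
  out
}
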
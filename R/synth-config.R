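#' Configuration for one synthetic subject
#'
#' Collects every knob of the single-subject generator: true module count,
#' envelope noise, gait timing, target propulsion and step-length symmetry,
#' streamline weights, scanner batch and the couplings from pathway
#' asymmetry to clinical scores.
#'
#' @param true_n_modules True number of modules (2, 3 or 4).
#' @param noise_sd Envelope noise scale as a fraction of each channel's
#'   signal RMS (>= 0).
#' @param n_cycles Number of gait cycles to simulate (>= 20; module
#'   analysis conventionally requires at least 20 cycles).
#' @param cycle_duration_s Nominal gait-cycle duration in seconds.
#' @param cycle_jitter_sd S.d. of the lognormal multiplicative jitter on
#'   cycle duration (default 0.03).
#' @param fs_hz Sampling rate of EMG and GRF in Hz (default 2000).
#' @param pp_true Target paretic propulsion in `[0, 1]` (0.5 = symmetric).
#' @param psr_true Target paretic step ratio in `[0, 1]` (0.5 = symmetric).
#' @param grf_noise_sd S.d. of additive measurement noise on GRF channels,
#'   in newtons.
#' @param cst_lesioned,cst_nonlesioned,crp_lesioned,crp_nonlesioned
#'   Nonnegative streamline weights for the corticospinal tract and
#'   corticoreticular pathway per hemisphere.
#' @param scanner_batch Scanner batch label.
#' @param clinical_coupling Named list of effect sizes linking CRP/CST
#'   asymmetry to clinical scores; see [default_clinical_coupling()].
#' @param seed Integer seed for all randomness of this subject.
#' @return An object of class `subject_config`.
#' @export
subject_config <- function(true_n_modules = 2,
                           noise_sd = 0.05,
                           n_cycles = 25,
                           cycle_duration_s = 1.1,
                           cycle_jitter_sd = 0.03,
                           fs_hz = 2000,
                           pp_true = 0.4,
                           psr_true = 0.5,
                           grf_noise_sd = 0.5,
                           cst_lesioned = 4, cst_nonlesioned = 6,
                           crp_lesioned = 8, crp_nonlesioned = 13,
                           scanner_batch = "A",
                           clinical_coupling = default_clinical_coupling(),
                           seed = 1) {
  if (!(true_n_modules %in% c(2, 3, 4))) {
    stop_mw("invalid_argument", "`true_n_modules` must be 2, 3 or 4")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_mw("invalid_argument", "`noise_sd` must be >= 0")
  }
  if (!is.numeric(n_cycles) || n_cycles < 20) {
    stop_mw("invalid_argument",
            "`n_cycles` must be >= 20 (module analysis needs at least 20 gait cycles)")
  }
  if (!is.numeric(fs_hz) || fs_hz <= 0) {
    stop_mw("invalid_argument", "`fs_hz` must be > 0")
  }
  check_scalar01(pp_true, "pp_true")
  check_scalar01(psr_true, "psr_true")
  for (nm in c("cst_lesioned", "cst_nonlesioned", "crp_lesioned",
               "crp_nonlesioned")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) {
      stop_mw("invalid_argument", sprintf("`%s` must be >= 0", nm))
    }
  }
  structure(list(
    true_n_modules = as.integer(true_n_modules), noise_sd = noise_sd,
    n_cycles = as.integer(n_cycles), cycle_duration_s = cycle_duration_s,
    cycle_jitter_sd = cycle_jitter_sd, fs_hz = fs_hz,
    pp_true = pp_true, psr_true = psr_true, grf_noise_sd = grf_noise_sd,
    cst_lesioned = cst_lesioned, cst_nonlesioned = cst_nonlesioned,
    crp_lesioned = crp_lesioned, crp_nonlesioned = crp_nonlesioned,
    scanner_batch = scanner_batch, clinical_coupling = clinical_coupling,
    seed = as.integer(seed)), class = "subject_config")
}

#' Default clinical-score couplings
#'
#' Linear effect sizes linking the (raw) interhemispheric asymmetry ratios
#' to clinical scores, plus the residual noise s.d. of each score. Signs
#' follow the observed correlation directions in hemiparetic cohorts:
#' larger (more symmetric) CRP/CST ratios go with better FMA-LE, DGI,
#' six-minute-walk distance, Berg balance, self-selected speed, and with
#' smaller deviation of paretic propulsion from symmetry. Magnitudes give
#' moderate-to-strong correlations (|rho| roughly 0.5-0.65) at cohort
#' sizes around 40.
#'
#' @return Named list of coefficients.
#' @export
default_clinical_coupling <- function() {
  list(
    fma_intercept = 19, fma_crp = 10, fma_cst = 6, fma_sd = 4,
    dgi_intercept = 14, dgi_crp = 8, dgi_sd = 2.2,
    smwt_intercept = 150, smwt_crp = 180, smwt_sd = 60,
    bbs_intercept = 40, bbs_crp = 14, bbs_sd = 4,
    speed_intercept = 0.45, speed_crp = 0.45, speed_sd = 0.12,
    ppdev_intercept = 0.28, ppdev_crp = -0.18, ppdev_cst = -0.10,
    ppdev_sd = 0.05)
}
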
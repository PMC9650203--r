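# Synthetic ground reaction forces. Vertical force per belt is a half-sine
# stance lobe (clearing the event-detection threshold quickly); the
# anterior-posterior channel has a negative braking lobe in early stance
# and a positive propulsive half-sine lobe in late stance. Both legs share
# the lobe shape and duration, so the ratio of positive anterior impulses
# equals `pp_true` analytically. The generator draws the same cycle timing
# as the EMG generator for the same seed.

half_sine_lobe_ <- function(t, t0, t1, amplitude) {
  inside <- t >= t0 & t < t1
  y <- numeric(length(t))
  y[inside] <- amplitude * sin(pi * (t[inside] - t0) / (t1 - t0))
  y
}

#' Generate a synthetic GRF trace and step lengths
#'
#' Builds per-belt vertical and anterior-posterior forces whose positive
#' anterior impulses satisfy paretic / (paretic + nonparetic) = `pp_true`
#' by construction (identical half-sine propulsive lobes scaled by
#' `2 * pp_true` and `2 * (1 - pp_true)`), and per-step lengths whose
#' paretic step ratio equals `psr_true` exactly (both legs share each
#' stride's jitter factor).
#'
#' @param config A [subject_config()]; `pp_true` and `psr_true` must lie
#'   strictly inside (0, 1) unless `allow_degenerate = TRUE`, in which
#'   case a zero-impulse leg is produced.
#' @param allow_degenerate Permit `pp_true` of exactly 0 or 1.
#' @param stride_m Nominal stride length in metres.
#' @return List with elements `grf` ([grf_trace()]) and `step_lengths`
#'   (data frame with columns `paretic`, `nonparetic` in metres).
#' @export
#' @examples
#' g <- generate_grf(subject_config(pp_true = 0.3, seed = 2))
#' paretic_propulsion(g$grf)
generate_grf <- function(config, allow_degenerate = FALSE, stride_m = 1.0) {
  stopifnot(inherits(config, "subject_config"))
  if (!allow_degenerate && (config$pp_true <= 0 || config$pp_true >= 1)) {
    stop_mw("invalid_argument",
            "`pp_true` must be in (0, 1); set `allow_degenerate = TRUE` for a zero-impulse leg")
  }
  fs <- config$fs_hz
  fr <- event_fractions_()
  with_seed_(config$seed, {
    timing <- cycle_timing_(config)
    s <- timing$starts
    d <- timing$dur
    # extend past the last nonparetic stance so both legs carry the same
    # number of complete propulsive lobes
    total <- s[length(s)] + (1 + fr[["np_toe_off"]]) * d[length(d)]
    n <- as.integer(ceiling(total * fs)) + 1L
    t <- (seq_len(n) - 1L) / fs
    body_n <- 700
    amp_base <- 160
    pv <- av <- nv <- na_ <- numeric(n)
    for (i in seq_along(s)) {
      p0 <- s[i]; p1 <- s[i] + fr[["p_toe_off"]] * d[i]
      pv <- pv + half_sine_lobe_(t, p0, p1, body_n)
      # braking then propulsion within paretic stance
      av <- av + half_sine_lobe_(t, p0 + 0.05 * (p1 - p0),
                                 p0 + 0.40 * (p1 - p0), -0.5 * amp_base)
      av <- av + half_sine_lobe_(t, p0 + 0.60 * (p1 - p0),
                                 p0 + 0.95 * (p1 - p0),
                                 amp_base * 2 * config$pp_true)
      q0 <- s[i] + fr[["np_heel_strike"]] * d[i]
      q1 <- s[i] + (1 + fr[["np_toe_off"]]) * d[i]
      nv <- nv + half_sine_lobe_(t, q0, q1, body_n)
      na_ <- na_ + half_sine_lobe_(t, q0 + 0.05 * (q1 - q0),
                                   q0 + 0.40 * (q1 - q0), -0.5 * amp_base)
      na_ <- na_ + half_sine_lobe_(t, q0 + 0.60 * (q1 - q0),
                                   q0 + 0.95 * (q1 - q0),
                                   amp_base * 2 * (1 - config$pp_true))
    }
    if (config$grf_noise_sd > 0) {
      pv <- pv + rnorm(n, 0, config$grf_noise_sd)
      av <- av + rnorm(n, 0, config$grf_noise_sd)
      nv <- nv + rnorm(n, 0, config$grf_noise_sd)
      na_ <- na_ + rnorm(n, 0, config$grf_noise_sd)
    }
    stride <- stride_m * exp(rnorm(config$n_cycles, 0, 0.02))
    steps <- data.frame(paretic = config$psr_true * stride,
                        nonparetic = (1 - config$psr_true) * stride)
    list(grf = grf_trace(paretic = list(vertical = pv, anterior = av),
                         nonparetic = list(vertical = nv, anterior = na_),
                         fs_hz = fs),
         step_lengths = steps)
  })
}
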
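# Synthetic EMG: module activations tiled across jittered gait cycles,
# mixed through the ground-truth weights, then used to amplitude-modulate
# a band-limited (20-450 Hz) Gaussian carrier. The rectified/low-passed
# envelope of the output approximates weights %*% activations up to the
# configured noise, and survives the 40 Hz high-pass of the envelope
# pipeline.

# jittered cycle start times and durations for one subject
cycle_timing_ <- function(config) {
  dur <- config$cycle_duration_s *
    exp(rnorm(config$n_cycles, 0, config$cycle_jitter_sd))
  starts <- c(0, cumsum(dur))
  list(starts = starts[-length(starts)], dur = dur,
       total = sum(dur))
}

# within-cycle event timing (fractions of the paretic cycle)
event_fractions_ <- function() {
  c(np_toe_off = 0.12, np_heel_strike = 0.50, p_toe_off = 0.62)
}

events_from_timing_ <- function(timing) {
  fr <- event_fractions_()
  s <- timing$starts
  d <- timing$dur
  np_to <- s + fr[["np_toe_off"]] * d
  gait_events(
    paretic_heel_strikes = c(s, s[length(s)] + d[length(d)]),
    paretic_toe_offs = s + fr[["p_toe_off"]] * d,
    nonparetic_heel_strikes = s + fr[["np_heel_strike"]] * d,
    # the first nonparetic toe-off precedes that leg's first heel strike
    # (its stance began before the trace); it is dropped so events interleave
    nonparetic_toe_offs = np_to[-1L])
}

#' Generate a synthetic EMG recording
#'
#' Builds raw-like surface EMG for the eight paretic-leg muscles by tiling
#' each ground-truth module activation across `n_cycles` gait cycles with
#' lognormal duration jitter, mixing the activations through the module
#' weights, adding envelope noise, and amplitude-modulating a band-limited
#' (20-450 Hz) zero-mean Gaussian carrier. Returns the gait events implied
#' by the tiling alongside the recording; everything is reproducible from
#' `config$seed`.
#'
#' @param config A [subject_config()].
#' @param truth A [make_truth_templates()] ground-truth object.
#' @return List with elements `emg` ([emg_recording()]) and `events`
#'   ([gait_events()]).
#' @export
#' @examples
#' cfg <- subject_config(true_n_modules = 2, n_cycles = 20, seed = 7)
#' tr <- make_truth_templates(2, seed = 7)
#' sub <- generate_emg(cfg, tr)
#' sub$emg
generate_emg <- function(config, truth) {
  stopifnot(inherits(config, "subject_config"), inherits(truth, "gt_modules"))
  fs <- config$fs_hz
  with_seed_(config$seed, {
    timing <- cycle_timing_(config)
    n <- as.integer(ceiling(timing$total * fs)) + 1L
    t <- (seq_len(n) - 1L) / fs
    # percent-of-cycle phase for every sample
    cyc <- findInterval(t, timing$starts)
    phase <- 100 * (t - timing$starts[cyc]) / timing$dur[cyc]
    phase <- clip_(phase, 0, 100)
    # module activations sampled at each time point
    A <- t(vapply(seq_len(truth$n_modules), function(j) {
      approx(0:100, truth$activations[j, ], xout = phase)$y
    }, numeric(n)))
    E <- truth$weights %*% A
    if (config$noise_sd > 0) {
      rms <- sqrt(rowMeans(E^2))
      E <- E + config$noise_sd * rms * matrix(rnorm(length(E)), nrow = nrow(E))
      E <- pmax(E, 0)
    }
    # band-limited Gaussian carrier, unit RMS per channel
    bp <- signal::butter(2, c(20, min(450, 0.45 * fs)) / (fs / 2),
                         type = "pass")
    pad <- 3L * as.integer(ceiling(fs / 20))
    carrier <- t(apply(matrix(rnorm(8L * n), nrow = 8L), 1L, function(x) {
      y <- filtfilt_refl_(bp, x, pad)
      y / sqrt(mean(y^2))
    }))
    raw <- E * carrier
    list(emg = emg_recording(raw, fs, truth$muscle_names, "paretic"),
         events = events_from_timing_(timing),
         envelope_truth = E)
  })
}
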
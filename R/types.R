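#' EMG recording container
#'
#' Wraps a channels-by-time matrix of surface EMG (or EMG envelopes) with
#' its sampling rate and muscle labels.
#'
#' @param samples Numeric matrix, 8 muscles x time samples, finite values.
#' @param fs_hz Sampling rate in Hz (> 0). EMG for module analysis is
#'   conventionally sampled at 2,000 Hz.
#' @param muscle_names Ordered channel labels; defaults to
#'   [modwalk_muscles()].
#' @param leg `"paretic"` or `"nonparetic"`. Module analysis uses the
#'   paretic leg only.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs_hz,
                          muscle_names = modwalk_muscles(),
                          leg = c("paretic", "nonparetic")) {
  leg <- match.arg(leg)
  samples <- as.matrix(samples)
  if (nrow(samples) != length(muscle_names)) {
    stop_mw("invalid_argument", "`samples` must have one row per muscle")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop_mw("invalid_argument", "`fs_hz` must be a positive scalar")
  }
  if (!all(is.finite(samples))) {
    stop_mw("invalid_argument", "EMG samples must be finite")
  }
  rownames(samples) <- muscle_names
  structure(
    list(samples = samples, fs_hz = fs_hz, muscle_names = muscle_names,
         leg = leg),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%s leg)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz, x$leg))
  invisible(x)
}

#' Gait event set
#'
#' Heel-strike and toe-off times for both legs. Within each leg the times
#' are strictly increasing and toe-offs interleave with heel strikes: the
#' i-th toe-off falls strictly between heel strikes i and i+1 (events
#' outside the first/last heel strike of a leg are trimmed by the
#' detector).
#'
#' @param paretic_heel_strikes,paretic_toe_offs,nonparetic_heel_strikes,nonparetic_toe_offs
#'   Numeric vectors of event times in seconds.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(paretic_heel_strikes, paretic_toe_offs,
                        nonparetic_heel_strikes, nonparetic_toe_offs) {
  ev <- list(
    paretic_heel_strikes = as.numeric(paretic_heel_strikes),
    paretic_toe_offs = as.numeric(paretic_toe_offs),
    nonparetic_heel_strikes = as.numeric(nonparetic_heel_strikes),
    nonparetic_toe_offs = as.numeric(nonparetic_toe_offs))
  for (nm in names(ev)) {
    if (length(ev[[nm]]) > 1L && any(diff(ev[[nm]]) <= 0)) {
      stop_mw("malformed_events",
              sprintf("`%s` must be strictly increasing", nm))
    }
  }
  check_leg <- function(hs, to, leg) {
    if (length(hs) == 0L) {
      if (length(to)) {
        stop_mw("malformed_events", sprintf(
          "%s leg: toe-offs present without heel strikes", leg))
      }
      return(invisible(NULL))
    }
    if (length(to) != length(hs) - 1L) {
      stop_mw("malformed_events", sprintf(
        "%s leg: expected one toe-off between successive heel strikes (%d heel strikes, %d toe-offs)",
        leg, length(hs), length(to)))
    }
    if (length(to) && (any(to <= hs[-length(hs)]) || any(to >= hs[-1L]))) {
      stop_mw("malformed_events", sprintf(
        "%s leg: each toe-off must fall between successive heel strikes", leg))
    }
  }
  check_leg(ev$paretic_heel_strikes, ev$paretic_toe_offs, "paretic")
  check_leg(ev$nonparetic_heel_strikes, ev$nonparetic_toe_offs, "nonparetic")
  structure(ev, class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> paretic: %d HS / %d TO; nonparetic: %d HS / %d TO\n",
              length(x$paretic_heel_strikes), length(x$paretic_toe_offs),
              length(x$nonparetic_heel_strikes), length(x$nonparetic_toe_offs)))
  invisible(x)
}

#' Ground-reaction-force trace for a split-belt treadmill
#'
#' Per-belt vertical and anterior-posterior force time series, in newtons,
#' with anterior force positive.
#'
#' @param paretic,nonparetic Lists with numeric elements `vertical` and
#'   `anterior` of equal length.
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `grf_trace`.
#' @export
grf_trace <- function(paretic, nonparetic, fs_hz) {
  lens <- c(length(paretic$vertical), length(paretic$anterior),
            length(nonparetic$vertical), length(nonparetic$anterior))
  if (length(unique(lens)) != 1L) {
    stop_mw("invalid_argument", "all GRF channels must have equal length")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop_mw("invalid_argument", "`fs_hz` must be a positive scalar")
  }
  structure(list(paretic = paretic, nonparetic = nonparetic,
                 fs_hz = fs_hz, n = lens[1L]),
            class = "grf_trace")
}

#' @export
print.grf_trace <- function(x, ...) {
  cat(sprintf("<grf_trace> 2 belts x (vertical, anterior), %d samples @ %g Hz\n",
              x$n, x$fs_hz))
  invisible(x)
}

#' Cycle-averaged EMG envelope
#'
#' Muscles x 101 nonnegative envelope matrix on the percent-gait-cycle
#' grid 0, 1, ..., 100, with column 1 anchored at paretic heel strike.
#'
#' @param matrix Nonnegative numeric matrix with 101 columns.
#' @param n_cycles_averaged Number of gait cycles averaged.
#' @return An object of class `cycle_envelope`.
#' @export
cycle_envelope <- function(matrix, n_cycles_averaged) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 101L) {
    stop_mw("invalid_argument", "cycle envelope must have exactly 101 columns")
  }
  if (any(matrix < 0)) {
    stop_mw("invalid_argument", "cycle envelope must be nonnegative")
  }
  structure(list(matrix = matrix,
                 n_cycles_averaged = as.integer(n_cycles_averaged)),
            class = "cycle_envelope")
}

#' @export
print.cycle_envelope <- function(x, ...) {
  cat(sprintf("<cycle_envelope> %d muscles x 101 points (avg of %d cycles)\n",
              nrow(x$matrix), x$n_cycles_averaged))
  invisible(x)
}

# the fixed order of the six gait-cycle regions
bin_labels_ <- function() {
  c("first_double_support",
    "single_stance_first_half",
    "single_stance_second_half",
    "second_double_support",
    "swing_first_half",
    "swing_second_half")
}

#' Six-bin gait-cycle summary
#'
#' Per-muscle mean envelope amplitude in the six named regions of the gait
#' cycle: first double support, first and second half of ipsilateral single
#' stance, second double support, first and second half of ipsilateral
#' swing. Bin boundaries are percentages of the paretic gait cycle derived
#' from the average timing of nonparetic toe-off, nonparetic heel strike
#' and paretic toe-off.
#'
#' @param bin_means Muscles x 6 matrix of mean amplitudes.
#' @param bin_edges_pct Strictly increasing boundaries, length 7, from 0
#'   to 100.
#' @return An object of class `bin_summary`.
#' @export
bin_summary <- function(bin_means, bin_edges_pct) {
  bin_means <- as.matrix(bin_means)
  if (ncol(bin_means) != 6L) {
    stop_mw("invalid_argument", "bin summary must have exactly 6 bins")
  }
  if (length(bin_edges_pct) != 7L || any(diff(bin_edges_pct) <= 0) ||
      bin_edges_pct[1L] != 0 || bin_edges_pct[7L] != 100) {
    stop_mw("malformed_events",
            "bin edges must be 7 strictly increasing values from 0 to 100")
  }
  colnames(bin_means) <- bin_labels_()
  structure(list(bin_means = bin_means,
                 bin_edges_pct = as.numeric(bin_edges_pct),
                 bin_labels = bin_labels_()),
            class = "bin_summary")
}

#' @export
print.bin_summary <- function(x, ...) {
  cat("<bin_summary> muscles x 6 gait-cycle bins; edges (% cycle):",
      paste(signif(x$bin_edges_pct, 4), collapse = ", "), "\n")
  invisible(x)
}
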
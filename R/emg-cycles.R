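# Cycle segmentation, six-bin summaries and amplitude normalization.

#' Segment envelopes into gait cycles and average on the 0-100% grid
#'
#' Each paretic heel-strike-to-heel-strike cycle is resampled to 101
#' points (0, 1, ..., 100% of the cycle) by linear interpolation and the
#' cycles are averaged pointwise. On a noiseless periodic signal with
#' equal cycle durations this reproduces the per-cycle template exactly.
#'
#' @param env An [emg_recording()] of envelopes (see [emg_envelope()]).
#' @param events A [gait_events()] object; paretic heel strikes define the
#'   cycles.
#' @param min_cycles_warn Warn when fewer usable cycles than this are
#'   available (module analysis conventionally uses at least 20).
#' @return A [cycle_envelope()].
#' @export
segment_and_normalize <- function(env, events, min_cycles_warn = 20) {
  stopifnot(inherits(env, "emg_recording"), inherits(events, "gait_events"))
  hs <- events$paretic_heel_strikes
  n <- ncol(env$samples)
  t_end <- (n - 1L) / env$fs_hz
  hs <- hs[hs >= 0 & hs <= t_end]
  if (length(hs) < 2L) {
    stop_mw("insufficient_cycles",
            "need at least 2 paretic heel strikes inside the recording")
  }
  n_cyc <- length(hs) - 1L
  if (n_cyc < min_cycles_warn) {
    warning(sprintf("only %d gait cycles available (< %d recommended)",
                    n_cyc, min_cycles_warn))
  }
  tt <- (seq_len(n) - 1L) / env$fs_hz
  acc <- matrix(0, nrow = nrow(env$samples), ncol = 101L)
  for (i in seq_len(n_cyc)) {
    xout <- hs[i] + (0:100) / 100 * (hs[i + 1L] - hs[i])
    for (ch in seq_len(nrow(env$samples))) {
      acc[ch, ] <- acc[ch, ] + approx(tt, env$samples[ch, ], xout = xout,
                                      rule = 2)$y
    }
  }
  cycle_envelope(pmax(acc / n_cyc, 0), n_cyc)
}

# average within-cycle event positions (percent of paretic cycle)
event_percentages_ <- function(events) {
  hs <- events$paretic_heel_strikes
  n_cyc <- length(hs) - 1L
  pct_of <- function(times) {
    vals <- numeric(0)
    for (i in seq_len(n_cyc)) {
      inside <- times[times >= hs[i] & times < hs[i + 1L]]
      if (length(inside)) {
        vals <- c(vals, 100 * (inside[1L] - hs[i]) / (hs[i + 1L] - hs[i]))
      }
    }
    if (!length(vals)) {
      stop_mw("malformed_events",
              "an event type never occurs inside a paretic cycle")
    }
    mean(vals)
  }
  c(np_toe_off = pct_of(events$nonparetic_toe_offs),
    np_heel_strike = pct_of(events$nonparetic_heel_strikes),
    p_toe_off = pct_of(events$paretic_toe_offs))
}

#' Average envelope amplitude in the six gait-cycle bins
#'
#' Computes the per-muscle mean of the averaged envelope within the six
#' named regions of the gait cycle. The four interior boundaries come
#' from the average percent-of-cycle timing of nonparetic toe-off (end of
#' first double support), nonparetic heel strike (start of second double
#' support) and paretic toe-off (start of swing); single stance and swing
#' are each split at their midpoint.
#'
#' @param cyc A [cycle_envelope()].
#' @param events A [gait_events()] object used to place the boundaries.
#' @return A [bin_summary()].
#' @export
bin_average <- function(cyc, events) {
  stopifnot(inherits(cyc, "cycle_envelope"), inherits(events, "gait_events"))
  p <- event_percentages_(events)
  if (!(0 < p[["np_toe_off"]] && p[["np_toe_off"]] < p[["np_heel_strike"]] &&
        p[["np_heel_strike"]] < p[["p_toe_off"]] && p[["p_toe_off"]] < 100)) {
    stop_mw("malformed_events",
            "bin boundaries are not strictly ordered within the cycle")
  }
  edges <- c(0, p[["np_toe_off"]],
             (p[["np_toe_off"]] + p[["np_heel_strike"]]) / 2,
             p[["np_heel_strike"]], p[["p_toe_off"]],
             (p[["p_toe_off"]] + 100) / 2, 100)
  bin_summary(bin_means_(cyc$matrix, edges), edges)
}

# columns of a percent grid falling in half-open bin [e_b, e_{b+1}) with a
# small tolerance absorbing floating-point jitter in event-derived edges;
# the last bin is closed at 100
bin_columns_ <- function(grid, edges, b) {
  eps <- 1e-9
  if (b < 6L) {
    which(grid >= edges[b] - eps & grid < edges[b + 1L] - eps)
  } else {
    which(grid >= edges[b] - eps & grid <= edges[b + 1L] + eps)
  }
}

# per-muscle column means over the six percent bins
bin_means_ <- function(mat, edges) {
  grid <- 0:100
  means <- matrix(NA_real_, nrow = nrow(mat), ncol = 6L)
  rownames(means) <- rownames(mat)
  for (b in seq_len(6L)) {
    means[, b] <- rowMeans(mat[, bin_columns_(grid, edges, b),
                               drop = FALSE])
  }
  means
}

#' Normalize envelope amplitude by the highest bin mean
#'
#' Divides each muscle's averaged envelope by that muscle's maximum
#' six-bin mean, so that after renormalization the highest bin mean of
#' every muscle equals 1. Normalizing to the mean amplitude of the most
#' active region (rather than the instantaneous peak) reduces
#' between-subject variability.
#'
#' @param cyc A [cycle_envelope()].
#' @param bins The matching [bin_summary()].
#' @param on_zero What to do with an all-zero muscle: `"error"` (default)
#'   or `"drop"` the muscle with a warning.
#' @return A [cycle_envelope()] with normalized amplitudes (possibly fewer
#'   muscles when `on_zero = "drop"`).
#' @export
normalize_amplitude <- function(cyc, bins, on_zero = c("error", "drop")) {
  stopifnot(inherits(cyc, "cycle_envelope"), inherits(bins, "bin_summary"))
  on_zero <- match.arg(on_zero)
  m <- apply(bins$bin_means, 1L, max)
  zero <- m <= 0
  if (any(zero)) {
    if (on_zero == "error") {
      stop_mw("zero_channel", sprintf(
        "muscle(s) with all-zero envelope: %s",
        paste(rownames(cyc$matrix)[zero], collapse = ", ")))
    }
    warning(sprintf("dropping all-zero muscle(s): %s",
                    paste(rownames(cyc$matrix)[zero], collapse = ", ")))
  }
  keep <- !zero
  cycle_envelope(cyc$matrix[keep, , drop = FALSE] / m[keep],
                 cyc$n_cycles_averaged)
}
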
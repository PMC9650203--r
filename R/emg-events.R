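# Gait event detection from vertical GRF: heel strike = sustained upward
# crossing of a force threshold, toe-off = sustained downward crossing.
# Contact/flight episodes shorter than the debounce windows are absorbed
# into their neighbours before events are read off.

detect_leg_events_ <- function(vertical, fs, threshold_n,
                               min_contact_s, min_flight_s) {
  above <- vertical > threshold_n
  if (!any(above)) {
    stop_mw("no_events", "no threshold crossings in vertical GRF")
  }
  r <- rle(above)
  # debounce: drop short contact runs, then short flight runs
  min_c <- max(1L, as.integer(round(min_contact_s * fs)))
  min_f <- max(1L, as.integer(round(min_flight_s * fs)))
  r$values[r$values & r$lengths < min_c] <- FALSE
  r <- rle(inverse.rle(r))
  inner <- seq_along(r$values)[-c(1L, length(r$values))]
  drop_f <- inner[!r$values[inner] & r$lengths[inner] < min_f]
  r$values[drop_f] <- TRUE
  above <- inverse.rle(r)
  d <- diff(above)
  hs <- which(d == 1L) + 1L  # first sample above threshold
  to <- which(d == -1L) + 1L # first sample below threshold
  if (!length(hs)) {
    stop_mw("no_events", "no sustained heel strikes detected")
  }
  # trim so toe-offs interleave between successive heel strikes
  to <- to[to > hs[1L] & to < hs[length(hs)]]
  list(heel_strikes = (hs - 1L) / fs, toe_offs = (to - 1L) / fs)
}

#' Detect gait events from ground reaction forces
#'
#' Reads heel strikes and toe-offs for both belts from the vertical force
#' channels: a heel strike is an upward crossing of `threshold_n`
#' sustained at least `min_contact_s`, a toe-off a downward crossing
#' sustained at least `min_flight_s`. Shorter episodes are treated as
#' noise and absorbed. The returned events satisfy the interleaving
#' invariants of [gait_events()].
#'
#' @param grf A [grf_trace()].
#' @param threshold_n Vertical-force threshold in newtons (default 20, a
#'   conventional value for instrumented treadmills).
#' @param min_contact_s,min_flight_s Debounce windows in seconds
#'   (default 10 ms).
#' @return A [gait_events()] object.
#' @export
detect_gait_events <- function(grf, threshold_n = 20,
                               min_contact_s = 0.01, min_flight_s = 0.01) {
  stopifnot(inherits(grf, "grf_trace"))
  p <- detect_leg_events_(grf$paretic$vertical, grf$fs_hz, threshold_n,
                          min_contact_s, min_flight_s)
  np <- detect_leg_events_(grf$nonparetic$vertical, grf$fs_hz, threshold_n,
                           min_contact_s, min_flight_s)
  gait_events(p$heel_strikes, p$toe_offs, np$heel_strikes, np$toe_offs)
}
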
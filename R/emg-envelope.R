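# EMG envelope extraction: zero-lag high-pass, demean, rectify, zero-lag
# low-pass. The "fourth-order zero-lag" response is realized as a
# forward-backward pass of a second-order Butterworth design, so the net
# magnitude response is fourth order with no phase lag.

# zero-phase filtering with reflective padding
filtfilt_refl_ <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filter(filt, xp)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[(pad + 1L):(pad + n)]
}

#' Extract EMG envelopes
#'
#' High-pass filters each channel (default 40 Hz) with a zero-lag
#' Butterworth filter whose net order is `order`, demeans, full-wave
#' rectifies, and low-pass filters (default 4 Hz) with the same zero-lag
#' scheme. Residual negative values from filter ringing are clipped at 0
#' so the envelope can feed non-negative matrix factorization.
#'
#' @param rec An [emg_recording()] of raw EMG.
#' @param hp_hz High-pass cutoff in Hz.
#' @param lp_hz Low-pass cutoff in Hz.
#' @param order Net filter order of the bidirectional pass (must be even;
#'   default 4, i.e. a second-order design applied forward and backward).
#' @return An [emg_recording()] holding nonnegative envelopes.
#' @export
emg_envelope <- function(rec, hp_hz = 40, lp_hz = 4, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (order %% 2 != 0) {
    stop_mw("invalid_argument", "`order` must be even (bidirectional pass)")
  }
  fs <- rec$fs_hz
  if (fs <= 2 * hp_hz) {
    stop_mw("invalid_argument",
            "sampling rate must exceed twice the high-pass cutoff")
  }
  pad <- 3L * as.integer(ceiling(fs / hp_hz))
  n <- ncol(rec$samples)
  if (n <= pad) {
    stop_mw("insufficient_data", sprintf(
      "signal too short for filtering: %d samples, need > %d", n, pad))
  }
  hp <- signal::butter(order / 2, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(order / 2, lp_hz / (fs / 2), type = "low")
  pad_lp <- min(3L * as.integer(ceiling(fs / lp_hz)), n - 1L)
  env <- t(apply(rec$samples, 1L, function(x) {
    y <- filtfilt_refl_(hp, x, pad)
    y <- y - mean(y)
    y <- abs(y)
    y <- filtfilt_refl_(lp, y, pad_lp)
    pmax(y, 0)
  }))
  emg_recording(env, fs, rec$muscle_names, rec$leg)
}
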
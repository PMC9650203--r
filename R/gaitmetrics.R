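# Propulsion and step-length symmetry metrics.

#' Positive anterior impulse of one leg
#'
#' Trapezoidal time integral of the positive part of the anterior GRF over
#' the analyzed interval, in newton-seconds. The positive anterior impulse
#' is the component of the ground reaction that accelerates the body
#' forward.
#'
#' @param trace A [grf_trace()].
#' @param leg `"paretic"` or `"nonparetic"`.
#' @return Impulse in N s.
#' @export
anterior_impulse <- function(trace, leg = c("paretic", "nonparetic")) {
  stopifnot(inherits(trace, "grf_trace"))
  leg <- match.arg(leg)
  a <- trace[[leg]]$anterior
  if (length(a) < 2L) {
    stop_mw("insufficient_data", "anterior force trace is empty or too short")
  }
  trapz_(pmax(a, 0), 1 / trace$fs_hz)
}

#' Paretic propulsion (Pp)
#'
#' The paretic leg's positive anterior impulse divided by the summed
#' positive anterior impulse of both legs. 0.5 indicates symmetric
#' propulsion; values below 0.5 indicate the paretic leg contributes less.
#'
#' @param trace A [grf_trace()].
#' @return Pp in `[0, 1]`.
#' @export
paretic_propulsion <- function(trace) {
  ip <- anterior_impulse(trace, "paretic")
  inp <- anterior_impulse(trace, "nonparetic")
  if (ip + inp <= 0) {
    stop_mw("undefined_metric",
            "both legs have zero positive anterior impulse")
  }
  ip / (ip + inp)
}

#' Paretic step ratio (PSR)
#'
#' The mean paretic step length divided by the mean stride length (stride
#' = paretic + nonparetic step). 0.5 indicates symmetric step lengths.
#'
#' @param step_lengths Data frame or list with numeric `paretic` and
#'   `nonparetic` per-step lengths.
#' @return PSR in `[0, 1]`.
#' @export
paretic_step_ratio <- function(step_lengths) {
  p <- mean(step_lengths$paretic)
  np <- mean(step_lengths$nonparetic)
  if (!is.finite(p + np) || p + np <= 0) {
    stop_mw("invalid_input", "stride length must be positive")
  }
  p / (p + np)
}

#' Deviation from symmetry
#'
#' `|value - 0.5|` for a symmetry ratio such as Pp or PSR; 0 means perfect
#' symmetry, 0.5 the maximum possible deviation.
#'
#' @param value A ratio in `[0, 1]`.
#' @return Deviation in `[0, 0.5]`.
#' @export
symmetry_deviation <- function(value) {
  if (any(!is.finite(value) | value < 0 | value > 1)) {
    stop_mw("invalid_input", "symmetry values must lie in [0, 1]")
  }
  abs(value - 0.5)
}

#' Propulsion metrics for one subject
#'
#' Convenience wrapper computing Pp, PSR and their deviations from
#' symmetry.
#'
#' @param trace A [grf_trace()].
#' @param step_lengths Per-step lengths (see [paretic_step_ratio()]).
#' @return An object of class `propulsion_metrics` with `pp`, `psr`,
#'   `pp_deviation`, `psr_deviation`.
#' @export
propulsion_metrics <- function(trace, step_lengths) {
  pp <- paretic_propulsion(trace)
  psr <- paretic_step_ratio(step_lengths)
  structure(list(pp = pp, psr = psr,
                 pp_deviation = symmetry_deviation(pp),
                 psr_deviation = symmetry_deviation(psr)),
            class = "propulsion_metrics")
}

#' @export
print.propulsion_metrics <- function(x, ...) {
  cat(sprintf("<propulsion_metrics> Pp = %.3f (dev %.3f), PSR = %.3f (dev %.3f)\n",
              x$pp, x$pp_deviation, x$psr, x$psr_deviation))
  invisible(x)
}
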
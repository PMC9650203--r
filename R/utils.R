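# internal helpers

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_mw <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "modwalk_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_scalar01 <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop_mw("invalid_argument", sprintf(
      "`%s` must be a single value in %s", name,
      if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

trapz_ <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2) * dt
}

clip_ <- function(x, lo, hi) pmin(pmax(x, lo), hi)
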
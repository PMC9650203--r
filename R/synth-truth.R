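# Ground-truth module templates for the synthetic generator.
#
# The two-module template reproduces the mass flexion-extension pattern:
# one stance-dominant module loading SO, MG, VM, LH, MH and GM, and one
# swing-dominant module loading TA and RF. Three- and four-module templates
# split the stance module along the healthy four-module convention:
# plantarflexors (SO, MG); quadriceps + hip abductor (VM, GM); hamstrings
# (MH, LH); dorsiflexors + rectus femoris (TA, RF).

# Gaussian bump on the 0..100 percent-cycle grid, wrapping around 100.
cycle_bump_ <- function(center, width, grid = 0:100) {
  d <- abs(grid - center)
  d <- pmin(d, 100 - d)
  exp(-0.5 * (d / width)^2)
}

# per-template muscle sets and activation timing (center, width in % cycle)
truth_layout_ <- function(n_modules) {
  m <- modwalk_muscles()
  idx <- function(...) match(c(...), m)
  switch(as.character(n_modules),
    "2" = list(
      list(muscles = idx("SO", "MG", "VM", "LH", "MH", "GM"),
           center = 30, width = 20),
      list(muscles = idx("TA", "RF"), center = 78, width = 10)),
    "3" = list(
      list(muscles = idx("VM", "GM", "MH", "LH"), center = 5, width = 9),
      list(muscles = idx("SO", "MG"), center = 45, width = 10),
      list(muscles = idx("TA", "RF"), center = 78, width = 9)),
    "4" = list(
      list(muscles = idx("SO", "MG"), center = 45, width = 10),
      list(muscles = idx("VM", "GM"), center = 10, width = 9),
      list(muscles = idx("MH", "LH"), center = 95, width = 8),
      list(muscles = idx("TA", "RF"), center = 78, width = 9)))
}

#' Ground-truth module templates
#'
#' Builds the nonnegative weight and activation matrices used as ground
#' truth by the synthetic EMG generator. For `n_modules = 2` the first
#' module loads the stance muscles (SO, MG, VM, LH, MH, GM) with a
#' stance-phase activation and the second loads TA and RF with a
#' swing-phase activation; for 3 and 4 the stance module is split along
#' the healthy four-module convention. Weights and timing are jittered
#' deterministically from `seed` so that subjects differ while the module
#' structure is preserved.
#'
#' @param n_modules Number of modules, one of 2, 3 or 4.
#' @param seed Integer seed; the same `(n_modules, seed)` pair always
#'   yields identical matrices.
#' @param weight_jitter Relative s.d. of the multiplicative jitter applied
#'   to main-muscle weights (default 0.15).
#' @return An object of class `gt_modules` with elements `n_modules`,
#'   `weights` (8 x k), `activations` (k x 101) and `muscle_names`.
#' @export
#' @examples
#' tr <- make_truth_templates(2, seed = 1)
#' dim(tr$weights)
make_truth_templates <- function(n_modules, seed, weight_jitter = 0.15) {
  if (!is.numeric(n_modules) || length(n_modules) != 1L ||
      !(n_modules %in% c(2, 3, 4))) {
    stop_mw("invalid_argument", "`n_modules` must be 2, 3 or 4")
  }
  layout <- truth_layout_(n_modules)
  k <- length(layout)
  with_seed_(seed, {
    W <- matrix(runif(8L * k, 0.01, 0.05), nrow = 8L, ncol = k)
    C <- matrix(0, nrow = k, ncol = 101L)
    for (j in seq_len(k)) {
      mod <- layout[[j]]
      W[mod$muscles, j] <- 0.9 * exp(rnorm(length(mod$muscles),
                                           0, weight_jitter))
      center <- mod$center + rnorm(1, 0, 1.5)
      width <- mod$width * exp(rnorm(1, 0, 0.08))
      C[j, ] <- cycle_bump_(center %% 100, width) + 0.02
    }
    rownames(W) <- modwalk_muscles()
    structure(list(n_modules = as.integer(n_modules), weights = W,
                   activations = C, muscle_names = modwalk_muscles()),
              class = "gt_modules")
  })
}

#' @export
print.gt_modules <- function(x, ...) {
  cat(sprintf("<gt_modules> %d modules, %d muscles x 101-point activations\n",
              x$n_modules, nrow(x$weights)))
  invisible(x)
}
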
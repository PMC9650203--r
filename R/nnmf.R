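# Module extraction: multiplicative-update NNMF, uncentered VAF reports
# partitioned by muscle and by gait-cycle bin, and the module-count rule
# (all VAF >= 90%, or no muscle/bin gains more than 5 percentage points
# from one extra module).

# canonical form: unit-maximum weight columns, compensating row scaling
canonicalize_ <- function(W, C) {
  s <- apply(W, 2L, max)
  s[s <= 0] <- 1
  list(W = sweep(W, 2L, s, "/"), C = sweep(C, 1L, s, "*"))
}

#' Fit a non-negative matrix factorization
#'
#' Minimizes the squared Frobenius error of `X ~ W %*% C` by
#' multiplicative updates, run from `restarts` seeded random nonnegative
#' initializations plus an optional warm start (a previous solution padded
#' with a small random module). The best-SSE solution is returned in
#' canonical form (weight columns scaled to unit maximum, activation rows
#' rescaled to compensate); ties between restarts are broken by the lower
#' restart index.
#'
#' @param X Nonnegative matrix (muscles x time points) with no all-zero
#'   rows.
#' @param k Number of modules, `1 <= k <= nrow(X)`.
#' @param seed Integer seed for the random initializations.
#' @param restarts Number of random restarts (default 50).
#' @param max_iter Maximum multiplicative-update iterations per run.
#' @param tol Relative SSE decrease below which a run stops (checked every
#'   `check_every` iterations).
#' @param check_every Iterations between convergence checks (default 10).
#' @param warm_start Optional list with `W` and `C` from a smaller-`k`
#'   fit, padded with a low-magnitude random module and used as an extra
#'   candidate initialization.
#' @return An object of class `module_decomposition` with `W` (muscles x
#'   k), `C` (k x time), `k`, `reconstruction`, `final_sse`, `seed_used`,
#'   `restarts`.
#' @export
nnmf_fit <- function(X, k, seed = 1, restarts = 50, max_iter = 10000,
                     tol = 1e-6, check_every = 10, warm_start = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) {
    stop_mw("invalid_input", "NNMF input must be nonnegative")
  }
  if (any(rowSums(X) == 0)) {
    stop_mw("invalid_input", "NNMF input must have no all-zero rows")
  }
  if (k < 1 || k > nrow(X)) {
    stop_mw("invalid_argument",
            sprintf("`k` must be between 1 and %d", nrow(X)))
  }
  m <- nrow(X); n <- ncol(X)
  scale0 <- mean(X)
  with_seed_(seed, {
    best <- NULL
    run_one <- function(W0, C0) {
      nnmf_mu_cpp(X, W0, C0, as.integer(max_iter), tol,
                  as.integer(check_every))
    }
    if (!is.null(warm_start)) {
      kw <- ncol(warm_start$W)
      extra <- k - kw
      W0 <- cbind(warm_start$W,
                  matrix(runif(m * max(extra, 0), 0, 1e-3 * scale0), m))
      C0 <- rbind(warm_start$C,
                  matrix(runif(max(extra, 0) * n, 0, 1e-3 * scale0),
                         max(extra, 0)))
      fit <- run_one(pmax(W0[, seq_len(k), drop = FALSE], 1e-9),
                     pmax(C0[seq_len(k), , drop = FALSE], 1e-9))
      best <- fit
    }
    for (r in seq_len(restarts)) {
      W0 <- matrix(runif(m * k, 0.1, 1) * scale0, m, k)
      C0 <- matrix(runif(k * n, 0.1, 1), k, n)
      fit <- run_one(W0, C0)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
    cf <- canonicalize_(best$W, best$C)
    rec <- cf$W %*% cf$C
    rownames(cf$W) <- rownames(X)
    structure(list(W = cf$W, C = cf$C, k = as.integer(k),
                   reconstruction = rec,
                   final_sse = sum((X - rec)^2),
                   seed_used = as.integer(seed),
                   restarts = as.integer(restarts)),
              class = "module_decomposition")
  })
}

#' @export
print.module_decomposition <- function(x, ...) {
  cat(sprintf("<module_decomposition> k = %d, SSE = %.4g (%d restarts)\n",
              x$k, x$final_sse, x$restarts))
  invisible(x)
}

#' Plot module weights and activations
#'
#' One row per module: a bar chart of muscle weights and the activation
#' profile over the gait cycle.
#'
#' @param x A `module_decomposition`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.module_decomposition <- function(x, ...) {
  op <- graphics::par(mfrow = c(x$k, 2), mar = c(2.5, 3, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_len(x$k)) {
    graphics::barplot(x$W[, j], names.arg = rownames(x$W), las = 2,
                      main = sprintf("module %d weights", j), ...)
    graphics::plot(0:100, x$C[j, ], type = "l", xlab = "", ylab = "",
                   main = sprintf("module %d activation (%% cycle)", j))
  }
  invisible(x)
}

vaf_ <- function(sse, ssq) {
  if (ssq <= 0) {
    stop_mw("undefined_vaf", "zero sum of squares in a VAF partition")
  }
  100 * (1 - sse / ssq)
}

#' Variability accounted for, overall, per muscle and per bin
#'
#' Uncentered VAF, `100 * (1 - SSE / SSQ)` with `SSQ` the sum of squared
#' data entries, computed for the whole matrix, for each muscle row over
#' the full cycle, and for each gait-cycle bin (columns within the bin
#' boundaries, pooled across muscles).
#'
#' @param X The nonnegative matrix that was factorized.
#' @param decomp A `module_decomposition` for `X`.
#' @param bin_edges_pct Seven bin boundaries in percent cycle (see
#'   [bin_summary()]), used to partition the columns.
#' @return An object of class `vaf_report` with `vaf_overall`,
#'   `vaf_per_muscle` (length 8), `vaf_per_bin` (length 6) and `k`.
#' @export
compute_vaf <- function(X, decomp, bin_edges_pct) {
  X <- as.matrix(X)
  E <- X - decomp$reconstruction
  if (!all(dim(E) == dim(X))) {
    stop_mw("invalid_argument", "decomposition does not match X")
  }
  grid <- seq(0, 100, length.out = ncol(X))
  per_bin <- vapply(seq_len(6L), function(b) {
    cols <- bin_columns_(grid, bin_edges_pct, b)
    vaf_(sum(E[, cols]^2), sum(X[, cols]^2))
  }, numeric(1))
  per_muscle <- vapply(seq_len(nrow(X)), function(i) {
    vaf_(sum(E[i, ]^2), sum(X[i, ]^2))
  }, numeric(1))
  names(per_muscle) <- rownames(X)
  names(per_bin) <- bin_labels_()
  structure(list(vaf_overall = vaf_(sum(E^2), sum(X^2)),
                 vaf_per_muscle = per_muscle,
                 vaf_per_bin = per_bin, k = decomp$k),
            class = "vaf_report")
}

#' @export
print.vaf_report <- function(x, ...) {
  cat(sprintf("<vaf_report> k = %d, overall VAF = %.1f%%, min muscle = %.1f%%, min bin = %.1f%%\n",
              x$k, x$vaf_overall, min(x$vaf_per_muscle), min(x$vaf_per_bin)))
  invisible(x)
}

min_vaf_ <- function(vr) min(c(vr$vaf_per_muscle, vr$vaf_per_bin))

#' Select the number of modules by the VAF rule
#'
#' Adds modules one at a time: stop at the first `k` for which the VAF of
#' every muscle and every gait-cycle bin is at least `vaf_threshold`
#' (default 90%); otherwise, if moving to `k + 1` raises no individual
#' muscle or bin VAF by more than `gain_threshold` percentage points
#' (default 5), stop at `k` and discard the `k + 1` fit; hard cap at
#' `k_max`. Fits are warmed from the previous `k`, which makes the
#' overall VAF non-decreasing along the trail.
#'
#' @inheritParams nnmf_fit
#' @param bin_edges_pct Bin boundaries for the VAF partitions.
#' @param k_max Hard cap on the module count (default 8).
#' @param vaf_threshold,gain_threshold The two stopping thresholds, in
#'   percent and percentage points.
#' @return An object of class `module_count_decision` with `k_selected`,
#'   `stop_reason` (`all_thresholds_met`, `gain_below_5pct` or
#'   `k_max_reached`), `pattern_class` (`two_modules` iff
#'   `k_selected <= 2`, else `more_than_two`), `trail` (list of per-`k`
#'   records) and `fits` (the retained decompositions).
#' @export
select_module_number <- function(X, bin_edges_pct, seed = 1, restarts = 50,
                                 k_max = 8, vaf_threshold = 90,
                                 gain_threshold = 5, max_iter = 10000,
                                 tol = 1e-6) {
  X <- as.matrix(X)
  k_max <- min(k_max, nrow(X))
  trail <- list()
  fits <- list()
  fit <- nnmf_fit(X, 1L, seed = seed, restarts = restarts,
                  max_iter = max_iter, tol = tol)
  vr <- compute_vaf(X, fit, bin_edges_pct)
  k <- 1L
  repeat {
    fits[[k]] <- fit
    if (min_vaf_(vr) >= vaf_threshold) {
      trail[[k]] <- list(k = k, vaf = vr, stop_reason = "all_thresholds_met")
      k_sel <- k; reason <- "all_thresholds_met"
      break
    }
    if (k == k_max) {
      trail[[k]] <- list(k = k, vaf = vr, stop_reason = "k_max_reached")
      k_sel <- k; reason <- "k_max_reached"
      break
    }
    fit_next <- nnmf_fit(X, k + 1L, seed = seed + k, restarts = restarts,
                         max_iter = max_iter, tol = tol,
                         warm_start = list(W = fit$W, C = fit$C))
    vr_next <- compute_vaf(X, fit_next, bin_edges_pct)
    gains <- c(vr_next$vaf_per_muscle - vr$vaf_per_muscle,
               vr_next$vaf_per_bin - vr$vaf_per_bin)
    if (max(gains) <= gain_threshold) {
      trail[[k]] <- list(k = k, vaf = vr, stop_reason = "gain_below_5pct")
      k_sel <- k; reason <- "gain_below_5pct"
      break
    }
    trail[[k]] <- list(k = k, vaf = vr, stop_reason = "continued")
    fit <- fit_next
    vr <- vr_next
    k <- k + 1L
  }
  structure(list(k_selected = k_sel, stop_reason = reason,
                 pattern_class = if (k_sel <= 2L) "two_modules"
                                 else "more_than_two",
                 trail = trail, fits = fits,
                 decomposition = fits[[k_sel]]),
            class = "module_count_decision")
}

#' @export
print.module_count_decision <- function(x, ...) {
  cat(sprintf("<module_count_decision> k = %d (%s), pattern: %s\n",
              x$k_selected, x$stop_reason, x$pattern_class))
  invisible(x)
}

cosine_ <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# all permutations of 1..n (n small)
permutations_ <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub))) }))
}

#' Match extracted modules to a reference
#'
#' Finds the one-to-one assignment of extracted weight columns to
#' reference weight columns that maximizes the summed cosine similarity
#' (exhaustive search over permutations for up to 6 modules, greedy
#' beyond). Used for parameter-recovery checks against the generator's
#' ground truth.
#'
#' @param decomp A `module_decomposition` (or any list with a `W`
#'   matrix).
#' @param reference A `gt_modules` or `module_decomposition` with a
#'   weight matrix `weights` or `W`.
#' @return List with `assignment` (index into reference columns for each
#'   extracted column), `similarities` (per matched pair) and
#'   `mean_similarity`.
#' @export
match_modules <- function(decomp, reference) {
  W1 <- decomp$W
  W2 <- if (!is.null(reference$weights)) reference$weights else reference$W
  k1 <- ncol(W1); k2 <- ncol(W2)
  if (k1 < 1 || k2 < 1) {
    stop_mw("invalid_argument", "both sides must have at least one module")
  }
  S <- outer(seq_len(k1), seq_len(k2),
             Vectorize(function(i, j) cosine_(W1[, i], W2[, j])))
  assignment <- rep(NA_integer_, k1)
  if (k1 <= k2 && k2 <= 6L) {
    perms <- permutations_(k2)
    best_val <- -Inf
    for (p in seq_len(nrow(perms))) {
      idx <- perms[p, seq_len(k1)]
      val <- sum(S[cbind(seq_len(k1), idx)])
      if (val > best_val + 1e-12) {
        best_val <- val
        assignment <- idx
      }
    }
  } else {
    avail <- seq_len(k2)
    for (i in order(apply(S, 1L, max), decreasing = TRUE)) {
      if (!length(avail)) break
      j <- avail[which.max(S[i, avail])]
      assignment[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  assignment <- unname(assignment)
  matched <- which(!is.na(assignment))
  sims <- S[cbind(matched, assignment[matched])]
  list(assignment = assignment, similarities = sims,
       mean_similarity = mean(sims))
}
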
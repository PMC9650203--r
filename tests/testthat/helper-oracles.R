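# Independent brute-force oracles used across test files. These are kept
# deliberately naive (explicit loops, closed forms) so they do not share
# code paths with the implementation.

# Pearson correlation on hand-computed midranks
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# exhaustive pair count for the Mann-Whitney U statistic
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  }
  u
}

# one-way ANOVA F from explicit between/within mean squares
oracle_f <- function(values, groups) {
  groups <- as.character(groups)
  gs <- unique(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0; n <- length(values)
  for (g in gs) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (length(gs) - 1)) / (ssw / (n - length(gs)))
}

# uncentered VAF over an arbitrary index set, recomputed from scratch
oracle_vaf <- function(X, recon, rows, cols) {
  e2 <- 0; x2 <- 0
  for (i in rows) for (j in cols) {
    e2 <- e2 + (X[i, j] - recon[i, j])^2
    x2 <- x2 + X[i, j]^2
  }
  100 * (1 - e2 / x2)
}

# exhaustive best-threshold search for a 1-D Gini split
oracle_best_threshold <- function(x, labels) {
  v <- sort(unique(x))
  thr <- (v[-1] + v[-length(v)]) / 2
  gini <- function(l) {
    p <- table(l) / length(l)
    1 - sum(p^2)
  }
  n <- length(x)
  best <- NULL; best_imp <- Inf
  for (th in thr) {
    l <- labels[x < th]; r <- labels[x >= th]
    imp <- (length(l) * gini(l) + length(r) * gini(r)) / n
    if (imp < best_imp - 1e-12) {
      best_imp <- imp; best <- th
    }
  }
  best
}

# exhaustive best-permutation mean cosine between weight matrices
oracle_match <- function(W1, W2) {
  k <- ncol(W1)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(k))) {
    val <- mean(vapply(seq_len(k),
                       function(i) cosv(W1[, i], W2[, p[i]]), numeric(1)))
    if (val > best) best <- val
  }
  best
}

# default bin edges used when a test needs fixed, valid boundaries
test_edges <- function() c(0, 12, 31, 50, 62, 81, 100)

# events with exact within-cycle fractions 12 / 50 / 62 % over unit cycles
make_exact_events <- function(n_cycles) {
  s <- 0:(n_cycles - 1)
  gait_events(
    paretic_heel_strikes = c(s, n_cycles),
    paretic_toe_offs = s + 0.62,
    nonparetic_heel_strikes = s + 0.50,
    nonparetic_toe_offs = (s + 1.12)[-n_cycles])
}
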
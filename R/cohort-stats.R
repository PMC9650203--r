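# Nonparametric cohort statistics: tie-corrected Spearman correlation
# with a t-approximation p-value, Mann-Whitney U (exact when feasible),
# and one-way ANOVA with Bonferroni-adjusted pairwise post-hocs.

#' Spearman rank correlation with pairwise-complete deletion
#'
#' Average-rank (tie-corrected) Spearman rho, i.e. the Pearson
#' correlation of the midranks, with a two-sided p-value from the
#' t-approximation on `n - 2` degrees of freedom. Incomplete pairs are
#' dropped (pairwise-complete), matching the handling of cohorts where
#' not every outcome measure is available for every subject.
#'
#' @param x,y Numeric vectors of equal length.
#' @param labels Optional character vector of length 2 naming the pair.
#' @return An object of class `correlation_result` with `rho`, `df`
#'   (`n_used - 2`), `p_value`, `n_used`.
#' @export
spearman_cor <- function(x, y, labels = NULL) {
  if (is.null(labels)) {
    labels <- c(deparse(substitute(x))[1L], deparse(substitute(y))[1L])
    labels <- ifelse(nchar(labels) > 24,
                     paste0(substr(labels, 1, 21), "..."), labels)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) {
    stop_mw("insufficient_data",
            "need at least 4 complete pairs for a correlation")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop_mw("undefined_correlation",
            "correlation undefined for a constant vector")
  }
  rho <- cor(rank(x), rank(y))
  df <- n - 2L
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(pair = labels, rho = rho, df = df,
                 p_value = min(p, 1), n_used = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s ~ %s: rho = %.3f (df = %d, p = %.4g)\n",
              x$pair[1L], x$pair[2L], x$rho, x$df, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs `(i, j)` with `a_i > b_j`, plus half the tied
#' pairs. The two-sided p-value is exact (from the null distribution of
#' U) when there are no ties and `n_a * n_b <= 10000`, otherwise a
#' tie-corrected normal approximation is used.
#'
#' @param a,b Numeric samples (both nonempty).
#' @return List with `U`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) {
    stop_mw("insufficient_data", "both samples must be nonempty")
  }
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && na * nb <= 10000) {
    p_less <- pwilcox(U, na, nb)
    p_greater <- pwilcox(U - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(p_less, p_greater))
    method <- "exact"
  } else {
    N <- na + nb
    tab <- table(c(a, b))
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    z <- (U - na * nb / 2) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(U = U, p_value = p, n_a = na, n_b = nb, method = method)
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Standard one-way ANOVA F test across labeled groups, followed by
#' pairwise t tests (pooled SD) with Bonferroni adjustment capped at 1.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor), at least 2 groups with
#'   at least 2 observations each.
#' @return List with `F`, `p_value`, `df_between`, `df_within`,
#'   `pairwise_p` (matrix of adjusted p-values) and `group_means`.
#' @export
anova_posthoc <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop_mw("invalid_argument",
            "need >= 2 groups with >= 2 observations each")
  }
  fit <- lm(values ~ groups)
  av <- anova(fit)
  if (av[["Mean Sq"]][2L] <= 0) {
    stop_mw("undefined_f", "zero within-group variance: F undefined")
  }
  pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                        pool.sd = TRUE)
  list(F = av[["F value"]][1L], p_value = av[["Pr(>F)"]][1L],
       df_between = av[["Df"]][1L], df_within = av[["Df"]][2L],
       pairwise_p = pmin(pw$p.value, 1),
       group_means = tapply(values, groups, mean))
}
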
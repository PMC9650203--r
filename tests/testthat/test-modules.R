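# NNMF fitting, VAF computation, module-count selection and module
# matching.

test_that("an exactly rank-1 matrix factorizes to 100% VAF at k = 1", {
  set.seed(1)
  w <- runif(8, 0.2, 1)
  c_ <- runif(101, 0.2, 1)
  X <- outer(w, c_)
  fit <- nnmf_fit(X, 1, seed = 1, restarts = 5)
  vr <- compute_vaf(X, fit, test_edges())
  expect_gt(vr$vaf_overall, 100 - 1e-6)
  expect_true(all(vr$vaf_per_muscle > 100 - 1e-6))
  expect_true(all(vr$vaf_per_bin > 100 - 1e-6))
})

test_that("NNMF recovers a noiseless 4-module mixture", {
  tr <- make_truth_templates(4, seed = 2)
  X <- tr$weights %*% tr$activations
  fit <- nnmf_fit(X, 4, seed = 2, restarts = 20)
  m <- match_modules(fit, tr)
  expect_true(all(m$similarities > 0.95))
})

test_that("NNMF is deterministic, canonical and validates input", {
  set.seed(4)
  X <- matrix(runif(8 * 101, 0.1, 1), 8, 101)
  a <- nnmf_fit(X, 3, seed = 7, restarts = 5)
  b <- nnmf_fit(X, 3, seed = 7, restarts = 5)
  expect_identical(a$W, b$W)
  expect_identical(a$C, b$C)
  # canonical form: unit-max weight columns, SSE consistent
  expect_equal(unname(apply(a$W, 2, max)), rep(1, 3), tolerance = 1e-12)
  expect_equal(a$reconstruction, a$W %*% a$C, tolerance = 1e-10)
  expect_equal(a$final_sse, sum((X - a$reconstruction)^2),
               tolerance = 1e-10)
  Xneg <- X; Xneg[1, 1] <- -1
  expect_error(nnmf_fit(Xneg, 2), class = "invalid_input")
  expect_error(nnmf_fit(X, 9), class = "invalid_argument")
  Xz <- X; Xz[2, ] <- 0
  expect_error(nnmf_fit(Xz, 2), class = "invalid_input")
})

test_that("VAF has the closed-form value for a half-amplitude reconstruction", {
  set.seed(5)
  X <- matrix(runif(8 * 101, 0.1, 1), 8, 101)
  perfect <- list(reconstruction = X, k = 2L)
  vp <- compute_vaf(X, perfect, test_edges())
  expect_equal(vp$vaf_overall, 100)
  expect_true(all(vp$vaf_per_muscle == 100))
  expect_true(all(vp$vaf_per_bin == 100))
  half <- list(reconstruction = X / 2, k = 2L)
  vh <- compute_vaf(X, half, test_edges())
  expect_equal(vh$vaf_overall, 75, tolerance = 1e-12)
  expect_equal(unname(vh$vaf_per_muscle), rep(75, 8), tolerance = 1e-12)
  expect_equal(unname(vh$vaf_per_bin), rep(75, 6), tolerance = 1e-12)
})

test_that("per-partition VAF equals the brute-force oracle", {
  set.seed(6)
  for (rep in 1:5) {
    X <- matrix(runif(8 * 101, 0.05, 1), 8, 101)
    recon <- X * matrix(runif(8 * 101, 0.5, 1.2), 8, 101)
    vr <- compute_vaf(X, list(reconstruction = recon, k = 2L), test_edges())
    for (i in 1:8) {
      expect_equal(unname(vr$vaf_per_muscle[i]),
                   oracle_vaf(X, recon, i, 1:101), tolerance = 1e-9)
    }
    edges <- test_edges()
    for (b in 1:6) {
      cols <- which(0:100 >= edges[b] &
                    (if (b < 6) 0:100 < edges[b + 1] else TRUE))
      expect_equal(unname(vr$vaf_per_bin[b]),
                   oracle_vaf(X, recon, 1:8, cols), tolerance = 1e-9)
    }
  }
})

test_that("the VAF rule selects the true module count on noiseless mixtures", {
  tr2 <- make_truth_templates(2, seed = 8)
  X2 <- tr2$weights %*% tr2$activations
  d2 <- select_module_number(X2, test_edges(), seed = 1, restarts = 10)
  expect_equal(d2$k_selected, 2L)
  expect_equal(d2$stop_reason, "all_thresholds_met")
  expect_equal(d2$pattern_class, "two_modules")

  tr4 <- make_truth_templates(4, seed = 8)
  X4 <- tr4$weights %*% tr4$activations
  d4 <- select_module_number(X4, test_edges(), seed = 1, restarts = 10)
  expect_equal(d4$k_selected, 4L)
  expect_equal(d4$pattern_class, "more_than_two")
})

test_that("a single-module structure classifies as two_modules", {
  set.seed(9)
  X <- outer(runif(8, 0.3, 1), runif(101, 0.3, 1))
  X <- X + matrix(abs(rnorm(length(X), 0, 1e-4)), 8)
  d <- select_module_number(X, test_edges(), seed = 2, restarts = 5)
  expect_equal(d$k_selected, 1L)
  expect_equal(d$pattern_class, "two_modules")
})

test_that("overall VAF is non-decreasing along the selection trail", {
  cfg <- subject_config(true_n_modules = 4, n_cycles = 22, noise_sd = 0.1,
                        seed = 13)
  tr <- make_truth_templates(4, seed = 13)
  sub <- generate_emg(cfg, tr)
  res <- module_analysis(sub$emg, sub$events, seed = 13, restarts = 5)
  vafs <- vapply(res$decision$trail, function(e) e$vaf$vaf_overall,
                 numeric(1))
  expect_true(all(diff(vafs) >= -1e-8))
  expect_true(all(vafs <= 100 + 1e-9))
})

test_that("module matching recovers permutations and the exhaustive optimum", {
  tr <- make_truth_templates(4, seed = 10)
  W <- tr$weights
  ident <- match_modules(list(W = W), tr)
  expect_equal(ident$assignment, 1:4)
  expect_equal(ident$similarities, rep(1, 4), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  shuf <- match_modules(list(W = W[, perm]), tr)
  expect_equal(shuf$assignment, perm)
  # noisy weights: mean similarity equals the brute-force best permutation
  set.seed(11)
  Wn <- pmax(W + matrix(rnorm(length(W), 0, 0.1), nrow(W)), 0)
  got <- match_modules(list(W = Wn), tr)
  expect_equal(got$mean_similarity, oracle_match(Wn, W), tolerance = 1e-12)
})
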
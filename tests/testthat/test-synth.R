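# Synthetic generator: truth templates, EMG, GRF and cohorts.

test_that("two-module truth template separates stance and swing muscles", {
  tr <- make_truth_templates(2, seed = 1)
  W <- tr$weights
  expect_identical(rownames(W), modwalk_muscles())
  # swing muscles barely load the stance module and vice versa
  expect_lt(W["TA", 1], 0.1 * max(W[, 1]))
  expect_lt(W["RF", 1], 0.1 * max(W[, 1]))
  expect_lt(W["SO", 2], 0.1 * max(W[, 2]))
  expect_lt(W["GM", 2], 0.1 * max(W[, 2]))
  # stance module peaks in stance (<62%), swing module in swing
  expect_lt(which.max(tr$activations[1, ]) - 1, 62)
  expect_gt(which.max(tr$activations[2, ]) - 1, 62)
})

test_that("truth templates are deterministic and well-formed for k = 2..4", {
  for (k in 2:4) {
    a <- make_truth_templates(k, seed = 3)
    b <- make_truth_templates(k, seed = 3)
    expect_identical(a, b)
    expect_equal(dim(a$weights), c(8L, k))
    expect_equal(dim(a$activations), c(k, 101L))
    expect_true(all(a$weights >= 0))
    expect_true(all(a$activations >= 0))
    expect_true(all(apply(a$weights, 1, max) > 0))
    expect_true(all(apply(a$weights, 2, max) > 0))
    expect_true(all(apply(a$activations, 1, max) > 0))
  }
  expect_error(make_truth_templates(5, seed = 1), class = "invalid_argument")
  expect_error(make_truth_templates(1, seed = 1), class = "invalid_argument")
})

test_that("generated EMG tiles n_cycles cycles with consistent events", {
  cfg <- subject_config(true_n_modules = 2, n_cycles = 20, seed = 5)
  tr <- make_truth_templates(2, seed = 5)
  sub <- generate_emg(cfg, tr)
  expect_gte(length(sub$events$paretic_heel_strikes), 21)
  expect_equal(nrow(sub$emg$samples), 8)
  # same config + seed reproduces bit-identical output
  sub2 <- generate_emg(cfg, tr)
  expect_identical(sub$emg$samples, sub2$emg$samples)
  # a different seed changes the raw samples
  cfg3 <- subject_config(true_n_modules = 2, n_cycles = 20, seed = 6)
  sub3 <- generate_emg(cfg3, tr)
  expect_false(isTRUE(all.equal(sub$emg$samples[, 1:1000],
                                sub3$emg$samples[, 1:1000])))
})

test_that("noiseless EMG round-trips through the envelope pipeline within 5%", {
  cfg <- subject_config(true_n_modules = 2, n_cycles = 30, noise_sd = 0,
                        seed = 11)
  tr <- make_truth_templates(2, seed = 11)
  sub <- generate_emg(cfg, tr)
  cyc <- segment_and_normalize(emg_envelope(sub$emg), sub$events)
  target <- tr$weights %*% tr$activations
  est <- cyc$matrix
  s <- sum(est * target) / sum(est^2)  # carrier rectification scale
  err <- sqrt(mean((s * est - target)^2)) / sqrt(mean(target^2))
  expect_lt(err, 0.05)
})

test_that("GRF generator hits the configured propulsion and step ratios", {
  g0 <- generate_grf(subject_config(pp_true = 0.5, grf_noise_sd = 0,
                                    seed = 2))
  expect_lt(abs(paretic_propulsion(g0$grf) - 0.5), 1e-6)
  g3 <- generate_grf(subject_config(pp_true = 0.3, seed = 2))
  expect_lt(abs(paretic_propulsion(g3$grf) - 0.3), 0.01)
  expect_equal(paretic_step_ratio(g3$step_lengths), 0.5, tolerance = 1e-9)
  g6 <- generate_grf(subject_config(psr_true = 0.6, seed = 4))
  expect_equal(paretic_step_ratio(g6$step_lengths), 0.6, tolerance = 1e-9)
})

test_that("degenerate propulsion targets need the explicit flag", {
  cfg <- subject_config(pp_true = 0, seed = 1)
  expect_error(generate_grf(cfg), class = "invalid_argument")
  g <- generate_grf(subject_config(pp_true = 0, grf_noise_sd = 0, seed = 1),
                    allow_degenerate = TRUE)
  expect_equal(anterior_impulse(g$grf, "paretic"), 0)
  expect_equal(paretic_propulsion(g$grf), 0)
})

test_that("cohort generation is deterministic and scenario-checked", {
  a <- generate_cohort(12, 4, seed = 9)
  b <- generate_cohort(12, 4, seed = 9)
  expect_identical(a$table, b$table)
  expect_error(generate_cohort(5, 2, scenario = "nope"),
               class = "invalid_argument")
  h <- generate_cohort(0, 5, seed = 1)
  expect_equal(nrow(h$table), 5)
  expect_true(all(h$table$group == "healthy"))
  expect_true(all(is.na(h$table$true_k)))
})

test_that("paper-like subgroup contralesional CRP means match the group structure", {
  coh <- generate_cohort(43, 17, seed = 5)
  st <- coh$table[coh$table$group == "stroke", ]
  m <- tapply(st$crp_contra_raw, st$subgroup, mean)
  expect_lt(abs(m[["C"]] - 16.8) / 16.8, 0.2)
  expect_lt(abs(m[["A"]] - 13.2) / 13.2, 0.2)
  expect_lt(abs(m[["B"]] - 11.5) / 11.5, 0.2)
  # two-module subgroups carry the two-module ground truth
  expect_true(all(st$true_k[st$subgroup %in% c("B", "C")] == 2))
  expect_true(all(st$true_k[st$subgroup %in% c("A", "X")] > 2))
})
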
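# Envelope extraction, event detection, segmentation, binning and
# amplitude normalization.

test_that("envelope nulls zero and DC input", {
  fs <- 2000
  zero <- emg_recording(matrix(0, 1, 4000), fs, "m1")
  expect_true(all(emg_envelope(zero)$samples == 0))
  dc <- emg_recording(matrix(5, 1, 4000), fs, "m1")
  env <- emg_envelope(dc)$samples[1, 1000:3000]
  expect_lt(max(env), 0.01 * 5)
})

test_that("envelope of an 80 Hz sinusoid matches the frequency-response oracle", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)
  rec <- emg_recording(matrix(sin(2 * pi * 80 * t), 1), fs, "m1")
  env <- emg_envelope(rec)$samples[1, ]
  mid <- env[round(length(env) * 0.25):round(length(env) * 0.75)]
  # independent oracle: bidirectional 2nd-order Butterworth high-pass gain
  # at 80 Hz times the rectified-sine mean (low-pass DC gain is 1)
  gain_hp2 <- 1 / sqrt(1 + (40 / 80)^4)
  expected <- gain_hp2^2 * (2 / pi)
  expect_lt(abs(mean(mid) - expected) / expected, 0.02)
})

test_that("envelope rejects too-short signals", {
  rec <- emg_recording(matrix(rnorm(50), 1), 2000, "m1")
  expect_error(emg_envelope(rec), class = "insufficient_data")
})

test_that("event detection finds constructed square-pulse contacts exactly", {
  fs <- 2000
  n <- 10 * fs
  rises <- c(0.5, 1.6, 2.7, 3.8, 4.9) * fs + 1
  v <- numeric(n)
  for (r in rises) v[r:(r + 0.7 * fs)] <- 700
  nv <- numeric(n)
  for (r in rises + 0.55 * fs) nv[r:(r + 0.7 * fs)] <- 700
  g <- grf_trace(list(vertical = v, anterior = numeric(n)),
                 list(vertical = nv, anterior = numeric(n)), fs)
  ev <- detect_gait_events(g)
  expect_equal(ev$paretic_heel_strikes, (rises - 1) / fs)
  # toe-offs fall between successive heel strikes (constructor-enforced)
  expect_length(ev$paretic_toe_offs, length(rises) - 1)
})

test_that("all-zero GRF raises a no-events error", {
  g <- grf_trace(list(vertical = numeric(1000), anterior = numeric(1000)),
                 list(vertical = numeric(1000), anterior = numeric(1000)),
                 2000)
  expect_error(detect_gait_events(g), class = "no_events")
})

test_that("debounced detection on noisy pulses matches the noiseless oracle", {
  fs <- 2000
  n <- 8 * fs
  rises <- (1:5) * 1.2 * fs + 1
  v <- numeric(n)
  for (r in rises) v[r:(r + 0.7 * fs)] <- 700
  clean <- grf_trace(list(vertical = v, anterior = numeric(n)),
                     list(vertical = v, anterior = numeric(n)), fs)
  ev_clean <- detect_gait_events(clean)
  set.seed(42)
  noisy <- grf_trace(list(vertical = v + rnorm(n, 0, 10),
                          anterior = numeric(n)),
                     list(vertical = v + rnorm(n, 0, 10),
                          anterior = numeric(n)), fs)
  ev_noisy <- detect_gait_events(noisy)
  expect_equal(ev_noisy$paretic_heel_strikes, ev_clean$paretic_heel_strikes,
               tolerance = 1.5 / fs)
  expect_equal(ev_noisy$paretic_toe_offs, ev_clean$paretic_toe_offs,
               tolerance = 1.5 / fs)
})

test_that("segmentation reproduces an exactly periodic template", {
  fs <- 100
  n_cyc <- 6
  template <- matrix(runif(2 * 101, 0.2, 1), 2, 101)
  template[, 101] <- template[, 1]  # periodic
  sig <- template[, rep(1:100, n_cyc + 1)][, 1:(n_cyc * 100 + 1)]
  rec <- emg_recording(sig, fs, c("m1", "m2"))
  ev <- gait_events(0:n_cyc, (0:(n_cyc - 1)) + 0.62,
                    (0:(n_cyc - 1)) + 0.5,
                    ((0:(n_cyc - 1)) + 1.12)[-n_cyc])
  cyc <- suppressWarnings(segment_and_normalize(rec, ev))
  expect_equal(cyc$matrix, template, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cyc$n_cycles_averaged, n_cyc)
})

test_that("averaging two cycles of x and 2x yields 1.5x", {
  fs <- 100
  template <- matrix(runif(101, 0.2, 1), 1, 101)
  template[, 101] <- template[, 1]
  sig <- matrix(c(template[1, 1:100], 2 * template[1, 1:100],
                  2 * template[1, 101]), nrow = 1)
  rec <- emg_recording(sig, fs, "m1")
  ev <- gait_events(0:2, c(0.62, 1.62), c(0.5, 1.5), 1.12)
  cyc <- suppressWarnings(segment_and_normalize(rec, ev))
  # the 100% point is the next cycle's heel-strike sample (half-open
  # cycles), so the identity holds on 0..99%
  expect_equal(cyc$matrix[, 1:100], 1.5 * template[, 1:100],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("segmentation tolerates 3% duration jitter on a smooth template", {
  fs <- 500
  n_cyc <- 25
  smooth <- 0.5 + 0.4 * sin(2 * pi * (0:100) / 100)
  set.seed(7)
  dur <- exp(rnorm(n_cyc, 0, 0.03))
  hs <- c(0, cumsum(dur))
  total_n <- ceiling(hs[n_cyc + 1] * fs) + 1
  tt <- (seq_len(total_n) - 1) / fs
  ci <- findInterval(tt, hs[1:n_cyc])
  phase <- 100 * (tt - hs[ci]) / dur[ci]
  sig <- matrix(approx(0:100, smooth, xout = pmin(phase, 100))$y, 1)
  rec <- emg_recording(sig, fs, "m1")
  ev <- gait_events(hs, hs[1:n_cyc] + 0.62 * dur, hs[1:n_cyc] + 0.5 * dur,
                    (hs[1:n_cyc] + 1.12 * dur)[-n_cyc])
  cyc <- segment_and_normalize(rec, ev)
  err <- sqrt(mean((cyc$matrix[1, ] - smooth)^2)) / sqrt(mean(smooth^2))
  expect_lt(err, 0.02)
})

test_that("fewer than two heel strikes is an error, few cycles a warning", {
  rec <- emg_recording(matrix(1, 1, 1000), 100, "m1")
  ev1 <- gait_events(0.5, numeric(0), numeric(0), numeric(0))
  expect_error(segment_and_normalize(rec, ev1),
               class = "insufficient_cycles")
  expect_warning(segment_and_normalize(rec, make_exact_events(5)),
                 "gait cycles")
})

test_that("bin averages follow the constructed boundaries", {
  ev <- make_exact_events(8)
  const <- cycle_envelope(matrix(3.5, 8, 101), 8)
  bc <- bin_average(const, ev)
  expect_equal(unname(bc$bin_means), matrix(3.5, 8, 6))
  expect_equal(bc$bin_edges_pct, c(0, 12, 31, 50, 62, 81, 100))
  # stance indicator: 1 before 62% of the cycle, 0 after
  ind <- matrix(rep(as.numeric(0:100 < 62), each = 8), 8, 101)
  bi <- bin_average(cycle_envelope(ind, 8), ev)
  expect_equal(unname(bi$bin_means),
               matrix(rep(c(1, 1, 1, 1, 0, 0), each = 8), 8, 6))
})

test_that("bin means of a linear ramp match the closed-form column means", {
  ev <- make_exact_events(8)
  ramp <- matrix(rep((0:100) / 100, each = 2), 2, 101, byrow = FALSE)
  br <- bin_average(cycle_envelope(ramp, 8), ev)
  # mean of j/100 over integer grid columns a..b-1 is (a + b - 1) / 200
  edges <- c(0, 12, 31, 50, 62, 81, 101)
  expected <- vapply(1:6, function(b) {
    cols <- edges[b]:(edges[b + 1] - 1)
    mean(cols / 100)
  }, numeric(1))
  expect_equal(unname(br$bin_means),
               matrix(rep(expected, each = 2), 2, 6), tolerance = 1e-12)
})

test_that("amplitude normalization sets every muscle's max bin mean to 1", {
  set.seed(3)
  ev <- make_exact_events(10)
  cyc <- cycle_envelope(matrix(runif(8 * 101, 0.1, 2), 8, 101), 10)
  bins <- bin_average(cyc, ev)
  norm <- normalize_amplitude(cyc, bins)
  # brute-force recomputation of bin means on the normalized envelope
  for (i in 1:8) {
    m <- vapply(1:6, function(b) {
      # same half-open convention, with the documented edge tolerance
      cols <- which(0:100 >= bins$bin_edges_pct[b] - 1e-9 &
                    (if (b < 6) 0:100 < bins$bin_edges_pct[b + 1] - 1e-9
                     else 0:100 <= 100))
      mean(norm$matrix[i, cols])
    }, numeric(1))
    expect_equal(max(m), 1, tolerance = 1e-12)
  }
  # idempotence
  bins2 <- bin_average(norm, ev)
  norm2 <- normalize_amplitude(norm, bins2)
  expect_equal(norm2$matrix, norm$matrix, tolerance = 1e-12)
})

test_that("all-zero channels error by default and drop on request", {
  ev <- make_exact_events(10)
  mat <- matrix(runif(8 * 101, 0.1, 1), 8, 101)
  mat[3, ] <- 0
  rownames(mat) <- modwalk_muscles()
  cyc <- cycle_envelope(mat, 10)
  bins <- bin_average(cyc, ev)
  expect_error(normalize_amplitude(cyc, bins), class = "zero_channel")
  expect_warning(norm <- normalize_amplitude(cyc, bins, on_zero = "drop"),
                 "MG")
  expect_equal(nrow(norm$matrix), 7)
})
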
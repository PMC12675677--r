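test_that("templates are 200 ms, peak-centered, and averaging is well-behaved", {
  tpl <- TPL$carotid
  expect_equal(length(tpl$samples), round(0.2 * FS))
  expect_lte(abs(which.max(tpl$samples) - (round(0.2 * FS) %/% 2 + 1)), 1)

  # average of one epoch is that epoch cropped around its peak
  acc <- cape:::acceleration_chain(
    c(numeric(3000), canonical_pulse(FS), numeric(3000)), FS, filter_spec())
  t1 <- build_template(list(acc), FS)
  p <- which.max(acc)
  expect_equal(t1$samples, acc[(p - 1000):(p + 999)])
  # idempotent for identical epochs
  t2 <- build_template(list(acc, acc), FS)
  expect_equal(t2$samples, t1$samples)
  # time-shifted copies of one pulse collapse to the same template
  t3 <- build_template(list(acc, c(numeric(137), acc)), FS)
  expect_lt(max(abs(t3$samples - t1$samples)), 1e-9)
})

test_that("epochs too short to crop raise an input error", {
  e <- c(numeric(100), 1, numeric(100))  # peak too close to the edges
  expect_error(build_template(list(e), FS), class = "cape_input_error")
})

test_that("template files round-trip", {
  path <- file.path(tempdir(), "tpl.txt")
  write_template(TPL$femoral, path)
  back <- read_template(path)
  expect_identical(back$site, "femoral")
  expect_equal(back$fs, FS)
  expect_equal(back$samples, TPL$femoral$samples)
  unlink(path)
})

test_that("sliding cross-correlation matches the matched-filter picture", {
  y <- TPL$carotid$samples
  tr <- sliding_cross_correlation(y, TPL$carotid)
  expect_equal(tr$n_lags, 1)
  expect_equal(tr$values[1], sum(y^2), tolerance = 1e-12)

  x <- c(numeric(500), y, numeric(300))
  tr2 <- sliding_cross_correlation(x, TPL$carotid)
  expect_equal(tr2$n_lags, length(x) - length(y) + 1)
  expect_equal(which.max(tr2$values), 501)

  expect_error(sliding_cross_correlation(y[1:10], TPL$carotid),
               class = "cape_input_error")
})

test_that("FFT trace equals the brute-force two-loop oracle", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(500:4000, 1)
    m <- sample(50:300, 1)
    x <- rnorm(n); y <- rnorm(m)
    tr <- sliding_cross_correlation(x, y)
    bf <- brute_xcorr(x, y)
    expect_lt(max(abs(tr$values - bf)) / max(abs(bf)), 1e-9)
  }
})

test_that("the CCT is K times the mean absolute correlation", {
  c0 <- 0.37
  expect_equal(compute_cct(c(c0, -c0, c0, -c0), K = 2), 2 * c0)
  expect_equal(compute_cct(rnorm(10), K = 0), 0)
  set.seed(42)
  v <- rnorm(1000)
  acc_sum <- 0
  for (vi in v) acc_sum <- acc_sum + abs(vi)  # independent summation
  expect_equal(compute_cct(v, K = 2.5), 2.5 * acc_sum / 1000,
               tolerance = 1e-12)
  expect_error(compute_cct(numeric(0), K = 1), class = "cape_input_error")
})

test_that("clean pulse trains are detected beat-for-beat within 2 ms", {
  sim <- quick_sim(duration = 10.6, seed = 43, noise_sd = 0, ptt_mod_amp = 0)
  acc <- displacement_to_acceleration(sim$recording)
  truth_t <- sim$truth$carotid_fiducials[, 1]
  expect_equal(length(truth_t), 10)
  det <- detect_fiducials(acc$channels[1, ], TPL$carotid,
                          detection_config(K = 2.5), fs = FS)
  expect_equal(nrow(det), 10)
  expect_lt(max(abs(det$time - truth_t)), 2e-3)
})

test_that("noise-only and all-zero channels yield (near) nothing", {
  set.seed(44)
  acc <- cape:::acceleration_chain(rnorm(20 * FS, 0, 0.1), FS, filter_spec())
  det <- detect_fiducials(acc, TPL$carotid, detection_config(K = 5), fs = FS)
  expect_lt(nrow(det), 1)

  det0 <- detect_fiducials(numeric(5 * FS), TPL$carotid,
                           detection_config(), fs = FS)
  expect_equal(nrow(det0), 0)
})

test_that("raw-mode detection is exactly invariant to amplitude scaling", {
  sim <- quick_sim(duration = 6, seed = 45)
  acc <- displacement_to_acceleration(sim$recording)
  d1 <- detect_fiducials(acc$channels[1, ], TPL$carotid,
                         detection_config(), fs = FS)
  d2 <- detect_fiducials(3.7 * acc$channels[1, ], TPL$carotid,
                         detection_config(), fs = FS)
  expect_equal(d1$index, d2$index)
  expect_equal(d1$time, d2$time, tolerance = 1e-9)
})

test_that("raising K never adds detections", {
  sim <- quick_sim(duration = 10, seed = 46)
  acc <- displacement_to_acceleration(sim$recording)
  tr <- sliding_cross_correlation(acc$channels[7, ], TPL$femoral)
  counts <- sapply(seq(1, 5, by = 0.5), function(K)
    nrow(detect_fiducials(acc$channels[7, ], TPL$femoral,
                          detection_config(K = K), fs = FS, trace = tr)))
  expect_true(all(diff(counts) <= 0))
})
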
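mk_beat <- function(i, t, delays) {
  list(beat = i, beat_time = t, n_carotid = 6, n_femoral = 6,
       k = length(delays), delays = delays)
}

test_that("per-beat PTT is the sample median of the delays", {
  expect_equal(beat_ptt(c(0.060, 0.070, 0.080)), 0.070)
  expect_equal(beat_ptt(c(0.060, 0.070, 0.080, 0.090)), 0.075)
  expect_equal(beat_ptt(c(rep(0.070, 35), 0.200)), 0.070)
  expect_error(beat_ptt(numeric(0)), class = "cape_input_error")
})

test_that("the beat gate retains k >= BQT and discards below", {
  beats <- list(mk_beat(1, 1, rep(0.07, 14)),
                mk_beat(2, 2, rep(0.07, 15)),
                mk_beat(3, 3, rep(0.07, 36)))
  bt <- apply_bqt(beats, quality_config(bqt = 15, rqt = 1))
  expect_equal(bt$passed_bqt, c(FALSE, TRUE, TRUE))
  expect_true(is.na(bt$ptt_hbeat[1]))
  expect_equal(bt$ptt_hbeat[2], 0.07)
})

test_that("the four aggregators implement outer-of-inner statistics", {
  sym <- c(0.06, 0.07, 0.08)
  beats <- lapply(1:3, function(i) mk_beat(i, i, sym))
  bt <- apply_bqt(beats, quality_config(bqt = 1, rqt = 1))
  for (agg in c("median_median", "median_mean", "mean_median", "mean_mean"))
    expect_equal(overall_ptt(bt, agg), 0.07)

  beats2 <- list(mk_beat(1, 1, rep(0.070, 3)),
                 mk_beat(2, 2, rep(0.072, 3)),
                 mk_beat(3, 3, rep(0.074, 3)))
  bt2 <- apply_bqt(beats2, quality_config(bqt = 1, rqt = 1))
  expect_equal(overall_ptt(bt2, "median_median"), 0.072)
  expect_error(overall_ptt(bt2[0, ], "median_median"),
               class = "cape_input_error")
})

test_that("median_median resists gross outlier pairs better than mean_mean", {
  set.seed(61)
  truth <- 0.070
  # 20 beats, 36 pairs each, 10% of pairs replaced by gross outliers
  beats <- lapply(1:20, function(i) {
    d <- rnorm(36, truth, 0.001)
    n_out <- rbinom(1, 36, 0.1)
    if (n_out > 0) d[seq_len(n_out)] <- 0.200
    mk_beat(i, i, d)
  })
  bt <- apply_bqt(beats, quality_config(bqt = 1, rqt = 1))
  err_mm <- abs(overall_ptt(bt, "median_median") - truth)
  err_uu <- abs(overall_ptt(bt, "mean_mean") - truth)
  expect_lt(err_mm, err_uu)
})

test_that("PWV follows 0.8 d / PTT and the recording gate withholds", {
  beats10 <- lapply(1:10, function(i) mk_beat(i, i, rep(0.1, 20)))
  geom <- list(distance_d = 1.0)
  est <- estimate_recording(beats10, quality_config(bqt = 15, rqt = 10),
                            geom)
  expect_equal(est$pwv, 8.0)
  expect_equal(est$pwv * est$overall_ptt, 0.8 * geom$distance_d)

  est15 <- estimate_recording(beats10, quality_config(bqt = 15, rqt = 15),
                              geom)
  expect_true(is.na(est15$overall_ptt))
  expect_identical(est15$confidence, "unreliable")
  expect_equal(est15$n_beats_valid, 10)
})

test_that("confidence labels follow the matched preset", {
  beats <- lapply(1:16, function(i) mk_beat(i, i, rep(0.07, 20)))
  geom <- list(distance_d = 0.5)
  expect_identical(
    estimate_recording(beats, quality_preset("excellent"), geom)$confidence,
    "excellent")
  expect_identical(
    estimate_recording(beats, quality_preset("acceptable"), geom)$confidence,
    "acceptable")
  expect_identical(
    estimate_recording(beats, quality_config(K = 3, bqt = 10, rqt = 5),
                       geom)$confidence,
    "custom")
})

test_that("raising BQT or RQT never gains valid beats or availability", {
  set.seed(62)
  beats <- lapply(1:20, function(i)
    mk_beat(i, i, rnorm(sample(5:36, 1), 0.07, 0.002)))
  prev_valid <- Inf
  for (bqt in c(10, 15, 20)) {
    bt <- apply_bqt(beats, quality_config(bqt = bqt, rqt = 1))
    expect_lte(sum(bt$passed_bqt), prev_valid)
    prev_valid <- sum(bt$passed_bqt)
    prev_avail <- TRUE
    for (rqt in c(5, 10, 15)) {
      est <- estimate_recording(beats, quality_config(bqt = bqt, rqt = rqt),
                                list(distance_d = 0.5))
      avail <- !is.na(est$pwv)
      expect_true(prev_avail || !avail)  # availability can only shrink
      prev_avail <- avail
    }
  }
})

test_that("overall PTT lies within the span of per-beat PTTs", {
  set.seed(63)
  beats <- lapply(1:15, function(i) mk_beat(i, i, rnorm(20, 0.07, 0.003)))
  bt <- apply_bqt(beats, quality_config(bqt = 1, rqt = 1))
  for (agg in c("median_median", "mean_median"))
    expect_true(overall_ptt(bt, agg) >= min(bt$ptt_hbeat) &&
                overall_ptt(bt, agg) <= max(bt$ptt_hbeat))
})

test_that("the trend interpolates interior gaps and flags them", {
  beats <- list(mk_beat(1, 1, rep(0.070, 20)),
                mk_beat(2, 2, rep(0.070, 5)),     # fails BQT
                mk_beat(3, 3, rep(0.074, 20)))
  bt <- apply_bqt(beats, quality_config(bqt = 15, rqt = 1))
  tr <- beat_trend(bt)
  expect_equal(tr$ptt[2], 0.072)
  expect_identical(tr$status, c("observed", "interpolated", "observed"))

  # no gaps -> identity
  beats2 <- beats[c(1, 3)]
  tr2 <- beat_trend(apply_bqt(beats2, quality_config(bqt = 15, rqt = 1)))
  expect_identical(tr2$status, c("observed", "observed"))
  expect_equal(tr2$ptt, c(0.070, 0.074))

  # fewer than two valid beats -> no interpolation, gaps stay missing
  beats3 <- list(mk_beat(1, 1, rep(0.07, 20)),
                 mk_beat(2, 2, rep(0.07, 5)))
  tr3 <- beat_trend(apply_bqt(beats3, quality_config(bqt = 15, rqt = 1)))
  expect_identical(tr3$status, c("observed", "missing"))

  # leading/trailing gaps stay empty
  beats4 <- list(mk_beat(1, 1, rep(0.07, 5)),
                 mk_beat(2, 2, rep(0.07, 20)),
                 mk_beat(3, 3, rep(0.07, 20)),
                 mk_beat(4, 4, rep(0.07, 5)))
  tr4 <- beat_trend(apply_bqt(beats4, quality_config(bqt = 15, rqt = 1)))
  expect_identical(tr4$status,
                   c("missing", "observed", "observed", "missing"))
})
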
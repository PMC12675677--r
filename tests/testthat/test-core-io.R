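test_that("recording round-trips through CSV + sidecar unchanged", {
  sim <- quick_sim(duration = 2, seed = 11)
  rec <- sim$recording
  path <- file.path(tempdir(), "rt.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$channels, rec$channels, tolerance = 1e-12)
  expect_identical(back$site_map, rec$site_map)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$geometry$distance_d, rec$geometry$distance_d)
  expect_identical(back$subject_id, rec$subject_id)
  expect_equal(back$duration, ncol(rec$channels) / rec$fs)
  unlink(c(path, cape:::meta_path_for(path)))
})

test_that("duration is sample count over sampling rate", {
  rec <- ldv_recording(matrix(0, 12, 5000),
                       rep(c("carotid", "femoral"), each = 6),
                       fs = 10000, distance_d = 0.5)
  expect_equal(rec$duration, 0.5)
})

test_that("missing sidecar fields are configuration errors naming the field", {
  sim <- quick_sim(duration = 1, seed = 12)
  path <- file.path(tempdir(), "mf.csv")
  mp <- write_recording(sim$recording, path)
  meta <- jsonlite::read_json(mp)
  meta$distance_d <- NULL
  jsonlite::write_json(meta, mp, auto_unbox = TRUE)
  expect_error(read_recording(path), "distance_d",
               class = "cape_config_error")
  unlink(c(path, mp))
})

test_that("format validation rejects inconsistent inputs", {
  ch <- matrix(0, 4, 100)
  # site map not partitioning channels into the two sites
  expect_error(ldv_recording(ch, c("carotid", "carotid", "x", "femoral"),
                             distance_d = 0.5),
               class = "cape_format_error")
  expect_error(ldv_recording(ch, rep("carotid", 4), distance_d = 0.5),
               class = "cape_format_error")
  # channel count vs site map length
  expect_error(ldv_recording(ch, rep("carotid", 3), distance_d = 0.5),
               class = "cape_format_error")
  # geometry sanity bound
  expect_error(ldv_recording(ch, c("carotid", "carotid", "femoral", "femoral"),
                             distance_d = 2.0),
               class = "cape_config_error")
  # partial recordings are accepted with a warning and flagged
  expect_warning(
    rec <- ldv_recording(ch, c("carotid", "carotid", "femoral", "femoral"),
                         distance_d = 0.5),
    "partial")
  expect_false(rec$full_device)
})

test_that("non-uniform time step is a format error", {
  sim <- quick_sim(duration = 1, seed = 13)
  path <- file.path(tempdir(), "jit.csv")
  mp <- write_recording(sim$recording, path)
  tab <- data.table::fread(path)
  tab$time[5] <- tab$time[5] + 0.5 / sim$recording$fs
  data.table::fwrite(tab, path)
  expect_error(read_recording(path), class = "cape_format_error")
  unlink(c(path, mp))
})

test_that("results round-trip and record the per-beat table and grade", {
  sim <- quick_sim(duration = 6, seed = 14)
  bundle <- estimate_pwv(sim$recording,
                         quality_config(bqt = 15, rqt = 3),
                         templates = TPL)
  path <- file.path(tempdir(), "res.cape.json")
  write_results(bundle, path)
  back <- read_results(path)
  expect_equal(back$recording_estimate$overall_ptt,
               bundle$recording_estimate$overall_ptt)
  expect_equal(back$recording_estimate$pwv, bundle$recording_estimate$pwv)
  expect_identical(back$recording_estimate$confidence,
                   bundle$recording_estimate$confidence)
  expect_equal(back$per_beat$k, bundle$per_beat$k)
  expect_equal(back$per_beat$ptt_hbeat, bundle$per_beat$ptt_hbeat)
  expect_equal(nrow(back$per_beat), nrow(bundle$per_beat))
  expect_equal(unclass(back$config_used), unclass(bundle$config_used))
  unlink(path)
})

test_that("withheld estimates serialize with null PTT/PWV and grade unreliable", {
  sim <- quick_sim(duration = 6, seed = 15)
  bundle <- estimate_pwv(sim$recording, quality_preset("excellent"),
                         templates = TPL)  # ~5 beats < RQT 15
  expect_identical(bundle$recording_estimate$confidence, "unreliable")
  path <- file.path(tempdir(), "wh.cape.json")
  write_results(bundle, path)
  raw <- jsonlite::read_json(path)
  expect_null(raw$overall_ptt)
  expect_null(raw$pwv)
  expect_identical(raw$confidence, "unreliable")
  back <- read_results(path)
  expect_true(is.na(back$recording_estimate$pwv))
  unlink(path)
})
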
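#' Quality configuration
#'
#' The two-level quality gate: a heartbeat is kept only if it contributed at
#' least `bqt` carotid-femoral peak pairs (local, beat quality threshold),
#' and the recording yields an estimate only if at least `rqt` heartbeats
#' pass (global, recording quality threshold). Both comparisons are
#' inclusive (`k >= bqt`, `n_valid >= rqt`). `rqt` is an absolute beat count
#' for a nominal 20 s recording; `rqt_per_20s = TRUE` scales it
#' proportionally for other durations.
#'
#' Two presets mirror the guideline-graded operating points:
#' `"excellent"` = (K = 2.5, BQT = 15, RQT = 15) and
#' `"acceptable"` = (K = 2.5, BQT = 15, RQT = 10).
#'
#' @param K detection tuning factor (see [detection_config()]).
#' @param bqt minimum pairs per beat, in `[1, 36]` (default 15).
#' @param rqt minimum valid beats per recording (default 15).
#' @param aggregator one of `"median_median"` (default), `"median_mean"`,
#'   `"mean_median"`, `"mean_mean"`; outer statistic named first.
#' @param rqt_per_20s logical; scale `rqt` with recording duration.
#' @return an object of class `quality_config`.
#' @export
quality_config <- function(K = 2.5, bqt = 15, rqt = 15,
                           aggregator = c("median_median", "median_mean",
                                          "mean_median", "mean_mean"),
                           rqt_per_20s = FALSE) {
  if (bqt < 1 || bqt > 36) cape_stop("bqt must lie in [1, 36]",
                                     "cape_config_error")
  if (rqt < 1) cape_stop("rqt must be >= 1", "cape_config_error")
  structure(list(K = K, bqt = as.integer(bqt), rqt = as.integer(rqt),
                 aggregator = match.arg(aggregator),
                 rqt_per_20s = isTRUE(rqt_per_20s)),
            class = "quality_config")
}

#' Preset quality configurations
#'
#' @param mode `"excellent"` (K = 2.5, BQT = 15, RQT = 15) or
#'   `"acceptable"` (K = 2.5, BQT = 15, RQT = 10).
#' @param aggregator passed to [quality_config()].
#' @return a `quality_config`.
#' @export
quality_preset <- function(mode = c("excellent", "acceptable"),
                           aggregator = "median_median") {
  mode <- match.arg(mode)
  quality_config(K = 2.5, bqt = 15,
                 rqt = if (mode == "excellent") 15 else 10,
                 aggregator = aggregator)
}

# label for the confidence grade implied by a config (presets only)
config_grade <- function(cfg) {
  if (cfg$K == 2.5 && cfg$bqt == 15 && cfg$rqt == 15) "excellent"
  else if (cfg$K == 2.5 && cfg$bqt == 15 && cfg$rqt == 10) "acceptable"
  else "custom"
}

#' Per-beat PTT: the median of a beat's pair delays
#'
#' @param delays numeric vector of carotid-femoral delays in seconds
#'   (non-empty).
#' @return the sample median (mean of the central two for even counts).
#' @export
beat_ptt <- function(delays) {
  if (length(delays) < 1)
    cape_stop("beat has no delays", "cape_input_error")
  median(delays)
}

#' Apply the beat quality threshold
#'
#' Summarizes each beat and flags it kept (`k >= bqt`) or discarded.
#' Discarded beats stay in the table (they appear as gaps in the trend);
#' their per-beat PTT is `NA`.
#'
#' @param beats list of beats from [match_and_enumerate()].
#' @param cfg a [quality_config()].
#' @return data frame with columns `beat`, `beat_time`, `k`, `ptt_hbeat`
#'   (median delay), `mean_delay`, `passed_bqt`.
#' @export
apply_bqt <- function(beats, cfg = quality_config()) {
  rows <- lapply(beats, function(b) {
    passed <- b$k >= cfg$bqt && b$k > 0
    data.frame(
      beat = b$beat, beat_time = b$beat_time, k = b$k,
      ptt_hbeat = if (passed) beat_ptt(b$delays) else NA_real_,
      mean_delay = if (passed) mean(b$delays) else NA_real_,
      passed_bqt = passed)
  })
  if (!length(rows))
    return(data.frame(beat = integer(0), beat_time = numeric(0),
                      k = integer(0), ptt_hbeat = numeric(0),
                      mean_delay = numeric(0), passed_bqt = logical(0)))
  do.call(rbind, rows)
}

#' Overall PTT over the valid beats
#'
#' The four aggregators combine an outer statistic over beats with an inner
#' statistic over each beat's pair delays: `mean_mean` (mean of per-beat
#' means), `mean_median` (mean of per-beat medians), `median_mean` (median
#' of per-beat means) and `median_median` (median of per-beat medians, the
#' default and most outlier-robust choice).
#'
#' @param beat_table output of [apply_bqt()], or any data frame with
#'   `ptt_hbeat`, `mean_delay` and `passed_bqt` columns.
#' @param aggregator aggregator name (outer statistic first).
#' @return overall PTT in seconds.
#' @export
overall_ptt <- function(beat_table, aggregator = "median_median") {
  valid <- beat_table[beat_table$passed_bqt, , drop = FALSE]
  if (nrow(valid) < 1)
    cape_stop("no valid beats to aggregate", "cape_input_error")
  inner <- switch(aggregator,
                  median_median = , mean_median = valid$ptt_hbeat,
                  median_mean = , mean_mean = valid$mean_delay,
                  cape_stop("unknown aggregator", "cape_config_error"))
  outer_fun <- if (startsWith(aggregator, "median")) median else mean
  outer_fun(inner)
}

#' Beat-to-beat PTT trend
#'
#' Time-indexed per-beat PTT series. Beats discarded by the quality gate are
#' filled by linear interpolation between the neighbouring valid beats to
#' keep the trend continuous, and flagged `"interpolated"`; leading and
#' trailing gaps are left empty (`NA`, flagged `"missing"`).
#'
#' @param beat_table output of [apply_bqt()].
#' @return data frame with columns `beat`, `time`, `ptt`, `status` in
#'   `{"observed", "interpolated", "missing"}`.
#' @export
beat_trend <- function(beat_table) {
  tr <- data.frame(beat = beat_table$beat, time = beat_table$beat_time,
                   ptt = beat_table$ptt_hbeat,
                   status = ifelse(beat_table$passed_bqt, "observed",
                                   "missing"))
  valid <- which(beat_table$passed_bqt)
  if (length(valid) >= 2) {
    inner <- setdiff(seq(min(valid), max(valid)), valid)
    if (length(inner)) {
      tr$ptt[inner] <- approx(x = tr$time[valid], y = tr$ptt[valid],
                              xout = tr$time[inner])$y
      tr$status[inner] <- "interpolated"
    }
  }
  tr
}

#' Estimate PTT, PWV and confidence for a recording
#'
#' Applies the recording quality threshold: with at least `rqt` valid beats
#' the overall PTT is aggregated and converted to pulse wave velocity as
#' `PWV = 0.8 * d / PTT` (d the straight carotid-femoral distance; 0.8 the
#' consensus path-length correction factor), and the confidence grade is the
#' preset the configuration matches (excellent/acceptable, else "custom").
#' Otherwise the estimate is withheld and the grade is `"unreliable"`.
#'
#' @param beats list of beats from [match_and_enumerate()], or a beat table
#'   from [apply_bqt()].
#' @param cfg a [quality_config()].
#' @param geometry list with `distance_d` in metres (as in an
#'   `ldv_recording`'s `geometry`).
#' @param duration recording duration in seconds; used only when
#'   `cfg$rqt_per_20s` is set.
#' @return an object of class `recording_estimate` with fields
#'   `n_beats_total`, `n_beats_valid`, `overall_ptt`, `pwv`, `confidence`,
#'   `trend`, and the `beat_table`.
#' @export
estimate_recording <- function(beats, cfg = quality_config(), geometry,
                               duration = 20) {
  beat_table <- if (is.data.frame(beats)) beats else apply_bqt(beats, cfg)
  n_valid <- sum(beat_table$passed_bqt)
  rqt_eff <- if (cfg$rqt_per_20s) ceiling(cfg$rqt * duration / 20) else cfg$rqt
  if (n_valid >= rqt_eff) {
    ptt <- overall_ptt(beat_table, cfg$aggregator)
    if (ptt <= 0)
      cape_stop("non-positive overall PTT", "cape_internal_error")
    pwv <- 0.8 * geometry$distance_d / ptt
    confidence <- config_grade(cfg)
  } else {
    ptt <- NA_real_
    pwv <- NA_real_
    confidence <- "unreliable"
  }
  structure(list(
    n_beats_total = nrow(beat_table),
    n_beats_valid = n_valid,
    overall_ptt = ptt,
    pwv = pwv,
    confidence = confidence,
    trend = beat_trend(beat_table),
    beat_table = beat_table
  ), class = "recording_estimate")
}

#' @export
print.recording_estimate <- function(x, ...) {
  if (is.na(x$overall_ptt)) {
    cat(sprintf("<recording_estimate> withheld (unreliable): %d/%d valid beats\n",
                x$n_beats_valid, x$n_beats_total))
  } else {
    cat(sprintf(
      "<recording_estimate> PTT = %.1f ms, PWV = %.2f m/s [%s], %d/%d valid beats\n",
      1000 * x$overall_ptt, x$pwv, x$confidence,
      x$n_beats_valid, x$n_beats_total))
  }
  invisible(x)
}

#' Full pipeline: displacement recording to PTT/PWV estimate
#'
#' Runs preprocessing (acceleration), template-matching fiducial detection,
#' beat clustering and pair enumeration, the BQT/RQT quality gate and the
#' final aggregation, returning a [result_bundle()].
#'
#' @param rec a displacement `ldv_recording`.
#' @param quality a [quality_config()]; its `K` drives detection.
#' @param templates optional named templates list (see
#'   [detect_all_fiducials()]).
#' @param pairing a [pairing_config()].
#' @param filter a [filter_spec()].
#' @param detection optional [detection_config()]; defaults to
#'   `detection_config(K = quality$K)`.
#' @param input_path recorded in provenance.
#' @return a `result_bundle`.
#' @export
estimate_pwv <- function(rec, quality = quality_config(), templates = NULL,
                         pairing = pairing_config(), filter = filter_spec(),
                         detection = NULL, input_path = NA_character_) {
  stopifnot(inherits(rec, "ldv_recording"))
  if (is.null(detection)) detection <- detection_config(K = quality$K)
  acc <- if (rec$units == "acceleration") rec
         else displacement_to_acceleration(rec, filter)
  beats <- extract_beats(acc, templates, detection, pairing)
  est <- estimate_recording(beats, quality, rec$geometry,
                            duration = rec$duration)
  result_bundle(est, est$beat_table, quality, input_path = input_path)
}
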
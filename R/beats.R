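#' Pairing configuration
#'
#' Beat segmentation is ECG-free: fiducial peaks from one site are grouped
#' into heartbeats by single-linkage temporal clustering (gap `beat_gap`),
#' and each carotid beat is matched to the femoral beat whose median time
#' falls inside the physiological transit window `[delay_min, delay_max]`
#' after its own. The default window (20-250 ms) covers PWV of roughly
#' 4-20 m/s over typical corrected carotid-femoral path lengths.
#'
#' @param beat_gap clustering gap threshold in seconds (default 0.3).
#' @param delay_min,delay_max carotid-to-femoral transit window in seconds
#'   (defaults 0.02 and 0.25).
#' @return an object of class `pairing_config`.
#' @export
pairing_config <- function(beat_gap = 0.3, delay_min = 0.02,
                           delay_max = 0.25) {
  if (beat_gap <= 0) cape_stop("beat_gap must be positive",
                               "cape_config_error")
  if (!(0 < delay_min && delay_min < delay_max))
    cape_stop("need 0 < delay_min < delay_max", "cape_config_error")
  structure(list(beat_gap = beat_gap, delay_min = delay_min,
                 delay_max = delay_max), class = "pairing_config")
}

#' Cluster one site's fiducial peaks into heartbeats
#'
#' Single-linkage clustering in time: a new cluster starts wherever the gap
#' between consecutive peaks exceeds `beat_gap`. If one channel contributed
#' more than one peak to a cluster, the peak with the higher correlation
#' score is kept (earlier time wins a tie), so each cluster has at most one
#' peak per channel.
#'
#' @param peaks data frame as returned by [detect_all_fiducials()],
#'   restricted to one site.
#' @param cfg a [pairing_config()].
#' @return list of data frames (one per cluster, time-ordered), each with an
#'   attribute `median_time`.
#' @export
cluster_peaks <- function(peaks, cfg = pairing_config()) {
  if (nrow(peaks) == 0) return(list())
  peaks <- peaks[order(peaks$time), , drop = FALSE]
  cl_id <- cumsum(c(1, diff(peaks$time) > cfg$beat_gap))
  lapply(split(peaks, cl_id), function(cl) {
    # one peak per channel: highest cc_score, earlier time at equal score
    cl <- cl[order(cl$channel, -cl$cc_score, cl$time), , drop = FALSE]
    cl <- cl[!duplicated(cl$channel), , drop = FALSE]
    cl <- cl[order(cl$time), , drop = FALSE]
    attr(cl, "median_time") <- median(cl$time)
    cl
  })
}

#' Match carotid and femoral beats and enumerate cf-peak pairs
#'
#' Each carotid cluster is matched to the femoral cluster whose median time
#' lies within the transit window after its own median; if two qualify the
#' nearer one is taken (a message logs the ambiguity) and a femoral cluster
#' is consumed by at most one carotid cluster. All carotid x femoral peak
#' combinations are then enumerated (up to 6 x 6 = 36 per heartbeat); pairs
#' whose individual delay falls outside the window are dropped, so `k` equals
#' the product of the site peak counts whenever all combinations are
#' physiological. Unmatched carotid clusters yield beats with `k = 0`.
#'
#' @param carotid_clusters,femoral_clusters output of [cluster_peaks()].
#' @param cfg a [pairing_config()].
#' @return list of beats; each beat is a list with `beat`, `beat_time`
#'   (median carotid peak time), `n_carotid`, `n_femoral`, `k`, and `delays`
#'   (femoral minus carotid peak times, seconds).
#' @export
match_and_enumerate <- function(carotid_clusters, femoral_clusters,
                                cfg = pairing_config()) {
  fem_times <- vapply(femoral_clusters, attr, numeric(1), "median_time")
  fem_used <- rep(FALSE, length(femoral_clusters))
  beats <- vector("list", length(carotid_clusters))
  for (i in seq_along(carotid_clusters)) {
    car <- carotid_clusters[[i]]
    tc <- attr(car, "median_time")
    lag <- fem_times - tc
    ok <- which(!fem_used & lag >= cfg$delay_min & lag <= cfg$delay_max)
    delays <- numeric(0)
    n_fem <- 0L
    if (length(ok)) {
      if (length(ok) > 1)
        message(sprintf(
          "beat %d: %d femoral clusters in the transit window; matching the nearer",
          i, length(ok)))
      j <- ok[which.min(lag[ok])]
      fem_used[j] <- TRUE
      fem <- femoral_clusters[[j]]
      n_fem <- nrow(fem)
      delays <- as.vector(outer(car$time, fem$time,
                                function(a, b) b - a))
      delays <- delays[delays >= cfg$delay_min & delays <= cfg$delay_max]
    }
    beats[[i]] <- list(beat = i, beat_time = tc, n_carotid = nrow(car),
                       n_femoral = n_fem, k = length(delays),
                       delays = delays)
  }
  beats
}

#' Detect and pair beats for a whole recording
#'
#' Convenience wrapper: fiducial detection on every channel, per-site
#' clustering and carotid-femoral pair enumeration.
#'
#' @param acc_rec an acceleration `ldv_recording`.
#' @param templates optional named templates list (see
#'   [detect_all_fiducials()]).
#' @param detection a [detection_config()].
#' @param pairing a [pairing_config()].
#' @return list of beats as from [match_and_enumerate()].
#' @export
extract_beats <- function(acc_rec, templates = NULL,
                          detection = detection_config(),
                          pairing = pairing_config()) {
  peaks <- detect_all_fiducials(acc_rec, templates, detection)
  car <- cluster_peaks(peaks[peaks$site == "carotid", , drop = FALSE], pairing)
  fem <- cluster_peaks(peaks[peaks$site == "femoral", , drop = FALSE], pairing)
  match_and_enumerate(car, fem, pairing)
}
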
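#' Construct an LDV recording
#'
#' An `ldv_recording` holds aligned skin-displacement channels from the two
#' measurement sites (carotid and femoral), the sampling rate and the
#' measurement geometry. A full-device recording has six channels per site;
#' recordings with fewer channels are accepted with a warning and flagged as
#' partial (the 36-pair cap per heartbeat simply shrinks).
#'
#' Displacement amplitude is treated as arbitrary units: all downstream
#' computation is timing- and threshold-relative, so the absolute scale of
#' the demodulated displacement never enters the PTT/PWV arithmetic.
#'
#' @param channels numeric matrix, one row per channel, one column per sample.
#' @param site_map character vector, one of `"carotid"`/`"femoral"` per channel.
#' @param fs sampling rate in Hz (default 10000).
#' @param distance_d straight carotid-to-femoral distance in metres.
#' @param subject_id opaque identifier string.
#' @param units `"displacement"` or `"acceleration"`.
#' @return an object of class `ldv_recording`.
#' @export
ldv_recording <- function(channels, site_map, fs = 10000, distance_d,
                          subject_id = "anonymous", units = "displacement") {
  if (!is.matrix(channels) || !is.numeric(channels))
    cape_stop("`channels` must be a numeric matrix (one row per channel)",
              "cape_format_error")
  if (length(site_map) != nrow(channels))
    cape_stop(sprintf("site_map length (%d) does not match channel count (%d)",
                      length(site_map), nrow(channels)), "cape_format_error")
  if (!all(site_map %in% c("carotid", "femoral")))
    cape_stop("site_map entries must be 'carotid' or 'femoral'",
              "cape_format_error")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    cape_stop("fs must be a single positive number", "cape_config_error")
  if (missing(distance_d) || is.null(distance_d))
    cape_stop("measurement geometry field 'distance_d' is missing",
              "cape_config_error")
  if (!is.numeric(distance_d) || distance_d <= 0 || distance_d >= 1.5)
    cape_stop("distance_d must be in (0, 1.5) metres", "cape_config_error")
  n_car <- sum(site_map == "carotid")
  n_fem <- sum(site_map == "femoral")
  if (n_car == 0 || n_fem == 0)
    cape_stop("site_map must include both a carotid and a femoral site",
              "cape_format_error")
  full_device <- (n_car == 6 && n_fem == 6)
  if (!full_device)
    warning(sprintf(
      "partial recording: %d carotid + %d femoral channels (full device is 6 + 6)",
      n_car, n_fem), call. = FALSE)
  structure(list(
    channels = channels,
    site_map = as.character(site_map),
    fs = fs,
    duration = ncol(channels) / fs,
    geometry = list(distance_d = distance_d),
    subject_id = subject_id,
    units = match.arg(units, c("displacement", "acceleration")),
    full_device = full_device
  ), class = "ldv_recording")
}

#' @export
print.ldv_recording <- function(x, ...) {
  cat(sprintf("<ldv_recording> %s: %d channels (%d carotid, %d femoral), %s\n",
              x$subject_id, nrow(x$channels),
              sum(x$site_map == "carotid"), sum(x$site_map == "femoral"),
              x$units))
  cat(sprintf("  fs = %g Hz, duration = %.3f s, d = %.3f m%s\n",
              x$fs, x$duration, x$geometry$distance_d,
              if (x$full_device) "" else " [partial]"))
  invisible(x)
}

#' Channel indices for one measurement site
#'
#' @param rec an `ldv_recording`.
#' @param site `"carotid"` or `"femoral"`.
#' @return integer vector of row indices into `rec$channels`.
#' @export
site_channels <- function(rec, site) {
  which(rec$site_map == match.arg(site, c("carotid", "femoral")))
}

meta_path_for <- function(path) sub("\\.[^.]+$", "", path) |> paste0(".meta.json")

#' Write a recording to disk
#'
#' Writes `<path>` as a delimited table (first column `time` in seconds,
#' remaining columns one per channel, named `<site>_<i>`) plus a JSON metadata
#' sidecar `<stem>.meta.json` holding the sampling rate, site map, geometry
#' and subject id.
#'
#' @param rec an `ldv_recording`.
#' @param path output CSV path; the sidecar path is derived from it.
#' @return invisibly, the sidecar path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ldv_recording"))
  n <- ncol(rec$channels)
  idx_in_site <- stats::ave(seq_along(rec$site_map), rec$site_map,
                            FUN = seq_along)
  ch_names <- sprintf("%s_%d", rec$site_map, idx_in_site)
  tab <- data.table::as.data.table(t(rec$channels))
  data.table::setnames(tab, ch_names)
  tab <- cbind(data.table::data.table(time = (seq_len(n) - 1) / rec$fs), tab)
  data.table::fwrite(tab, path)
  meta <- list(fs = rec$fs, site_map = rec$site_map,
               distance_d = rec$geometry$distance_d,
               subject_id = rec$subject_id, units = rec$units)
  mp <- meta_path_for(path)
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. The time column is checked for uniform
#' spacing consistent with the declared sampling rate (more than 1% jitter in
#' the time step is rejected as a format error).
#'
#' @param path CSV path (first column time in seconds, then channels).
#' @param meta_path JSON sidecar path; by default derived from `path`.
#' @return an `ldv_recording`.
#' @export
read_recording <- function(path, meta_path = meta_path_for(path)) {
  if (!file.exists(meta_path))
    cape_stop(sprintf("metadata sidecar not found: %s", meta_path),
              "cape_config_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fs", "site_map", "distance_d")) {
    if (is.null(meta[[f]]))
      cape_stop(sprintf("sidecar is missing required field '%s'", f),
                "cape_config_error")
  }
  tab <- data.table::fread(path)
  if (ncol(tab) < 2)
    cape_stop("recording table needs a time column plus at least one channel",
              "cape_format_error")
  tstep <- diff(tab[[1]])
  if (length(tstep) && any(abs(tstep - 1 / meta$fs) > 0.01 / meta$fs))
    cape_stop("non-uniform time step (> 1% jitter) in recording table",
              "cape_format_error")
  channels <- t(as.matrix(tab[, -1]))
  dimnames(channels) <- NULL
  if (nrow(channels) != length(meta$site_map))
    cape_stop(sprintf("channel count (%d) does not match sidecar site_map (%d)",
                      nrow(channels), length(meta$site_map)),
              "cape_format_error")
  ldv_recording(channels, meta$site_map, fs = meta$fs,
                distance_d = meta$distance_d,
                subject_id = meta$subject_id %||% "anonymous",
                units = meta$units %||% "displacement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle an estimate with its provenance
#'
#' @param recording_estimate a `recording_estimate` (see [estimate_recording()]).
#' @param per_beat per-beat data frame (beat, time, k, ptt, kept flag).
#' @param config_used the `quality_config` used.
#' @param input_path path of the source recording, if any.
#' @return an object of class `result_bundle`.
#' @export
result_bundle <- function(recording_estimate, per_beat, config_used,
                          input_path = NA_character_) {
  structure(list(
    recording_estimate = recording_estimate,
    per_beat = as.data.frame(per_beat),
    config_used = config_used,
    provenance = list(
      input_path = input_path,
      software = sprintf("cape %s", as.character(packageVersion("cape"))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  print(x$recording_estimate)
  cat(sprintf("  beats: %d total, %d kept\n",
              nrow(x$per_beat), sum(x$per_beat$passed_bqt)))
  invisible(x)
}

#' Write results to disk
#'
#' Serializes a [result_bundle()] to a JSON results file (`<name>.cape.json`
#' by convention): overall PTT (s), PWV (m/s), confidence grade, number of
#' valid beats, and the per-beat table (beat index, time, pair count k, PTT,
#' kept/discarded flag). A withheld estimate is stored with `null` PTT/PWV
#' and grade `"unreliable"`.
#'
#' @param bundle a `result_bundle`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  est <- bundle$recording_estimate
  out <- list(
    overall_ptt = est$overall_ptt,   # NA serializes as null
    pwv = est$pwv,
    confidence = est$confidence,
    n_beats_total = est$n_beats_total,
    n_beats_valid = est$n_beats_valid,
    per_beat = bundle$per_beat,
    trend = est$trend,
    config = unclass(bundle$config_used),
    provenance = bundle$provenance
  )
  ok <- tryCatch({
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cape_stop(sprintf("cannot write results to '%s'", path),
                     "cape_io_error")
  invisible(path)
}

#' Read results from disk
#'
#' @param path a results file written by [write_results()].
#' @return a `result_bundle`.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(quality_config, x$config[c("K", "bqt", "rqt", "aggregator")])
  est <- structure(list(
    n_beats_total = x$n_beats_total,
    n_beats_valid = x$n_beats_valid,
    overall_ptt = x$overall_ptt %||% NA_real_,
    pwv = x$pwv %||% NA_real_,
    confidence = x$confidence,
    trend = as.data.frame(x$trend)
  ), class = "recording_estimate")
  bundle <- result_bundle(est, as.data.frame(x$per_beat), cfg,
                          input_path = x$provenance$input_path)
  bundle$provenance <- x$provenance
  bundle
}
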
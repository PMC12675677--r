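#' Build an acceleration template
#'
#' Templates are 200 ms acceleration epochs centered on their peak, built by
#' re-centering each supplied epoch on its unique global maximum, cropping to
#' 200 ms and averaging sample-wise. One template per site (carotid, femoral)
#' is used during detection; the same tuning factor K applies to both.
#'
#' @param epochs list of numeric acceleration epochs, each at least 200 ms
#'   long with a unique global maximum.
#' @param fs sampling rate in Hz.
#' @param site `"carotid"` or `"femoral"`.
#' @param span_s template span in seconds (200 ms; fixed by design, exposed
#'   for testing only).
#' @return an object of class `pulse_template`.
#' @export
build_template <- function(epochs, fs, site = "carotid", span_s = 0.2) {
  site <- match.arg(site, c("carotid", "femoral"))
  if (!is.list(epochs) || length(epochs) < 1)
    cape_stop("need at least one epoch", "cape_input_error")
  m <- round(span_s * fs)
  half <- m %/% 2
  cropped <- lapply(epochs, function(e) {
    p <- which(e == max(e))
    if (length(p) != 1)
      cape_stop("epoch does not have a unique global maximum",
                "cape_input_error")
    lo <- p - half
    hi <- lo + m - 1
    if (lo < 1 || hi > length(e))
      cape_stop("epoch shorter than the template span after centering on its peak",
                "cape_input_error")
    e[lo:hi]
  })
  samples <- Reduce(`+`, cropped) / length(cropped)
  out <- structure(list(samples = samples, fs = fs, site = site),
                   class = "pulse_template")
  ctr <- which.max(samples)
  if (abs(ctr - (half + 1)) > 1)
    cape_stop("averaged template peak is not at the center sample",
              "cape_input_error")
  out
}

#' @export
print.pulse_template <- function(x, ...) {
  cat(sprintf("<pulse_template> site %s, %d samples (%.0f ms) at %g Hz\n",
              x$site, length(x$samples), 1000 * length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Default site templates derived from the canonical synthetic pulse
#'
#' The clinical template epochs travel with the device, so the package ships
#' templates derived from [canonical_pulse()]: the pulse is embedded in a
#' zero-padded trace, run through the same filtering/differentiation chain as
#' real data, and cropped to 200 ms around its acceleration peak. Users with
#' device templates should supply their own via [read_template()].
#'
#' @param site `"carotid"` or `"femoral"`.
#' @param fs sampling rate in Hz.
#' @param spec the [filter_spec()] used for the acceleration chain.
#' @return a `pulse_template`.
#' @export
default_template <- function(site = "carotid", fs = 10000,
                             spec = filter_spec()) {
  pad <- numeric(round(0.3 * fs))
  trace <- c(pad, canonical_pulse(fs), pad)
  acc <- acceleration_chain(trace, fs, spec)
  build_template(list(acc), fs, site = site)
}

#' Write / read a template file
#'
#' Plain-text format: first line a JSON header (`site`, `fs`), then one
#' sample per line.
#'
#' @param template a `pulse_template`.
#' @param path file path.
#' @return `write_template` invisibly returns `path`; `read_template` returns
#'   a `pulse_template`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "pulse_template"))
  header <- jsonlite::toJSON(list(site = template$site, fs = template$fs),
                             auto_unbox = TRUE)
  writeLines(c(header, format(template$samples, digits = 17, trim = TRUE,
                              scientific = TRUE)), path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  structure(list(samples = as.numeric(lines[-1]), fs = header$fs,
                 site = header$site), class = "pulse_template")
}

#' Detection configuration
#'
#' `K` scales the cross-correlation threshold (CCT): the threshold is
#' `K * mean(|r|)` over all lags of the sliding cross-correlation, so larger
#' K trades sensitivity for specificity. The refractory period prevents
#' double detections within one beat on the same channel. Raw (unnormalized)
#' correlation is the default: the threshold self-scales with the trace, so
#' detection is invariant to the channel's amplitude scale; a per-lag
#' normalized mode is available for morphology-robust experiments.
#'
#' @param K dimensionless tuning factor in `[1, 5]` (default 2.5).
#' @param refractory minimum separation between detections on one channel,
#'   seconds (default 0.3, i.e. max ~200 bpm).
#' @param cc_normalization `"raw"` or `"normalized"`.
#' @param peak_fit half-width in seconds of the local parabola fit that
#'   refines the acceleration-peak location (default 0.03; 0 disables
#'   refinement and keeps the discrete argmax).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(K = 2.5, refractory = 0.3,
                             cc_normalization = c("raw", "normalized"),
                             peak_fit = 0.03) {
  if (!is.numeric(K) || K < 1 || K > 5)
    cape_stop("K must lie in [1, 5]", "cape_config_error")
  if (refractory <= 0)
    cape_stop("refractory must be positive", "cape_config_error")
  if (peak_fit < 0 || peak_fit > 0.05)
    cape_stop("peak_fit must lie in [0, 0.05] s", "cape_config_error")
  structure(list(K = K, refractory = refractory,
                 cc_normalization = match.arg(cc_normalization),
                 peak_fit = peak_fit),
            class = "detection_config")
}

#' Sliding cross-correlation of a template over a signal
#'
#' Raw valid-overlap cross-correlation: `values[i] = sum_j signal[i+j-1] *
#' template[j]`, for `i = 1 .. n_signal - n_template + 1` (the template
#' slides over the whole signal). Computed via FFT; tests verify equality
#' with the naive two-loop sum. In normalized mode each lag is divided by
#' the product of the window and template Euclidean norms.
#'
#' @param x numeric signal.
#' @param template a `pulse_template` (or plain numeric vector).
#' @param normalized logical, per-lag normalization (default FALSE).
#' @return an object of class `cc_trace` with fields `values`, `n_lags`,
#'   `template_length`.
#' @export
sliding_cross_correlation <- function(x, template, normalized = FALSE) {
  y <- if (inherits(template, "pulse_template")) template$samples else template
  n <- length(x); m <- length(y)
  if (n < m)
    cape_stop("signal is shorter than the template", "cape_input_error")
  L <- nextn(n, 2)
  X <- fft(c(x, numeric(L - n)))
  Y <- fft(c(y, numeric(L - m)))
  vals <- Re(fft(X * Conj(Y), inverse = TRUE))[seq_len(n - m + 1)] / L
  if (normalized) {
    cs <- c(0, cumsum(x^2))
    win_norm <- sqrt(pmax(cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)], 0))
    denom <- win_norm * sqrt(sum(y^2))
    vals <- ifelse(denom > 0, vals / denom, 0)
  }
  structure(list(values = vals, n_lags = n - m + 1, template_length = m),
            class = "cc_trace")
}

#' Cross-correlation threshold (CCT)
#'
#' `CCT = K * (1/N) * sum_i |r[i]|`, where `N` is the number of lag steps of
#' the sliding cross-correlation. A fiducial point is detected where the
#' trace exceeds this threshold.
#'
#' @param trace a `cc_trace` (or numeric vector of correlation values).
#' @param K tuning factor (>= 0; the configured detection range is `[1, 5]`).
#' @return the threshold, a single number.
#' @export
compute_cct <- function(trace, K) {
  vals <- if (inherits(trace, "cc_trace")) trace$values else trace
  if (length(vals) < 1) cape_stop("empty cross-correlation trace",
                                  "cape_input_error")
  if (!is.numeric(K) || K < 0) cape_stop("K must be >= 0", "cape_config_error")
  K * mean(abs(vals))
}

#' Detect fiducial peaks on one acceleration channel
#'
#' The template slides over the channel; every maximal run of lags whose
#' cross-correlation exceeds the CCT yields one candidate: the window at the
#' run's best-matching lag is searched for the local maximum of the
#' *acceleration* signal (the fiducial is defined on acceleration, not on
#' the correlation trace). Candidates closer than the refractory period are
#' resolved in favour of the higher correlation score.
#'
#' @param acc numeric acceleration channel.
#' @param template a `pulse_template`.
#' @param cfg a [detection_config()].
#' @param fs sampling rate in Hz.
#' @param trace optional precomputed `cc_trace` for `acc` (lets callers sweep
#'   K without recomputing the correlation).
#' @return data frame with columns `time` (s), `index` (1-based sample),
#'   `cc_score`; zero rows when nothing exceeds the CCT.
#' @export
detect_fiducials <- function(acc, template, cfg = detection_config(),
                             fs = template$fs, trace = NULL) {
  if (is.null(trace))
    trace <- sliding_cross_correlation(
      acc, template, normalized = (cfg$cc_normalization == "normalized"))
  cct <- compute_cct(trace, cfg$K)
  above <- trace$values > cct
  empty <- data.frame(time = numeric(0), index = integer(0),
                      cc_score = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  m <- trace$template_length
  cand <- apply(runs, 1, function(run) {
    seg <- run[1]:run[2]
    best <- seg[which.max(trace$values[seg])]
    win <- best:(best + m - 1)
    idx <- win[which.max(acc[win])]
    c(idx = idx, score = trace$values[best])
  })
  cand <- data.frame(index = as.integer(cand["idx", ]),
                     cc_score = cand["score", ])
  # sub-sample refinement: least-squares parabola around the discrete
  # maximum. The default window (+/- 30 ms) matches the quarter-period of
  # a ~8 Hz systolic upstroke -- the support of the acceleration peak --
  # and spans about two cycles of the dominant filtered noise (correlation
  # length ~1/(2*cutoff)), so the vertex averages the noise out. On a clean symmetric peak the vertex
  # coincides with the argmax; with peak_fit = 0 the argmax is kept.
  half_fit <- round(cfg$peak_fit * fs)
  refine <- function(idx) {
    if (half_fit < 2) return(as.numeric(idx))
    lo <- max(1L, idx - half_fit); hi <- min(length(acc), idx + half_fit)
    tt <- (lo:hi) - idx
    co <- stats::coef(stats::lm.fit(cbind(1, tt, tt^2), acc[lo:hi]))
    if (!is.finite(co[3]) || co[3] >= 0) return(as.numeric(idx))
    vertex <- -co[2] / (2 * co[3])
    idx + max(-half_fit, min(half_fit, vertex))
  }
  cand$pos <- vapply(cand$index, refine, numeric(1))

  # refractory: greedy by descending score, higher score wins a conflict
  cand <- cand[order(-cand$cc_score, cand$index), ]
  kept_at <- numeric(0)
  keep_row <- logical(nrow(cand))
  gap <- cfg$refractory * fs
  for (i in seq_len(nrow(cand))) {
    if (!length(kept_at) || all(abs(cand$index[i] - kept_at) >= gap)) {
      kept_at <- c(kept_at, cand$index[i])
      keep_row[i] <- TRUE
    }
  }
  out <- cand[keep_row, ]
  out <- out[order(out$index), ]
  data.frame(time = (out$pos - 1) / fs, index = out$index,
             cc_score = out$cc_score)
}

#' Detect fiducial peaks on every channel of an acceleration recording
#'
#' @param acc_rec an acceleration `ldv_recording`
#'   (see [displacement_to_acceleration()]).
#' @param templates named list with elements `carotid` and `femoral`, each a
#'   `pulse_template`; defaults to [default_template()] for each site.
#' @param cfg a [detection_config()].
#' @return data frame with columns `site`, `channel`, `time`, `index`,
#'   `cc_score`, ordered by time.
#' @export
detect_all_fiducials <- function(acc_rec, templates = NULL,
                                 cfg = detection_config()) {
  stopifnot(inherits(acc_rec, "ldv_recording"))
  if (acc_rec$units != "acceleration")
    cape_stop("fiducial detection expects an acceleration recording",
              "cape_input_error")
  if (is.null(templates))
    templates <- list(carotid = default_template("carotid", acc_rec$fs),
                      femoral = default_template("femoral", acc_rec$fs))
  res <- lapply(seq_along(acc_rec$site_map), function(ch) {
    site <- acc_rec$site_map[ch]
    det <- detect_fiducials(acc_rec$channels[ch, ], templates[[site]],
                            cfg, fs = acc_rec$fs)
    if (nrow(det)) cbind(site = site, channel = ch, det) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(site = character(0), channel = integer(0),
                      time = numeric(0), index = integer(0),
                      cc_score = numeric(0))
  out[order(out$time), , drop = FALSE]
}
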
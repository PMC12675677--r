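#' Canonical synthetic displacement pulse
#'
#' A smooth analytic single-pulse displacement waveform (400 ms): a fast
#' raised-cosine upstroke (120 ms) followed by a slower raised-cosine return
#' to baseline (280 ms), normalized to unit peak displacement. Its second
#' derivative has a single dominant sharp maximum near the foot of the
#' upstroke -- the feature the fiducial detector keys on -- which is all the
#' pipeline uses; waveform realism beyond that is deliberately not modelled.
#' Deterministic: two calls with the same `fs` return identical arrays.
#'
#' @param fs sampling rate in Hz.
#' @return numeric displacement vector of length `0.4 * fs`.
#' @export
canonical_pulse <- function(fs) {
  if (fs <= 0) cape_stop("fs must be positive", "cape_config_error")
  w1 <- 0.12                # upstroke width, s
  w2 <- 0.28                # return width, s
  t <- (seq_len(round((w1 + w2) * fs)) - 1) / fs
  v <- ifelse(t < w1,
              0.5 * (1 - cos(2 * pi * t / w1)),
              -(w1 / w2) * 0.5 * (1 - cos(2 * pi * (t - w1) / w2)))
  d <- cumsum(v) / fs
  d / max(d)
}

# Time from pulse onset to the acceleration maximum, after the same
# filtering/differentiation chain applied to real data. Deterministic in
# (fs, spec); the generator uses it to tabulate true fiducial instants.
fiducial_offset <- function(fs, spec = filter_spec()) {
  pad <- numeric(round(0.3 * fs))
  trace <- c(pad, canonical_pulse(fs), pad)
  acc <- acceleration_chain(trace, fs, spec)
  (which.max(acc) - length(pad) - 1) / fs
}

#' Simulation configuration
#'
#' Defines a synthetic 12-channel recording: beats at the given heart rate
#' (with timing jitter), each placing the canonical pulse on every carotid
#' channel at the beat onset and on every femoral channel after the true
#' transit time. The transit is `base_ptt + amplitude * sin(2*pi*f*t)`, a
#' slow sinusoidal modulation standing in for respiratory/Mayer-wave
#' variability. White Gaussian noise is added per channel (the pipeline's
#' 30 Hz low-pass shapes it); dropout channels carry noise only.
#'
#' Defaults describe the nominal study condition: 20 s at heart rate 60,
#' base transit 70 ms, mild 2 ms / 0.1 Hz modulation, 20 ms beat jitter,
#' noise SD 0.1 of the unit pulse amplitude (20 dB), straight distance
#' 0.5 m.
#'
#' @param duration recording length in seconds (default 20).
#' @param heart_rate beats per minute, in `[30, 200]` (default 60).
#' @param base_ptt mean transit time in seconds (default 0.07); must lie in
#'   the physiological pairing window.
#' @param ptt_mod_amp,ptt_mod_freq transit modulation amplitude (s) and
#'   frequency (Hz); defaults 0.002 and 0.1.
#' @param beat_jitter_sd SD of beat-interval jitter in seconds (default 0.02).
#' @param noise_sd per-channel white-noise SD in pulse-amplitude units
#'   (default 0.1).
#' @param channel_dropout integer channel indices carrying no pulses.
#' @param artifacts optional data frame of artifacts (see [degrade()]).
#' @param suppress optional data frame with columns `beat`, `channel`: the
#'   pulse of that beat is omitted on that channel.
#' @param fake_beats optional data frame with columns `beat`, `channel`,
#'   `offset` (s), `amplitude`: adds a mistimed replica pulse at the beat's
#'   femoral arrival plus `offset` on that channel.
#' @param channel_stagger max same-site inter-channel arrival stagger in
#'   seconds (default 0; at most 0.002, mimicking the 5 mm beam spacing).
#' @param fs sampling rate in Hz (default 10000).
#' @param distance_d straight carotid-femoral distance in metres (default 0.5).
#' @param seed integer RNG seed (default 1); identical seeds give
#'   bit-identical recordings.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(duration = 20, heart_rate = 60,
                              base_ptt = 0.07, ptt_mod_amp = 0.002,
                              ptt_mod_freq = 0.1, beat_jitter_sd = 0.02,
                              noise_sd = 0.1, channel_dropout = integer(0),
                              artifacts = NULL, suppress = NULL,
                              fake_beats = NULL, channel_stagger = 0,
                              fs = 10000, distance_d = 0.5, seed = 1) {
  if (heart_rate < 30 || heart_rate > 200)
    cape_stop("heart_rate must lie in [30, 200] bpm", "cape_config_error")
  pw <- pairing_config()
  if (base_ptt < pw$delay_min || base_ptt > pw$delay_max)
    cape_stop("base_ptt lies outside the physiological transit window",
              "cape_config_error")
  if (channel_stagger < 0 || channel_stagger > 0.002)
    cape_stop("channel_stagger must lie in [0, 0.002] s", "cape_config_error")
  structure(list(duration = duration, heart_rate = heart_rate,
                 base_ptt = base_ptt, ptt_mod_amp = ptt_mod_amp,
                 ptt_mod_freq = ptt_mod_freq,
                 beat_jitter_sd = beat_jitter_sd, noise_sd = noise_sd,
                 channel_dropout = as.integer(channel_dropout),
                 artifacts = artifacts, suppress = suppress,
                 fake_beats = fake_beats,
                 channel_stagger = channel_stagger, fs = fs,
                 distance_d = distance_d, seed = as.integer(seed)),
            class = "simulation_config")
}

add_pulse_at <- function(x, pulse, t0, fs, amplitude = 1) {
  i0 <- round(t0 * fs) + 1
  idx <- i0:(i0 + length(pulse) - 1)
  keep <- idx >= 1 & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + amplitude * pulse[keep]
  x
}

apply_artifacts <- function(channels, artifacts, fs) {
  pulse <- canonical_pulse(fs)
  n <- ncol(channels)
  for (i in seq_len(nrow(artifacts))) {
    a <- artifacts[i, ]
    ch <- a$channel
    if (is.na(ch) || ch < 1 || ch > nrow(channels))
      cape_stop(sprintf("unknown channel index %s in artifact spec", ch),
                "cape_input_error")
    if (a$type == "fake_pulse") {
      channels[ch, ] <- add_pulse_at(channels[ch, ], pulse, a$time, fs,
                                     amplitude = a$amplitude)
    } else if (a$type == "burst") {
      len <- round((a$duration %||na% 0.3) * fs)
      win <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
      burst <- a$amplitude * win * rnorm(len)
      i0 <- round(a$time * fs) + 1
      idx <- i0:(i0 + len - 1)
      keep <- idx >= 1 & idx <= n
      channels[ch, idx[keep]] <- channels[ch, idx[keep]] + burst[keep]
    } else if (a$type == "drift") {
      t <- (seq_len(n) - 1) / fs
      channels[ch, ] <- channels[ch, ] +
        a$amplitude * sin(2 * pi * (a$freq %||na% 0.5) * t)
    } else {
      cape_stop(sprintf("unknown artifact type '%s'", a$type),
                "cape_input_error")
    }
  }
  channels
}

`%||na%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Generate a synthetic 12-channel LDV recording with ground truth
#'
#' Deterministic and seedable; see [simulation_config()] for the model. The
#' returned ground truth records, per beat, the true carotid and femoral
#' arrival (onset) times and the true transit time, plus the per-channel
#' true fiducial instants (arrival + the acceleration-peak offset of the
#' canonical pulse + the channel stagger).
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `recording` (`ldv_recording`) and `truth`
#'   (class `ground_truth`: `beats` data frame with `beat`, `carotid_arrival`,
#'   `femoral_arrival`, `transit`; matrices `carotid_fiducials`,
#'   `femoral_fiducials`; scalar `fiducial_offset`).
#' @export
generate_recording <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  pulse <- canonical_pulse(fs)
  pulse_dur <- length(pulse) / fs
  period <- 60 / cfg$heart_rate
  stagger <- if (cfg$channel_stagger > 0)
    seq(0, cfg$channel_stagger, length.out = 6) else numeric(6)

  withr::with_seed(cfg$seed, {
    # beat onsets (carotid arrivals): drawn first so downstream randomness
    # (noise, bursts) never shifts the beat schedule between configurations
    onsets <- numeric(0)
    t0 <- 0.5
    repeat {
      t0 <- t0 + if (length(onsets)) period + rnorm(1, 0, cfg$beat_jitter_sd)
                 else rnorm(1, 0, cfg$beat_jitter_sd)
      if (t0 + cfg$base_ptt + cfg$ptt_mod_amp + pulse_dur > cfg$duration - 0.05)
        break
      onsets <- c(onsets, t0)
    }
    transit <- cfg$base_ptt +
      cfg$ptt_mod_amp * sin(2 * pi * cfg$ptt_mod_freq * onsets)
    fem_arrival <- onsets + transit
    transit <- fem_arrival - onsets  # keep the arrival/transit identity exact

    channels <- matrix(0, nrow = 12, ncol = n)
    site_map <- rep(c("carotid", "femoral"), each = 6)
    sup <- cfg$suppress
    for (b in seq_along(onsets)) {
      for (j in 1:6) {
        ch_c <- j; ch_f <- 6 + j
        if (!(ch_c %in% cfg$channel_dropout) &&
            !(!is.null(sup) && any(sup$beat == b & sup$channel == ch_c)))
          channels[ch_c, ] <- add_pulse_at(channels[ch_c, ], pulse,
                                           onsets[b] + stagger[j], fs)
        if (!(ch_f %in% cfg$channel_dropout) &&
            !(!is.null(sup) && any(sup$beat == b & sup$channel == ch_f)))
          channels[ch_f, ] <- add_pulse_at(channels[ch_f, ], pulse,
                                           fem_arrival[b] + stagger[j], fs)
      }
    }
    if (!is.null(cfg$fake_beats)) {
      for (i in seq_len(nrow(cfg$fake_beats))) {
        fk <- cfg$fake_beats[i, ]
        b <- fk$beat
        if (b < 1 || b > length(onsets))
          cape_stop("fake_beats refers to a beat outside the recording",
                    "cape_input_error")
        channels[fk$channel, ] <- add_pulse_at(
          channels[fk$channel, ], pulse,
          fem_arrival[b] + fk$offset, fs,
          amplitude = fk$amplitude %||na% 1)
      }
    }
    if (cfg$noise_sd > 0)
      channels <- channels + matrix(rnorm(12 * n, 0, cfg$noise_sd),
                                    nrow = 12)
    if (!is.null(cfg$artifacts))
      channels <- apply_artifacts(channels, cfg$artifacts, fs)

    off <- fiducial_offset(fs)
    car_fid <- outer(onsets, stagger[1:6], `+`) + off
    fem_fid <- outer(fem_arrival, stagger[1:6], `+`) + off
    rec <- ldv_recording(channels, site_map, fs = fs,
                         distance_d = cfg$distance_d,
                         subject_id = sprintf("sim-seed%d", cfg$seed))
    truth <- structure(list(
      beats = data.frame(beat = seq_along(onsets),
                         carotid_arrival = onsets,
                         femoral_arrival = fem_arrival,
                         transit = transit),
      carotid_fiducials = car_fid,
      femoral_fiducials = fem_fid,
      fiducial_offset = off
    ), class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats, mean transit %.1f ms\n",
              nrow(x$beats), 1000 * mean(x$beats$transit)))
  invisible(x)
}

#' Degrade a recording with artifacts
#'
#' Adds transient bursts, mistimed replica pulses or sinusoidal drift to
#' selected channels of an existing recording; metadata is unchanged. The
#' artifact table has columns `channel`, `time` (s), `type` in
#' `{"burst", "fake_pulse", "drift"}`, `amplitude`, and optionally
#' `duration` (s, bursts) and `freq` (Hz, drift). Zero rows (or zero
#' amplitudes) leave the recording unchanged.
#'
#' @param rec an `ldv_recording`.
#' @param artifacts artifact data frame as above.
#' @param seed optional seed for the burst noise; when `NULL` the current
#'   RNG state is used.
#' @return the degraded `ldv_recording`.
#' @export
degrade <- function(rec, artifacts, seed = NULL) {
  stopifnot(inherits(rec, "ldv_recording"))
  if (is.null(artifacts) || nrow(artifacts) == 0) return(rec)
  if (any(artifacts$channel < 1 | artifacts$channel > nrow(rec$channels)))
    cape_stop("artifact spec names a channel outside the recording",
              "cape_input_error")
  run <- function() {
    rec$channels <- apply_artifacts(rec$channels, artifacts, rec$fs)
    rec
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' True PWV implied by a simulation's ground truth
#'
#' @param truth a `ground_truth`.
#' @param distance_d straight distance in metres.
#' @return `0.8 * distance_d / mean(true transit)`, m/s.
#' @export
true_pwv <- function(truth, distance_d) {
  0.8 * distance_d / mean(truth$beats$transit)
}
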
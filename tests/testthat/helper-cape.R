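# Shared fixtures: templates are deterministic in fs, so build them once.
FS <- 10000
TPL <- list(carotid = default_template("carotid", FS),
            femoral = default_template("femoral", FS))

quick_sim <- function(duration = 6, seed = 1, noise_sd = 0.1,
                      ptt_mod_amp = 0.002, ...) {
  generate_recording(simulation_config(
    duration = duration, seed = seed, noise_sd = noise_sd,
    ptt_mod_amp = ptt_mod_amp, ...))
}

# independent brute-force oracle for the sliding cross-correlation
brute_xcorr <- function(x, y) {
  m <- length(y)
  vapply(seq_len(length(x) - m + 1),
         function(i) sum(x[i:(i + m - 1)] * y), numeric(1))
}
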
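# cape

Quality-driven estimation of carotid–femoral pulse transit time (PTT) and
pulse wave velocity (PWV) from multi-channel laser Doppler vibrometry (LDV)
recordings.

## The problem

Carotid–femoral PWV is the clinical gold-standard index of arterial
stiffness: the faster the pressure pulse travels from the neck to the groin,
the stiffer the aorta. A multi-beam LDV device measures skin displacement
over the two arteries without contact — six laser channels per site, twelve
in all — but the signals are noisy, motion-prone, and of highly variable
quality. `cape` turns such recordings into beat-to-beat and overall PTT/PWV
estimates, and refuses to report a number when the signal quality cannot
support one.

## The method

1. **Preprocessing.** Each displacement channel is low-pass filtered at
   30 Hz (4th-order Butterworth, zero-phase forward–backward) and
   differentiated twice, re-filtering after each derivative. The resulting
   acceleration signal sharpens the pulse-arrival feature and suppresses
   baseline motion drift.
2. **Fiducial detection.** A 200 ms site-specific acceleration template
   slides over each channel; the raw cross-correlation r[i] is thresholded
   at

   ```
   CCT = K * (1/N) * sum_i |r[i]|
   ```

   (N sliding steps, tuning factor K, default 2.5). Each supra-threshold
   region yields one fiducial point: the local maximum of the acceleration
   signal in the best-matching window.
3. **Cross-channel pairing.** Fiducials are clustered into heartbeats per
   site (ECG-free) and every carotid×femoral combination is enumerated — up
   to 6 × 6 = 36 pair delays per heartbeat.
4. **Two-level quality gate.** A heartbeat is kept only if it produced at
   least BQT pairs (default 15); the recording yields an estimate only if at
   least RQT heartbeats survive (default 15 per 20 s). Below that the result
   is *withheld* rather than wrong.
5. **Aggregation.** Per-beat PTT is the median of the beat's delays; the
   overall PTT is, by default, the median of per-beat medians
   (`median_median`; mean/median combinations are available). Finally

   ```
   PWV = 0.8 * d / PTT
   ```

   with `d` the measured straight carotid–femoral distance and 0.8 the
   consensus path-length correction. Estimates are graded
   excellent / acceptable / unreliable according to the preset thresholds
   used (K = 2.5, BQT = 15, RQT = 15 or 10).

The package also provides Bland–Altman device-agreement analysis with
guideline grading (excellent: |bias| < 0.5 m/s and SD < 0.8 m/s;
acceptable: |bias| < 1.0 and SD < 1.5; else poor), and a deterministic
synthetic recording generator with per-beat ground truth, so the whole
pipeline is testable without clinical data.

## Worked example

```r
library(cape)

sim <- generate_recording(simulation_config(duration = 20, seed = 42))
bundle <- estimate_pwv(sim$recording, quality_preset("excellent"))
print(bundle)
#> <recording_estimate> PTT = 70.3 ms, PWV = 5.69 m/s [excellent], 19/19 valid beats
#>   beats: 19 total, 19 kept

head(bundle$recording_estimate$trend, 3)
#>   beat      time        ptt   status
#> 1    1 0.5576064 0.06982258 observed
#> 2    2 1.5464028 0.07263597 observed
#> 3    3 2.5528627 0.07234207 observed

true_pwv(sim$truth, distance_d = 0.5)
#> [1] 5.712425
```

The simulated recording has a true mean transit of ~70 ms over a 0.5 m
path; the pipeline recovers 70.3 ms and a PWV of 5.69 m/s against a ground
truth of 5.71 m/s, grading the estimate *excellent* because all 19 beats
passed the beat gate under the strict preset. With `write_results(bundle,
"run1.cape.json")` the overall estimate, grade and per-beat table are
stored as JSON; `read_results()` restores them.

A thin CLI over these functions ships in `inst/cli/cape.R`:

```sh
Rscript inst/cli/cape.R simulate --duration 20 --seed 42 --out sim1
Rscript inst/cli/cape.R estimate sim1.csv --mode excellent
Rscript inst/cli/cape.R validate paired_pwv.csv
```

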
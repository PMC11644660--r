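# pulsemodal

Multimodal, non-contact heart-rate estimation from facial video in R.

Remote photoplethysmography (rPPG) reads the cardiac pulse out of the tiny
periodic skin-colour changes that blood volume induces in ordinary video.
`pulsemodal` implements the full pipeline for researchers working on
camera-based vital-sign measurement:

* **Region of interest** — a facial skin mask from 68-point landmarks
  (convex hull minus eye/nose/lip polygons) and per-frame spatial averaging
  to a mean RGB trace.
* **Pulse extraction** — the plane-orthogonal-to-skin (POS) projection
  `S1 = G − B`, `S2 = −2R + G + B`, `h = S1 + (σ(S1)/σ(S2))·S2` on
  window-normalized channels with overlap-add, plus green-channel,
  chrominance (CHROM) and ICA baselines.
* **Heart rate** — zero-phase 4th-order Butterworth bandpass over
  0.8–2.0 Hz (48–120 bpm) and the dominant FFT frequency, `bpm = 60·f_d`.
* **Signal features** — eleven descriptors of the filtered pulse
  (amplitude extremes and peak-to-peak, skewness, excess kurtosis, 30-bin
  amplitude entropy, zero crossings, spectral centroid and bandwidth,
  dominant frequency, total power).
* **Multimodal regression** — the feature rows fused with physical
  attributes (age, gender, height, weight, BMI), grid-searched SVR and
  random-forest models under seeded 5-fold cross-validation, MAE/RMSE/MAPE
  reporting, modality ablation, feature importances and partial dependence.
* **Synthetic data** — a cohort generator with realistic heart-rate effect
  structure (declines with age, higher for females, rises with BMI) and a
  pulsatile RGB-trace/frame simulator with known ground truth, so the whole
  pipeline is testable without private human-subject recordings.

Everything is tidyverse-native: data frames in, tibbles out, `autoplot()`
methods for traces, pulses, spectra, ablations and partial-dependence
curves, and broom-style `tidy()`/`glance()` for fitted models.

## Worked example

```r
library(pulsemodal)

# one minute of synthetic facial video at 30 fps, true heart rate 72 bpm
tr <- synth_rgb_trace(trace_spec(duration = 60, fps = 30, hr = 72, seed = 42))

pulse <- tr |> pos_project() |> bandpass()
estimate_hr(pulse)
#> # A tibble: 1 × 3
#>     bpm dominant_freq method
#>   <dbl>         <dbl> <chr>
#> 1    72           1.2 pos

round(as.data.frame(extract_features(pulse)), 4)
#>   max_value min_value peak_to_peak skewness kurtosis entropy zero_crossings
#> 1    0.5944   -0.5868       1.1813  -0.0026  -1.1898  4.6464            144
#>   spectral_centroid spectral_bandwidth dominant_frequency total_power
#> 1            1.4422             0.8081                1.2    129.3751
```

The estimate lands exactly on 72 bpm: a 60 s signal at 30 fps gives 1 bpm
spectral resolution, and the dominant frequency 1.2 Hz is the true pulse.
The 144 zero crossings match the expected `2 × 1.2 Hz × 60 s = 144` for a
clean bandpassed pulse, and the spectral centroid sits near the pulse
frequency, pulled slightly up by the second cardiac harmonic.

A full simulated study — cohort, traces, pulses, features, cross-validated
model — runs from one configuration:

```r
res <- run_pipeline(run_config(
  seed = 7,
  simulate = list(n_subjects = 60, duration = 60, fps = 30),
  stages = c("simulate", "pulse", "features", "train")
))
glance(res$cv)        # selected hyperparameters + MAE/RMSE/MAPE
ablation_study(res$features, res$cohort, seed = 7)  # modality ablation
```

A thin command-line wrapper over the same functions is installed under
`exec/`:

```sh
pulsemodal simulate --n 60 --duration 60 --fps 30 --seed 7 --out demo
pulsemodal pulse --trace demo/traces/S001.csv --method pos --out pulse.csv
pulsemodal features --pulse pulse.csv --out features.csv
```

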
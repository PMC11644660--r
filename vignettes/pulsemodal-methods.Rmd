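---
title: "Methods: multimodal non-contact heart-rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal non-contact heart-rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Remote photoplethysmography (rPPG) estimates heart rate from ordinary video
of a person's face. The cardiac cycle modulates the blood volume in the skin's
capillary bed, which modulates how much light the skin absorbs; a camera sees
this as a tiny periodic change in skin colour, strongest in the green channel
because hemoglobin absorbs strongly there. The difficulty is that this
pulsatile component is on the order of 1% of the mean intensity and sits on
top of much larger nuisance variation — illumination changes, motion, sensor
noise — that reaches the camera mainly through specular (surface) reflection,
which carries no pulse information.

`pulsemodal` implements a full estimation pipeline around this signal:

1. reduce each video frame to a mean RGB value over a facial skin mask
   (`build_roi_mask()`, `spatial_mean_rgb()`);
2. extract a blood-volume-pulse signal from the RGB trace
   (`pos_project()`, with `green_signal()`, `chrom_signal()` and
   `ica_signal()` as baselines);
3. bandpass the signal to the physiological band and read the heart rate off
   the dominant FFT frequency (`bandpass()`, `estimate_hr()`);
4. derive eleven signal features (`extract_features()`) and fuse them with
   physical attributes — age, gender, height, weight, BMI — in grid-searched
   SVR and random-forest regressions with cross-validation, ablation and
   interpretability outputs (`run_grid_search_cv()`, `ablation_study()`,
   `feature_importance()`, `partial_dependence()`, `compare_baselines()`).

Because multimodal face-video datasets with ground-truth heart rate are
essentially all private, the package ships a synthetic generator
(`sample_cohort()`, `synth_rgb_trace()`, `render_frames()`) that makes every
stage testable with known ground truth.

# Pulse extraction

## The POS projection

Let $C(n) = (R(n), G(n), B(n))^\top$ be the per-frame mean RGB trace. Within
a sliding window of $l$ frames ending at frame $n$, each channel is divided
by its window mean ("temporal normalization"), so a constant trace maps to
$(1,1,1)$ and any global intensity gain cancels exactly. The normalized
window is projected onto two chrominance axes,

$$S_1 = G - B, \qquad S_2 = -2R + G + B,$$

both orthogonal to the $(1,1,1)$ intensity direction — which is why additive
illumination changes common to all normalized channels vanish under the
projection. The two axes are recombined with an adaptive gain,

$$h = S_1 + \frac{\sigma(S_1)}{\sigma(S_2)}\, S_2,$$

and $h - \bar h$ is overlap-added into the output at the window's position.
The result has the same length as the input; the first $l-1$ samples are
covered by fewer windows and are flagged via the `partial_frames` attribute.

Numerical choices:

* the window is $l = \mathrm{round}(1.6\,\mathrm{fps})$ frames — 48 at
  30 fps — i.e. about 1.6 s, long enough to contain at least one full cardiac
  cycle at the slowest resting rate;
* $\sigma(\cdot)$ is the population standard deviation over the window;
* if $\sigma(S_2) = 0$ (possible on degenerate input), the gain term is
  dropped and $h = S_1$;
* a window whose channel mean is zero or negative is a degenerate-input
  error, since normalization is undefined there.

The gain invariance is exact in exact arithmetic; in floating point it is
bit-exact for power-of-two gains and holds to rounding error otherwise,
which is how the property is tested.

## Baselines

* **Green**: the mean-removed green channel.
* **CHROM**: channels are normalized by their global means, combined as
  $X_s = 3R_n - 2G_n$ and $Y_s = 1.5R_n + G_n - 1.5B_n$, and returned as
  $S = X_s - \alpha Y_s$ with $\alpha = \sigma(X_s)/\sigma(Y_s)$,
  mean-removed.
* **ICA**: the three mean-centred channels are whitened via the covariance
  eigendecomposition and unmixed by a symmetric fixed-point iteration with a
  $\tanh$ contrast; the component with the strongest in-band spectral peak is
  returned. The whitening is restricted to the subspace of non-negligible
  eigenvalues: a noise-free pulsatile trace is exactly rank one, and its
  single component *is* the pulse. If the iteration does not converge the
  green signal is returned with a warning rather than failing a batch run.
  The unmixing initialisation is drawn from the supplied seed, so output is
  reproducible.

## Filtering and heart-rate estimation

Resting heart rate lies in 48–120 bpm, i.e. 0.8–2.0 Hz; the default filter is
a 4th-order Butterworth bandpass with those cutoffs. It is applied
forward–backward (zero phase) so time-domain feature positions (peaks, zero
crossings) are not shifted; the package treats the stated order as the design
order of the underlying `signal::butter()` prototype. The default stage
order is extraction first, then filtering, both configurable.

`estimate_hr()` takes the magnitude spectrum of the signal — full length, no
zero padding, no taper, so a 60 s recording at 30 fps has exactly 1 bpm
resolution — restricts it to the band, and returns 60 times the frequency of
maximal magnitude. Ties resolve to the lowest frequency, and a warning is
issued when the resolution is coarser than 2 bpm. Because the search is
band-restricted, the estimate is guaranteed to lie in 48–120 bpm.

# Signal features

All eleven features are computed on the filtered pulse signal:

| feature | definition | units |
|---|---|---|
| `max_value`, `min_value` | extremes of $x(t)$ | amplitude |
| `peak_to_peak` | max − min | amplitude |
| `skewness` | $E[((x-\mu)/\sigma)^3]$, population moments | — |
| `kurtosis` | $E[((x-\mu)/\sigma)^4] - 3$ (excess) | — |
| `entropy` | Shannon entropy of 30-bin amplitude histogram | bits |
| `zero_crossings` | $\#\{t : x(t)x(t{+}1) < 0\}$ | count |
| `spectral_centroid` | $\sum f|X(f)| / \sum |X(f)|$, DC excluded | Hz |
| `spectral_bandwidth` | $\sum (f-SC)^2|X(f)| / \sum |X(f)|$ | Hz² |
| `dominant_frequency` | $\arg\max_f |X(f)|$, positive frequencies | Hz |
| `total_power` | $\sum_t x(t)^2$ | amplitude² |

Conventions worth noting, since they are genuinely open choices:

* **Entropy binning**: 30 equal-width bins spanning `[min, max]` of the
  signal (30 matching the assumed frame rate), rightmost bin closed; a
  constant signal has zero entropy by convention. A uniform ramp of 300
  samples occupies every bin equally and attains the maximum
  $\log_2 30 \approx 4.907$ bits — a closed form used in the tests.
* **Spectral bandwidth** is reported as the second moment itself (units
  Hz²), not its square root; `sqrt_bandwidth = TRUE` gives the conventional
  Hz version. Spectral sums weight by magnitude $|X(f)|$, not power.
* **Zero crossings** count only strict sign changes; a sample exactly at
  zero contributes no crossing. On a bandpassed pulse the count is
  approximately $2 f T$ and is, unsurprisingly, the most heart-rate-loaded
  feature in the forest's importances.
* `dominant_frequency` in the feature table is searched over all positive
  frequencies (the input is already bandpassed); the band restriction
  applies only to `estimate_hr()`.

Every feature is verified against an independent brute-force implementation
(explicit loops, direct $O(n^2)$ DFT) on random signals to $10^{-9}$
relative tolerance.

# Region of interest

The skin mask is built from 68-point facial landmarks: the face region —
by default the convex hull of all 68 points, optionally the jaw-and-brow
outline — minus four feature polygons (eyes, nose, lips) whose indices are
taken as printed 1-based lists; any 0-based detector output is shifted at
the I/O boundary (`read_landmarks(offset = 1)`). Polygons are rasterized
with an even-odd scanline fill on a 0-based pixel grid, sampling pixel
centres with half-open edge handling, so shared borders are never counted
twice and pixel counts match polygon areas exactly on axis-aligned shapes
(the property the tests exploit).

Excluded features are removed from the averaging region. An alternative
reading — painting them black but keeping them inside the region — is
available as `paint_black = TRUE`; it darkens the mean by the area fraction
of the features and is provided for compatibility, not as the default,
since black pixels bias the mean without adding pulse information.

# The multimodal regression

Per-subject feature rows are concatenated with physical attributes (age in
years, gender coded male = 0 / female = 1, height in cm, weight in kg, and
BMI recomputed as weight/(height/100)²). The default hyperparameter grids
are:

* SVR: kernel ∈ {linear, rbf}, C ∈ {0.01, 0.1, 1, 10, 100},
  γ ∈ {0.01, 0.1, 1, 10, 100} (rbf only; inapplicable to and collapsed for
  the linear kernel), ε ∈ {0.001, 0.01, 0.1, 1, 10};
* random forest: 50/100/200 trees, max depth none/5/10/20, minimum samples
  per split 2/5/10/20.

Selection uses the mean cross-validated MAE over a single seeded 5-fold
partition (RMSE selectable); ties resolve to the first configuration in
canonical grid order. The same folds score every configuration and provide
the reported fold-averaged MAE/RMSE/MAPE, mirroring a single-CV protocol;
this choice mildly favours optimistic selection relative to nested CV, which
is the standard trade-off at $n \approx 60$. The forest backend is
`ranger` (whose minimal-node-size-to-split parameter matches the
min-samples-per-split semantics); SVR is `e1071::svm` with predictors
z-scored using training-fold statistics only, since SVR is scale-sensitive
and the forest is not. An ε-tube wide enough to cover the training data
leaves an SVR with no support vectors; such a model predicts the training
mean rather than erroring, so extreme grid corners remain comparable.

`ablation_study()` produces the six-row table {RF, SVR} × {video-only,
physical-only, both}. `feature_importance()` reports impurity importances
normalized to sum to one, with `permutation_importance()` as a
model-agnostic cross-check, and `partial_dependence()` sweeps one feature
over its observed range while averaging predictions over the table.

# The synthetic generator

## Cohort

`sample_cohort()` draws ages uniformly (default 20–60), gender with a
default 25% female fraction, and Gaussian heights and weights
(170 ± 8 cm, 70 ± 12 kg). The reference heart rate is

$$\mathrm{hr} = \mathrm{hr}_\mathrm{base} + \beta_\mathrm{age}(a - \bar a)
 + \beta_\mathrm{bmi}(b - \bar b) + \beta_\mathrm{female}\,\mathbb{1}[f]
 + \varepsilon,$$

clipped to 48–120 bpm. The default effect directions encode what is known
about resting heart rate — it declines slightly with age, rises with BMI,
and is higher in women — with magnitudes
($\beta_\mathrm{age} = -0.1$ bpm/yr, $\beta_\mathrm{bmi} = +0.5$ bpm per
kg/m², $\beta_\mathrm{female} = +5$ bpm, residual sd 3 bpm) chosen once as
plausible values of the right order; they are configuration defaults, not
estimates of any particular cohort, and the effects are centred at cohort
means so `hr_base` is the expected cohort mean. With these defaults a
500-subject cohort recovers $\beta_\mathrm{bmi}$ by OLS within two standard
errors, which is the regression oracle in the tests.

## Traces

`synth_rgb_trace()` builds each channel as
$c(t) = b_c\,(1 + g_c s(t) + d(t) + \epsilon_c(t))$ with a cardiac waveform
$s(t)$ (fundamental plus a 0.2-weight second harmonic), a shared sinusoidal
illumination drift $d(t)$ and white noise. Defaults: green-dominant pulse
strengths $(0.33, 1, 0.66) \times 0.01$ — the ~1% modulation typical of
facial rPPG, strongest in green — moderate noise (0.3 × the green pulse
amplitude) and a slow 0.1 Hz drift of relative amplitude 0.05. Because the
drift enters all channels identically, the POS projection cancels it exactly
while the green channel does not — the mechanism behind the drift-robustness
comparison, where "strong drift" means relative amplitude 0.5 (50 × the
pulse) at 0.7 Hz, a flicker-like disturbance near the band edge.

`render_frames()` paints each frame's RGB value uniformly inside the face
polygon of a synthetic 68-landmark template over a fixed background, which
makes the spatial-averaging stage testable as an exact round trip.

What the generator does **not** emulate: head motion, photorealistic skin
reflectance and tone diversity, specular highlights, sensor quantization
(available optionally via `bit_depth`), or non-stationary heart rate within
a recording. Passing tests therefore demonstrate correctness of the
algorithms under controlled conditions, not field performance on real video.

## Study conditions used by the checks

The bundled acceptance analysis (`scripts/acceptance.R` and the acceptance
tests) uses problem sizes chosen to be informative at desk scale: 200
one-minute traces for heart-rate recovery (1 bpm spectral resolution);
ten 60-subject replicates with heavy trace noise (5 × the pulse amplitude —
a regime where video features alone are only partially informative and
attribute fusion has room to help) for the multimodal ablation, with a
reduced forest grid (100 trees, minimum split 2 or 5) inside the replicate
loop; and ten 15-subject replicates under strong drift for the POS-vs-green
comparison. The full printed grids remain the package defaults and are
exercised in the unit tests.

# Limitations

* Landmark detection itself is out of scope; coordinates are an input.
* The single-CV protocol reports fold-averaged test metrics at the selected
  configuration; with ~60 subjects these estimates carry substantial
  variance, and nested CV should be preferred when comparing close models.
* SHAP-style attributions are not implemented; impurity and permutation
  importances plus partial dependence cover interpretability.
* The heart-rate estimator returns the single dominant frequency; it does
  not track rate changes within a recording.
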
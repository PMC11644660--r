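#' Specification of a synthetic subject cohort
#'
#' Defines the generative model for a cohort of subjects with physical
#' attributes and a resting heart rate that depends on them. The effect
#' structure follows what is known about resting heart rate: it tends to
#' decrease with age, is higher in females, and increases with body mass
#' index. Effects are centred at the cohort means, so `hr_base` is the
#' expected cohort mean heart rate before clipping.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param age_range Uniform age bounds in years.
#' @param sex_ratio Fraction of female subjects in `[0, 1]`.
#' @param height_mean,height_sd Height distribution (cm).
#' @param weight_mean,weight_sd Weight distribution (kg).
#' @param hr_base Baseline (cohort-mean) heart rate, bpm.
#' @param beta_age Heart-rate slope per year of age (bpm/year, <= 0 typical).
#' @param beta_bmi Heart-rate slope per kg/m^2 of BMI (bpm, >= 0 typical).
#' @param beta_female Additive shift for female subjects (bpm, >= 0 typical).
#' @param hr_noise_sd Residual heart-rate noise, bpm (>= 0).
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60L,
                        age_range = c(20, 60),
                        sex_ratio = 0.25,
                        height_mean = 170, height_sd = 8,
                        weight_mean = 70, weight_sd = 12,
                        hr_base = 70,
                        beta_age = -0.1,
                        beta_bmi = 0.5,
                        beta_female = 5,
                        hr_noise_sd = 3,
                        seed = 1L) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (hr_noise_sd < 0) stop("`hr_noise_sd` must be >= 0", call. = FALSE)
  if (height_sd < 0 || weight_sd < 0) stop("distribution sd must be >= 0", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1) stop("`sex_ratio` must be in [0, 1]", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] > age_range[2] || age_range[1] < 0) {
    stop("`age_range` must be nondecreasing nonnegative bounds", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    sex_ratio = sex_ratio,
    height_mean = height_mean, height_sd = height_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    hr_base = hr_base, beta_age = beta_age, beta_bmi = beta_bmi,
    beta_female = beta_female, hr_noise_sd = hr_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Heart rates outside this range are not plausible at rest and are clipped.
HR_CLIP <- c(48, 120)

#' Sample a synthetic cohort
#'
#' Draws subject attributes from the cohort specification and assigns each
#' subject a reference heart rate
#' `hr_base + beta_age (age - mean age) + beta_bmi (bmi - mean bmi) +
#' beta_female 1[female] + N(0, hr_noise_sd)`, clipped to 48--120 bpm.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `age`, `gender`
#'   (`"male"`/`"female"`), `height` (cm), `weight` (kg), `bmi` (kg/m^2) and
#'   `hr_reference` (bpm); one row per subject.
#' @examples
#' cohort <- sample_cohort(cohort_spec(n_subjects = 10, seed = 42))
#' range(cohort$hr_reference)
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  female <- stats::rbinom(n, 1L, spec$sex_ratio)
  height <- pmax(stats::rnorm(n, spec$height_mean, spec$height_sd), 100)
  weight <- pmax(stats::rnorm(n, spec$weight_mean, spec$weight_sd), 30)
  bmi <- derive_bmi(weight, height)
  noise <- stats::rnorm(n, 0, spec$hr_noise_sd)

  hr <- spec$hr_base +
    spec$beta_age * (age - mean(age)) +
    spec$beta_bmi * (bmi - mean(bmi)) +
    spec$beta_female * female +
    noise
  hr <- pmin(pmax(hr, HR_CLIP[1]), HR_CLIP[2])

  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age,
    gender = ifelse(female == 1L, "female", "male"),
    height = height,
    weight = weight,
    bmi = bmi,
    hr_reference = hr
  )
}

#' Specification of a synthetic pulsatile RGB trace
#'
#' Describes an idealized facial-video trace: each channel is its baseline
#' intensity modulated by a cardiac pulse waveform (fundamental plus one
#' harmonic), a shared slow illumination drift, and white noise:
#' `c(t) = baseline_c * (1 + gain_c s(t) + drift(t) + eps_c(t))` with
#' `s(t) = sin(2 pi f t) + harmonic_ratio sin(4 pi f t)`, `f = hr/60`.
#'
#' Default pulse strengths are green-dominant (relative gains
#' `0.33 : 1 : 0.66` scaled by `amplitude`), reflecting the favourable
#' absorption of hemoglobin in the green band. Defaults include moderate
#' noise (0.3 x the green pulsatile amplitude) and a slow illumination drift.
#'
#' @param duration Trace length in seconds; `duration * fps` must be a whole
#'   number of frames.
#' @param fps Frame rate, Hz; must exceed twice the pulse frequency.
#' @param hr Heart rate, bpm.
#' @param baseline_rgb Nonnegative channel baselines (mean intensities).
#' @param amplitude Overall relative pulsatile strength of the green channel.
#' @param pulsatile_gain Per-channel relative strengths; defaults to
#'   `c(0.33, 1, 0.66) * amplitude`.
#' @param harmonic_ratio Strength of the second cardiac harmonic relative to
#'   the fundamental.
#' @param drift_amplitude,drift_freq Relative amplitude and frequency (Hz)
#'   of a shared sinusoidal illumination drift.
#' @param noise_sd Standard deviation of per-channel relative white noise.
#' @param seed Integer seed (noise and drift phase).
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(duration = 60,
                       fps = 30,
                       hr = 72,
                       baseline_rgb = c(r = 120, g = 100, b = 80),
                       amplitude = 0.01,
                       pulsatile_gain = c(0.33, 1, 0.66) * amplitude,
                       harmonic_ratio = 0.2,
                       drift_amplitude = 0.05,
                       drift_freq = 0.1,
                       noise_sd = 0.3 * amplitude,
                       seed = 1L) {
  n_frames <- duration * fps
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("`duration * fps` must be a whole number of frames", call. = FALSE)
  }
  if (fps <= 2 * (hr / 60)) {
    stop(sprintf("Nyquist violation: fps = %g cannot sample a %g bpm pulse", fps, hr),
         call. = FALSE)
  }
  if (any(pulsatile_gain < 0) || any(baseline_rgb < 0) || noise_sd < 0 ||
      drift_amplitude < 0) {
    stop("gains, baselines, noise and drift amplitudes must be >= 0", call. = FALSE)
  }
  if (length(pulsatile_gain) != 3L || length(baseline_rgb) != 3L) {
    stop("`baseline_rgb` and `pulsatile_gain` must have length 3", call. = FALSE)
  }
  structure(list(
    duration = duration, fps = fps, hr = hr,
    baseline_rgb = unname(baseline_rgb), pulsatile_gain = unname(pulsatile_gain),
    harmonic_ratio = harmonic_ratio,
    drift_amplitude = drift_amplitude, drift_freq = drift_freq,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "trace_spec")
}

#' Generate a synthetic RGB trace with known pulsatile content
#'
#' @param spec A [trace_spec()].
#' @return An [rgb_trace()] of `duration * fps` frames; bit-identical for a
#'   fixed seed.
#' @examples
#' tr <- synth_rgb_trace(trace_spec(duration = 10, hr = 72, seed = 3))
#' nrow(tr)  # 300 frames
#' @export
synth_rgb_trace <- function(spec = trace_spec()) {
  stopifnot(inherits(spec, "trace_spec"))
  n <- as.integer(round(spec$duration * spec$fps))
  t <- (seq_len(n) - 1L) / spec$fps
  f <- spec$hr / 60

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  drift_phase <- stats::runif(1, 0, 2 * pi)
  eps <- matrix(stats::rnorm(3L * n, 0, spec$noise_sd), nrow = 3L)

  s <- sin(2 * pi * f * t) + spec$harmonic_ratio * sin(4 * pi * f * t)
  drift <- spec$drift_amplitude * sin(2 * pi * spec$drift_freq * t + drift_phase)

  ch <- lapply(1:3, function(c_i) {
    spec$baseline_rgb[c_i] *
      (1 + spec$pulsatile_gain[c_i] * s + drift + eps[c_i, ])
  })
  rgb_trace(r = ch[[1]], g = ch[[2]], b = ch[[3]], fps = spec$fps)
}

#' Synthetic 68-point facial landmark template
#'
#' Lays out a plausible 68-point landmark set inside a frame: a jawline and
#' brow arc spanning a face oval, two eye polygons, a nose cluster and outer
#' and inner lip rings. The groups are positioned so that the index sets used
#' for region-of-interest exclusion (left eye 36/39/40/41, right eye
#' 42/45/46/47, nose 32--36, lips 49--60) form small coherent polygons well
#' inside the face.
#'
#' @param frame_shape `c(height, width)` in pixels.
#' @return A tibble with columns `idx` (1--68), `x`, `y` (0-based pixel
#'   coordinates, x rightwards, y downwards) and a `frame_shape` attribute.
#' @export
landmark_template <- function(frame_shape = c(480, 640)) {
  h <- frame_shape[1]; w <- frame_shape[2]
  cx <- w / 2; cy <- h / 2
  rx <- 0.3 * w; ry <- 0.42 * h

  pts <- matrix(NA_real_, nrow = 68, ncol = 2)
  set_pt <- function(idx, x, y) pts[idx, ] <<- cbind(x, y)

  # jawline (1..17): lower half of the face oval, ear to ear
  th <- seq(pi, 2 * pi, length.out = 17) - pi / 2
  set_pt(1:17, cx + rx * cos(th + pi / 2), cy - ry * sin(th + pi / 2))
  # brow arc (18..27): upper face, keeps the hull face-shaped
  th2 <- seq(0.15 * pi, 0.85 * pi, length.out = 10)
  set_pt(18:27, cx + 0.85 * rx * cos(th2), cy - 0.85 * ry * sin(th2))
  # nose bridge (28..31), descending towards the nose cluster
  set_pt(28:31, cx, cy - ry * c(0.30, 0.18, 0.06, -0.04))
  # nose cluster (32..36); 36 also closes the left-eye polygon
  nr <- 0.06 * min(rx, ry)
  set_pt(32:35, cx + c(-1.5, -0.5, 0.5, 1.5) * nr, cy + 0.10 * ry)
  set_pt(36, cx - 0.38 * rx, cy - 0.12 * ry)
  # left eye region (36..41); polygon uses 36, 39, 40, 41
  ex <- cx - 0.38 * rx; ey <- cy - 0.18 * ry
  er <- 0.08 * min(rx, ry)
  set_pt(37, ex - er, ey - er)
  set_pt(38, ex, ey - er)
  set_pt(39, ex + er, ey - er)
  set_pt(40, ex + er, ey + er)
  set_pt(41, ex - er, ey + er)
  # right eye region (42..47); polygon uses 42, 45, 46, 47
  ex2 <- cx + 0.38 * rx
  set_pt(42, ex2 - er, ey - er)
  set_pt(43, ex2 - er / 2, ey - er)
  set_pt(44, ex2 + er / 2, ey - er)
  set_pt(45, ex2 + er, ey - er)
  set_pt(46, ex2 + er, ey + er)
  set_pt(47, ex2 - er, ey + er)
  # outer lips (49..60) around the mouth centre; 48 at the left corner
  mx <- cx; my <- cy + 0.45 * ry
  mr_x <- 0.16 * rx; mr_y <- 0.10 * ry
  set_pt(48, mx - 1.3 * mr_x, my)
  th3 <- seq(0, 2 * pi, length.out = 13)[-13]
  set_pt(49:60, mx + mr_x * cos(th3), my + mr_y * sin(th3))
  # inner lips (61..68)
  th4 <- seq(0, 2 * pi, length.out = 9)[-9]
  set_pt(61:68, mx + 0.5 * mr_x * cos(th4), my + 0.5 * mr_y * sin(th4))

  out <- tibble::tibble(idx = 1:68, x = pts[, 1], y = pts[, 2])
  if (any(out$x < 0 | out$x >= w | out$y < 0 | out$y >= h)) {
    stop("landmark template does not fit inside the frame", call. = FALSE)
  }
  attr(out, "frame_shape") <- frame_shape
  class(out) <- c("landmark_set", class(out))
  out
}

#' Render a trace as a sequence of uniform-face frames
#'
#' Produces synthetic frames in which every pixel inside the face polygon
#' (convex hull of the landmarks) takes that frame's RGB value and the
#' background is a fixed colour. Used to exercise the region-of-interest
#' stage end to end: averaging the rendered frames over the face mask
#' recovers the generating trace.
#'
#' @param trace An [rgb_trace()].
#' @param frame_shape `c(height, width)` in pixels.
#' @param landmarks A landmark set (default: [landmark_template()] scaled to
#'   `frame_shape`). Must lie inside the frame.
#' @param background_rgb Fixed background colour.
#' @param bit_depth Optional integer bit depth; if given, pixel values are
#'   quantized to `0 .. 2^bit_depth - 1`.
#' @return A list with `frames` (list of `height x width x 3` arrays) and
#'   `landmarks` (constant across frames).
#' @export
render_frames <- function(trace, frame_shape = c(120, 160),
                          landmarks = landmark_template(frame_shape),
                          background_rgb = c(12, 12, 12),
                          bit_depth = NULL) {
  stopifnot(inherits(trace, "rgb_trace"))
  h <- frame_shape[1]; w <- frame_shape[2]
  if (any(landmarks$x < 0 | landmarks$x >= w | landmarks$y < 0 | landmarks$y >= h)) {
    stop("landmark template lies outside the frame", call. = FALSE)
  }
  hull <- grDevices::chull(landmarks$x, landmarks$y)
  face <- .fill_polygon(landmarks$x[hull], landmarks$y[hull], frame_shape)

  quant <- function(v) {
    if (is.null(bit_depth)) v else pmin(round(v), 2^bit_depth - 1)
  }
  frames <- lapply(seq_len(nrow(trace)), function(i) {
    fr <- array(0, dim = c(h, w, 3))
    vals <- c(trace$r[i], trace$g[i], trace$b[i])
    for (c_i in 1:3) {
      plane <- matrix(background_rgb[c_i], nrow = h, ncol = w)
      plane[face == 1L] <- vals[c_i]
      fr[, , c_i] <- quant(plane)
    }
    fr
  })
  list(frames = frames, landmarks = landmarks)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
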
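test_that("POS maps constant traces to exactly zero", {
  tr <- rgb_trace(r = rep(120, 200), g = rep(100, 200), b = rep(80, 200), fps = 30)
  out <- pos_project(tr)
  expect_equal(out$value, rep(0, 200))
})

test_that("POS is exactly invariant to global intensity gain", {
  tr <- synth_rgb_trace(trace_spec(duration = 10, hr = 80, seed = 8))
  ref <- pos_project(tr)$value
  for (k in c(2, 0.25)) {  # dyadic gains: scaling is exact in binary FP
    scaled <- rgb_trace(k * tr$r, k * tr$g, k * tr$b, fps = 30)
    expect_identical(pos_project(scaled)$value, ref)
  }
  # non-dyadic gain: invariance holds to rounding error
  scaled <- rgb_trace(3.7 * tr$r, 3.7 * tr$g, 3.7 * tr$b, fps = 30)
  expect_equal(pos_project(scaled)$value, ref, tolerance = 1e-10)
})

test_that("POS output length matches the trace and the window is fps-scaled", {
  tr <- synth_rgb_trace(trace_spec(duration = 10, hr = 70, seed = 1))
  out <- pos_project(tr)
  expect_equal(nrow(out), nrow(tr))
  expect_equal(attr(out, "partial_frames"), 47L)  # round(1.6 * 30) - 1
  expect_error(pos_project(tr[1:30, ] |> (\(d) rgb_trace(d$r, d$g, d$b, 30))()),
               "shorter")
})

test_that("POS recovers the pulse frequency on a clean synthetic trace", {
  tr <- clean_trace(hr = 72, duration = 20, seed = 3)
  sp <- magnitude_spectrum(pos_project(tr))
  peak <- sp$freq[-1][which.max(sp$magnitude[-1])]
  expect_lt(abs(peak - 1.2), 30 / nrow(tr) + 1e-12)
})

test_that("green baseline removes the mean and tracks the green channel", {
  t <- seq_len(300)
  tr <- rgb_trace(r = rep(10, 300), g = 5 + sin(t / 5), b = rep(10, 300), fps = 30)
  out <- green_signal(tr)
  expect_equal(out$value, sin(t / 5) - mean(sin(t / 5)))
  expect_equal(green_signal(rgb_trace(rep(1, 50), rep(2, 50), rep(3, 50), 30))$value,
               rep(0, 50))
  est <- estimate_hr(bandpass(green_signal(clean_trace(66, duration = 60, seed = 2))))
  expect_equal(est$dominant_freq, 1.1, tolerance = 30 / 1800)
})

test_that("CHROM is gain-invariant, zero on constant traces, and finds the pulse", {
  tr <- synth_rgb_trace(trace_spec(duration = 10, hr = 90, seed = 5))
  ref <- chrom_signal(tr)$value
  scaled <- rgb_trace(2 * tr$r, 2 * tr$g, 2 * tr$b, fps = 30)
  expect_identical(chrom_signal(scaled)$value, ref)

  const <- rgb_trace(rep(120, 100), rep(100, 100), rep(80, 100), fps = 30)
  expect_equal(chrom_signal(const)$value, rep(0, 100))

  est <- estimate_hr(bandpass(chrom_signal(clean_trace(90, duration = 60, seed = 4))))
  expect_equal(est$bpm, 90, tolerance = 1)
})

test_that("component separation recovers a known in-band source", {
  fps <- 30; t <- seq(0, 20 - 1 / fps, by = 1 / fps)
  src <- rbind(sin(2 * pi * 0.5 * t), sin(2 * pi * 1.2 * t), sin(2 * pi * 3.0 * t))
  set.seed(13)
  A <- matrix(runif(9, 0.5, 1.5), 3, 3)
  while (abs(det(A)) < 0.1) A <- matrix(runif(9, 0.5, 1.5), 3, 3)
  X <- A %*% src + 100  # offset keeps intensities positive
  tr <- rgb_trace(X[1, ], X[2, ], X[3, ], fps = fps)

  out <- ica_signal(tr, seed = 2)
  sp <- magnitude_spectrum(out)
  peak <- sp$freq[-1][which.max(sp$magnitude[-1])]
  expect_lt(abs(peak - 1.2), fps / length(t) + 1e-12)

  # fixed seed: identical output on repeated calls
  expect_identical(out$value, ica_signal(tr, seed = 2)$value)

  const <- rgb_trace(rep(1, 100), rep(1, 100), rep(1, 100), fps = 30)
  expect_error(ica_signal(const), "degenerate")
})

test_that("the Butterworth bandpass passes the band and rejects the stopband", {
  fps <- 30; t <- seq(0, 60 - 1 / fps, by = 1 / fps)
  inband <- pulse_signal(sin(2 * pi * 1.2 * t), fps)
  out <- bandpass(inband)
  expect_equal(nrow(out), length(t))
  expect_gte(sqrt(mean(out$value^2)), 0.9 * sqrt(mean(inband$value^2)))

  stopband <- pulse_signal(sin(2 * pi * 0.2 * t), fps)
  out2 <- bandpass(stopband)
  expect_lte(sqrt(mean(out2$value^2)), 0.1 * sqrt(mean(stopband$value^2)))

  zero <- pulse_signal(rep(0, 600), fps)
  expect_equal(bandpass(zero)$value, rep(0, 600))

  expect_error(bandpass(inband, filter_spec(0.8, 20)), "Nyquist")
  expect_error(filter_spec(2, 0.8), "low < high")
})

test_that("the magnitude spectrum matches closed forms", {
  fps <- 30
  impulse <- pulse_signal(c(1, rep(0, 63)), fps)
  sp <- magnitude_spectrum(impulse)
  expect_equal(sp$magnitude, rep(1, 33))
  expect_equal(sp$freq[2] - sp$freq[1], fps / 64)

  # sinusoid with integer cycles: peak magnitude A * N / 2 at its bin
  N <- 600; A <- 2.5
  t <- (0:(N - 1)) / fps
  sp2 <- magnitude_spectrum(pulse_signal(A * sin(2 * pi * 1.5 * t), fps))
  k <- which.max(sp2$magnitude)
  expect_equal(sp2$freq[k], 1.5)
  expect_equal(sp2$magnitude[k], A * N / 2, tolerance = 1e-9)

  const <- magnitude_spectrum(pulse_signal(rep(3, 100), fps))
  expect_equal(const$magnitude[1], 300)
  expect_equal(max(const$magnitude[-1]), 0)
})

test_that("heart-rate estimation hits the exact bin and respects the band", {
  fps <- 30; t <- seq(0, 60 - 1 / fps, by = 1 / fps)
  est <- estimate_hr(pulse_signal(sin(2 * pi * 1.2 * t), fps))
  expect_equal(est$bpm, 72)
  expect_equal(est$dominant_freq, 1.2)

  # any input stays inside the band once restricted
  set.seed(3)
  noise <- pulse_signal(rnorm(1800), fps)
  b <- estimate_hr(noise)$bpm
  expect_gte(b, 48); expect_lte(b, 120)

  # filtering does not move the estimate for an already in-band signal
  raw <- pulse_signal(sin(2 * pi * 1.2 * t), fps)
  expect_equal(estimate_hr(bandpass(raw))$bpm, estimate_hr(raw)$bpm, tolerance = 1)

  expect_warning(estimate_hr(pulse_signal(sin(2 * pi * 1.2 * t[1:300]), fps)),
                 "resolution")
})

test_that("all four extraction methods agree on clean traces", {
  tr <- clean_trace(hr = 78, duration = 60, seed = 10)
  bpms <- vapply(c("pos", "green", "chrom", "ica"), function(m) {
    estimate_hr(extract_pulse(tr, method = m, seed = 1))$bpm
  }, numeric(1))
  expect_true(all(abs(bpms - 78) <= 2))
  expect_lte(max(bpms) - min(bpms), 2)
})

test_that("end-to-end recovery works under moderate noise and drift", {
  tr <- synth_rgb_trace(trace_spec(duration = 60, hr = 85, seed = 17))
  est <- estimate_hr(bandpass(pos_project(tr)))
  expect_lt(abs(est$bpm - 85), 2)
})

test_that("the physiological passband converts to 48-120 bpm", {
  expect_equal(band_bpm(filter_spec(0.8, 2.0, 4)), c(48, 120))
})
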
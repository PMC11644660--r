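test_that("amplitude, shape and crossing features match their definitions", {
  expect_equal(amplitude_features(c(1, 3, 2, 5)),
               list(max_value = 5, min_value = 1, peak_to_peak = 4))
  expect_equal(amplitude_features(rep(2.5, 10)),
               list(max_value = 2.5, min_value = 2.5, peak_to_peak = 0))

  expect_equal(shape_features(c(-1, 0, 1))$skewness, 0)
  bf <- bf_shape(c(0, 0, 0, 1))
  got <- shape_features(c(0, 0, 0, 1))
  expect_equal(got$skewness, bf$skewness)
  expect_equal(got$kurtosis, bf$kurtosis)
  expect_error(shape_features(rep(1, 5)), "zero-variance")

  expect_equal(zero_crossings(c(1, 2, 3)), 0)
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  t <- seq(0, 10 - 1 / 30, by = 1 / 30)
  x <- sin(2 * pi * 1.1 * t + pi / 4)
  expect_equal(zero_crossings(x), bf_zero_crossings(x))
})

test_that("a large Gaussian sample has near-zero excess kurtosis", {
  set.seed(123)
  x <- rnorm(1e5)
  expect_lt(abs(shape_features(x)$kurtosis), 0.1)
  expect_lt(abs(shape_features(x)$skewness), 0.1)
})

test_that("entropy attains its closed forms", {
  expect_equal(signal_entropy(rep(4, 100)), 0)
  # uniform ramp, 10 samples per bin: maximal entropy log2(30)
  expect_equal(signal_entropy(0:299), log2(30))
  # balanced two-level square wave: one bit
  expect_equal(signal_entropy(rep(c(-1, 1), 50)), 1)
  # entropy is bounded by the bin count
  set.seed(5)
  for (i in 1:10) {
    h <- signal_entropy(rnorm(256))
    expect_gte(h, 0); expect_lte(h, log2(30))
  }
})

test_that("spectral centroid and bandwidth follow the two-point closed form", {
  fps <- 30; N <- 600
  t <- (0:(N - 1)) / fps
  # two equal-magnitude lines at 1.0 and 2.0 Hz
  x <- sin(2 * pi * 1.0 * t) + sin(2 * pi * 2.0 * t)
  sf <- spectral_features(magnitude_spectrum(pulse_signal(x, fps)))
  expect_equal(sf$spectral_centroid, 1.5, tolerance = 1e-6)
  expect_equal(sf$spectral_bandwidth, 0.25, tolerance = 1e-5)

  # single line: centroid at the line, bandwidth near zero
  x1 <- sin(2 * pi * 1.5 * t)
  sf1 <- spectral_features(magnitude_spectrum(pulse_signal(x1, fps)))
  expect_equal(sf1$spectral_centroid, 1.5, tolerance = fps / N)
  expect_lt(sf1$spectral_bandwidth, 0.05)

  # square-rooted variant is the square root of the printed second moment
  sf_sqrt <- spectral_features(magnitude_spectrum(pulse_signal(x, fps)),
                               sqrt_bandwidth = TRUE)
  expect_equal(sf_sqrt$spectral_bandwidth, sqrt(sf$spectral_bandwidth))

  expect_error(spectral_features(magnitude_spectrum(pulse_signal(rep(0, 64), fps))),
               "all-zero")
})

test_that("dominant frequency and total power follow their definitions", {
  fps <- 30
  expect_equal(power_features(pulse_signal(c(1, 1, 1, 1), fps))$total_power, 4)

  N <- 600; A <- 3
  t <- (0:(N - 1)) / fps
  pf <- power_features(pulse_signal(A * sin(2 * pi * 1.5 * t), fps))
  expect_equal(pf$total_power, A^2 * N / 2, tolerance = 1e-9)
  expect_equal(pf$dominant_frequency, 1.5)

  # the stronger of two lines wins the argmax
  mix <- 2 * sin(2 * pi * 1.0 * t) + sin(2 * pi * 1.5 * t)
  expect_equal(power_features(pulse_signal(mix, fps))$dominant_frequency, 1.0)
})

test_that("the assembled feature vector has a stable schema and sane values", {
  tr <- synth_rgb_trace(trace_spec(duration = 20, hr = 72, seed = 21))
  p <- bandpass(pos_project(tr))
  f <- extract_features(p)
  expect_named(f, c("max_value", "min_value", "peak_to_peak", "skewness",
                    "kurtosis", "entropy", "zero_crossings", "spectral_centroid",
                    "spectral_bandwidth", "dominant_frequency", "total_power"))
  expect_identical(names(f), names(extract_features(p)))
  expect_equal(f$peak_to_peak, f$max_value - f$min_value)

  # dominant frequency within a bin of the pulse; crossings near 2 f T
  expect_lt(abs(f$dominant_frequency - 1.2), 30 / nrow(tr) + 1e-12)
  expect_lt(abs(f$zero_crossings - 2 * 1.2 * 20), 3)

  expect_error(extract_features(pulse_signal(rep(1, 100), 30)), "zero-variance")
})

test_that("features transform correctly under scaling and shifts", {
  set.seed(31)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 256))
  s <- pulse_signal(x, 30)
  f <- extract_features(s)
  k <- 3.5
  fk <- extract_features(pulse_signal(k * x, 30))
  for (nm in c("skewness", "kurtosis", "entropy", "zero_crossings",
               "spectral_centroid", "spectral_bandwidth", "dominant_frequency")) {
    expect_equal(fk[[nm]], f[[nm]], tolerance = 1e-9, label = nm)
  }
  expect_equal(fk$peak_to_peak, k * f$peak_to_peak)
  expect_equal(fk$total_power, k^2 * f$total_power)

  # adding a constant moves the extremes but not the spread or shape
  fc <- extract_features(pulse_signal(x + 10, 30))
  expect_equal(fc$peak_to_peak, f$peak_to_peak)
  expect_equal(fc$skewness, f$skewness)
  expect_equal(fc$kurtosis, f$kurtosis)
})
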
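# Independent brute-force oracles. These deliberately avoid the package's
# code paths (direct O(n^2) DFT instead of fft(), explicit loops instead of
# vectorized moments) so agreement is evidence, not tautology.

bf_dft_magnitude <- function(x) {
  n <- length(x)
  t <- 0:(n - 1)
  ks <- 0:floor(n / 2)
  vapply(ks, function(k) {
    Mod(sum(x * exp(-2i * pi * k * t / n)))
  }, numeric(1))
}

bf_dft_freqs <- function(n, fps) (0:floor(n / 2)) * fps / n

bf_amplitude <- function(x) {
  s <- sort(x)
  list(max_value = s[length(s)], min_value = s[1],
       peak_to_peak = s[length(s)] - s[1])
}

bf_shape <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / n)
  sk <- 0; ku <- 0
  for (v in x) {
    z <- (v - mu) / sigma
    sk <- sk + z^3
    ku <- ku + z^4
  }
  list(skewness = sk / n, kurtosis = ku / n - 3)
}

bf_entropy <- function(x, n_bins = 30L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  width <- (rng[2] - rng[1]) / n_bins
  counts <- integer(n_bins)
  for (v in x) {
    i <- floor((v - rng[1]) / width) + 1L
    if (i > n_bins) i <- n_bins  # max value closes the last bin
    # guard against FP landing one bin early at an exact edge
    if (i < n_bins && v >= rng[1] + i * width) i <- i + 1L
    counts[i] <- counts[i] + 1L
  }
  h <- 0
  for (cnt in counts) {
    if (cnt > 0L) {
      p <- cnt / length(x)
      h <- h - p * log2(p)
    }
  }
  h
}

bf_zero_crossings <- function(x) {
  z <- 0L
  for (i in seq_len(length(x) - 1L)) {
    if (x[i] * x[i + 1L] < 0) z <- z + 1L
  }
  z
}

bf_spectral <- function(x, fps) {
  m <- bf_dft_magnitude(x)
  f <- bf_dft_freqs(length(x), fps)
  keep <- f > 0
  f <- f[keep]; m <- m[keep]
  sc <- sum(f * m) / sum(m)
  list(spectral_centroid = sc,
       spectral_bandwidth = sum((f - sc)^2 * m) / sum(m))
}

bf_power <- function(x, fps) {
  m <- bf_dft_magnitude(x)
  f <- bf_dft_freqs(length(x), fps)
  keep <- f > 0
  list(dominant_frequency = f[keep][which.max(m[keep])],
       total_power = sum(x * x))
}

bf_features <- function(x, fps, n_bins = 30L) {
  c(bf_amplitude(x), bf_shape(x),
    list(entropy = bf_entropy(x, n_bins), zero_crossings = bf_zero_crossings(x)),
    bf_spectral(x, fps), bf_power(x, fps))
}

# A clean sinusoidal trace helper for spectral oracles.
clean_trace <- function(hr, duration = 20, fps = 30, seed = 1L, ...) {
  synth_rgb_trace(trace_spec(duration = duration, fps = fps, hr = hr,
                             noise_sd = 0, drift_amplitude = 0, seed = seed, ...))
}

expect_rel_equal <- function(actual, expected, rel_tol = 1e-9) {
  denom <- max(abs(expected), 1e-12)
  expect_lt(abs(actual - expected) / denom, rel_tol)
}
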
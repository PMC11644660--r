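#' @title Signal features of the filtered pulse
#' @description Eleven time- and frequency-domain descriptors of a pulse
#'   signal: amplitude extremes, distribution shape, entropy, zero
#'   crossings, spectral centroid/bandwidth, dominant frequency and total
#'   power.
#' @name signal_features
NULL

#' Amplitude features
#'
#' @param signal A [pulse_signal()] (or numeric vector).
#' @return A named list: `max_value`, `min_value`,
#'   `peak_to_peak = max_value - min_value`.
#' @export
amplitude_features <- function(signal) {
  x <- pulse_values(signal)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  mx <- max(x); mn <- min(x)
  list(max_value = mx, min_value = mn, peak_to_peak = mx - mn)
}

#' Distribution-shape features
#'
#' Skewness `E[((x - mu)/sigma)^3]` and excess kurtosis
#' `E[((x - mu)/sigma)^4] - 3`, with population moments.
#'
#' @inheritParams amplitude_features
#' @return A named list: `skewness`, `kurtosis`.
#' @export
shape_features <- function(signal) {
  x <- pulse_values(signal)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  mu <- mean(x)
  sigma <- .pop_sd(x)
  if (sigma == 0) stop("zero-variance signal: shape features undefined", call. = FALSE)
  z <- (x - mu) / sigma
  list(skewness = mean(z^3), kurtosis = mean(z^4) - 3)
}

#' Amplitude entropy
#'
#' Shannon entropy of the signal's amplitude distribution after binning
#' into `n_bins` equal-width bins spanning `[min, max]` (rightmost bin
#' closed). A constant signal has zero entropy; a uniformly occupied
#' binning attains the maximum `log2(n_bins)` bits.
#'
#' @inheritParams amplitude_features
#' @param n_bins Number of amplitude bins; the default 30 matches the
#'   assumed 30 fps frame rate.
#' @return Entropy in bits.
#' @export
signal_entropy <- function(signal, n_bins = 30L) {
  x <- pulse_values(signal)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Zero crossings
#'
#' The number of strict sign changes between consecutive samples
#' (`x(t) x(t+1) < 0`); touches of zero do not count. A frequency proxy:
#' a sinusoid at `f` Hz crosses about `2 f` times per second.
#'
#' @inheritParams amplitude_features
#' @return Integer count.
#' @export
zero_crossings <- function(signal) {
  x <- pulse_values(signal)
  if (length(x) < 2L) stop("need at least two samples", call. = FALSE)
  n <- length(x)
  sum(x[-n] * x[-1] < 0)
}

#' Spectral centroid and bandwidth
#'
#' Magnitude-weighted mean frequency `SC = sum(f |X(f)|) / sum(|X(f)|)` and
#' the second moment around it,
#' `SB = sum((f - SC)^2 |X(f)|) / sum(|X(f)|)` (no square root, units
#' Hz^2; set `sqrt_bandwidth = TRUE` for the conventional Hz version). The
#' DC bin is excluded.
#'
#' @param spectrum A [magnitude_spectrum()] result.
#' @param sqrt_bandwidth Return the square root of the second moment.
#' @return A named list: `spectral_centroid` (Hz), `spectral_bandwidth`.
#' @export
spectral_features <- function(spectrum, sqrt_bandwidth = FALSE) {
  stopifnot(inherits(spectrum, "pulse_spectrum"))
  keep <- spectrum$freq > 0
  f <- spectrum$freq[keep]
  m <- spectrum$magnitude[keep]
  tot <- sum(m)
  if (tot <= 0) stop("all-zero spectrum: spectral features undefined", call. = FALSE)
  sc <- sum(f * m) / tot
  sb <- sum((f - sc)^2 * m) / tot
  list(spectral_centroid = sc,
       spectral_bandwidth = if (sqrt_bandwidth) sqrt(sb) else sb)
}

#' Dominant frequency and total power
#'
#' `dominant_frequency` is the positive frequency of maximal spectral
#' magnitude (ties resolve to the lowest frequency); `total_power` is the
#' time-domain energy `sum(x(t)^2)`.
#'
#' @inheritParams amplitude_features
#' @param spectrum A [magnitude_spectrum()] of the same signal (computed if
#'   omitted).
#' @return A named list: `dominant_frequency` (Hz), `total_power`.
#' @export
power_features <- function(signal, spectrum = NULL) {
  x <- pulse_values(signal)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  if (is.null(spectrum)) spectrum <- magnitude_spectrum(signal)
  keep <- spectrum$freq > 0
  f <- spectrum$freq[keep]
  m <- spectrum$magnitude[keep]
  list(dominant_frequency = f[which.max(m)], total_power = sum(x^2))
}

# Canonical feature column order used across the package.
SIGNAL_FEATURE_NAMES <- c(
  "max_value", "min_value", "peak_to_peak", "skewness", "kurtosis",
  "entropy", "zero_crossings", "spectral_centroid", "spectral_bandwidth",
  "dominant_frequency", "total_power"
)

#' Extract the eleven-feature vector
#'
#' Assembles all signal features of a filtered pulse signal into a single
#' stable-schema row, ready for concatenation with physical attributes.
#'
#' @param signal A filtered [pulse_signal()].
#' @param n_bins Amplitude bins for the entropy feature.
#' @return A one-row tibble with the columns `max_value`, `min_value`,
#'   `peak_to_peak`, `skewness`, `kurtosis`, `entropy`, `zero_crossings`,
#'   `spectral_centroid`, `spectral_bandwidth`, `dominant_frequency`,
#'   `total_power`.
#' @examples
#' tr <- synth_rgb_trace(trace_spec(duration = 20, hr = 72))
#' extract_features(bandpass(pos_project(tr)))
#' @export
extract_features <- function(signal, n_bins = 30L) {
  sp <- magnitude_spectrum(signal)
  row <- c(
    amplitude_features(signal),
    shape_features(signal),
    list(entropy = signal_entropy(signal, n_bins = n_bins),
         zero_crossings = zero_crossings(signal)),
    spectral_features(sp),
    power_features(signal, sp)
  )
  tibble::as_tibble(row[SIGNAL_FEATURE_NAMES])
}
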
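#' Bandpass filter specification
#'
#' The physiological passband used throughout: resting heart rate lies
#' between 48 and 120 bpm, i.e. 0.8--2.0 Hz, and a 4th-order Butterworth
#' design gives a flat passband with a steep roll-off.
#'
#' @param low,high Cutoff frequencies in Hz, `0 < low < high`.
#' @param order Butterworth design order (>= 1).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.8, high = 2.0, order = 4L) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high", call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  structure(list(low = low, high = high, order = as.integer(order)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param spec A `filter_spec`.
#' @return `band_bpm()`: the passband expressed in beats per minute,
#'   `60 * c(low, high)`.
#' @export
band_bpm <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  60 * c(spec$low, spec$high)
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Projection onto the plane orthogonal to the normalized skin-tone
# direction (1,1,1)/sqrt(3): rows span the chrominance plane.
POS_PROJECTION <- matrix(c(0, 1, -1,
                           -2, 1, 1), nrow = 2, byrow = TRUE)

#' POS pulse extraction
#'
#' Plane-orthogonal-to-skin projection: within a sliding window the RGB
#' trace is temporally normalized by its window mean, projected onto the
#' two chrominance axes `S1 = G - B` and `S2 = -2R + G + B`, recombined as
#' `h = S1 + (sd(S1)/sd(S2)) S2`, and the mean-removed `h` is overlap-added
#' into the output. Window-mean normalization makes the output exactly
#' invariant to global intensity gain, and the zero-sum projection rows
#' cancel illumination changes common to all channels.
#'
#' @param trace An [rgb_trace()].
#' @param window_l Window length in frames; defaults to `round(1.6 * fps)`
#'   (48 frames at 30 fps).
#' @return A [pulse_signal()] of the same length as the trace. The first
#'   `window_l - 1` samples receive fewer overlapping windows and are
#'   flagged in the `partial_frames` attribute.
#' @examples
#' tr <- synth_rgb_trace(trace_spec(duration = 20, hr = 72, noise_sd = 0,
#'                                  drift_amplitude = 0))
#' p <- pos_project(tr)
#' @export
pos_project <- function(trace, window_l = NULL) {
  stopifnot(inherits(trace, "rgb_trace"))
  fps <- trace_fps(trace)
  if (is.null(window_l)) window_l <- as.integer(round(1.6 * fps))
  n <- nrow(trace)
  if (n < window_l) {
    stop(sprintf("trace (%d frames) is shorter than the POS window (%d)", n, window_l),
         call. = FALSE)
  }
  C <- rbind(trace$r, trace$g, trace$b)
  H <- numeric(n)
  for (end in window_l:n) {
    idx <- (end - window_l + 1L):end
    Cw <- C[, idx, drop = FALSE]
    mu <- rowMeans(Cw)
    if (any(mu <= 0)) stop("zero or negative window-mean channel", call. = FALSE)
    Cn <- Cw / mu
    S <- POS_PROJECTION %*% Cn
    sd1 <- .pop_sd(S[1, ]); sd2 <- .pop_sd(S[2, ])
    h <- if (sd2 > 0) S[1, ] + (sd1 / sd2) * S[2, ] else S[1, ]
    H[idx] <- H[idx] + (h - mean(h))
  }
  out <- pulse_signal(H, fps, method = "pos")
  attr(out, "partial_frames") <- window_l - 1L
  out
}

#' Green-channel pulse baseline
#'
#' The simplest extraction: the mean-removed green channel, which carries
#' the strongest pulsatile component owing to hemoglobin absorption.
#'
#' @inheritParams pos_project
#' @return A [pulse_signal()].
#' @export
green_signal <- function(trace) {
  stopifnot(inherits(trace, "rgb_trace"))
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  pulse_signal(trace$g - mean(trace$g), trace_fps(trace), method = "green")
}

#' Chrominance (CHROM) pulse baseline
#'
#' Mean-normalizes each channel, forms the chrominance combinations
#' `Xs = 3 Rn - 2 Gn` and `Ys = 1.5 Rn + Gn - 1.5 Bn`, and returns
#' `S = Xs - alpha Ys` with the adaptive gain `alpha = sd(Xs)/sd(Ys)`,
#' mean-removed. Exactly invariant to global intensity gain.
#'
#' @inheritParams pos_project
#' @return A [pulse_signal()].
#' @export
chrom_signal <- function(trace) {
  stopifnot(inherits(trace, "rgb_trace"))
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  mu <- c(mean(trace$r), mean(trace$g), mean(trace$b))
  if (any(mu <= 0)) stop("zero or negative channel mean", call. = FALSE)
  Rn <- trace$r / mu[1]; Gn <- trace$g / mu[2]; Bn <- trace$b / mu[3]
  Xs <- 3 * Rn - 2 * Gn
  Ys <- 1.5 * Rn + Gn - 1.5 * Bn
  sdy <- .pop_sd(Ys)
  S <- if (sdy > 0) Xs - (.pop_sd(Xs) / sdy) * Ys else Xs
  pulse_signal(S - mean(S), trace_fps(trace), method = "chrom")
}

# Symmetric FastICA on a 3 x n matrix: whiten via the covariance
# eigendecomposition, then tanh-contrast fixed-point iteration with
# symmetric orthogonalization. Small and deterministic for a fixed seed.
.fast_ica3 <- function(X, seed, max_iter = 200L, tol = 1e-8) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  CovX <- (Xc %*% t(Xc)) / n
  eig <- eigen(CovX, symmetric = TRUE)
  if (max(eig$values) <= 0) {
    stop("degenerate trace: no channel variance", call. = FALSE)
  }
  # whiten onto the subspace of non-negligible variance; a noise-free
  # pulsatile trace is rank one and its single component IS the pulse
  r <- sum(eig$values > 1e-10 * max(eig$values))
  K <- diag(1 / sqrt(eig$values[1:r]), nrow = r) %*% t(eig$vectors[, 1:r, drop = FALSE])
  Z <- K %*% Xc
  if (r == 1L) return(list(S = Z, converged = TRUE))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(r * r), r, r)))

  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(Gp)) %*% W
    W_new <- sym_orth(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(S = W %*% Z, converged = converged)
}

#' Independent-component pulse baseline
#'
#' Separates the three mean-centred colour channels into independent
#' components and returns the component whose magnitude spectrum peaks
#' most strongly inside the physiological band, mean-removed. If the
#' separation does not converge the green-channel signal is returned
#' with a warning.
#'
#' @inheritParams pos_project
#' @param seed Integer seed for the separation initialisation; fixed seed
#'   gives identical output.
#' @param band A [filter_spec()] defining the in-band peak search.
#' @return A [pulse_signal()].
#' @export
ica_signal <- function(trace, seed = 1L, band = filter_spec()) {
  stopifnot(inherits(trace, "rgb_trace"))
  fps <- trace_fps(trace)
  X <- rbind(trace$r, trace$g, trace$b)
  if (ncol(X) < 10L) stop("trace too short for component separation", call. = FALSE)
  if (any(apply(X, 1, stats::sd) == 0)) {
    stop("degenerate trace: constant channel", call. = FALSE)
  }
  res <- tryCatch(.fast_ica3(X, seed = seed), error = function(e) e)
  if (inherits(res, "error") || !res$converged) {
    warning("component separation did not converge; falling back to the green channel",
            call. = FALSE)
    out <- green_signal(trace)
    attr(out, "method") <- "ica"
    return(out)
  }
  peak <- apply(res$S, 1, function(s) {
    sp <- magnitude_spectrum(pulse_signal(s, fps))
    inb <- sp$freq >= band$low & sp$freq <= band$high
    if (!any(inb)) return(0)
    max(sp$magnitude[inb])
  })
  best <- res$S[which.max(peak), ]
  pulse_signal(best - mean(best), fps, method = "ica")
}

#' Zero-phase Butterworth bandpass
#'
#' Applies the Butterworth bandpass of the given specification
#' forward-backward (zero phase), so peak positions in the time domain are
#' not shifted. Output length equals input length.
#'
#' @param signal A [pulse_signal()].
#' @param spec A [filter_spec()]; default 0.8--2.0 Hz, order 4.
#' @return A filtered [pulse_signal()].
#' @export
bandpass <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "pulse_signal"), inherits(spec, "filter_spec"))
  fps <- trace_fps(signal)
  if (spec$high >= fps / 2) {
    stop(sprintf("high cutoff %g Hz is at or above Nyquist (%g Hz)", spec$high, fps / 2),
         call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (fps / 2), type = "pass")
  y <- signal::filtfilt(bf, pulse_values(signal))
  out <- pulse_signal(y, fps, method = attr(signal, "method"))
  attr(out, "filter") <- spec
  out
}

#' One-sided magnitude spectrum
#'
#' The modulus of the discrete Fourier transform over nonnegative
#' frequencies, at resolution `fps / n_samples` Hz. No zero padding or
#' tapering is applied, so a 60 s recording at 30 fps resolves 1 bpm.
#'
#' @param signal A [pulse_signal()].
#' @return A tibble of class `pulse_spectrum` with columns `freq` (Hz) and
#'   `magnitude`.
#' @export
magnitude_spectrum <- function(signal) {
  x <- pulse_values(signal)
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  fps <- trace_fps(signal)
  X <- stats::fft(x)
  keep <- 1:(floor(n / 2) + 1L)
  out <- tibble::tibble(
    freq = (keep - 1L) * fps / n,
    magnitude = Mod(X[keep])
  )
  attr(out, "fps") <- fps
  attr(out, "n_samples") <- n
  class(out) <- c("pulse_spectrum", class(out))
  out
}

#' Heart rate from the dominant spectral frequency
#'
#' Restricts the magnitude spectrum to the physiological band and takes the
#' frequency of maximal magnitude; heart rate is `60 x` that frequency, so
#' the estimate always lies in 48--120 bpm for the default band. Ties
#' resolve to the lowest frequency.
#'
#' @param signal A [pulse_signal()].
#' @param band A [filter_spec()]; the search band in Hz.
#' @return A one-row tibble of class `hr_estimate`: `bpm`, `dominant_freq`
#'   (Hz), `method`.
#' @examples
#' s <- pulse_signal(sin(2 * pi * 1.2 * seq(0, 60 - 1/30, by = 1/30)), fps = 30)
#' estimate_hr(s)$bpm  # 72
#' @export
estimate_hr <- function(signal, band = filter_spec()) {
  stopifnot(inherits(band, "filter_spec"))
  x <- pulse_values(signal)
  fps <- trace_fps(signal)
  resolution_bpm <- 60 * fps / length(x)
  if (resolution_bpm > 2) {
    warning(sprintf("frequency resolution is %.2f bpm (> 2 bpm); use a longer signal",
                    resolution_bpm), call. = FALSE)
  }
  sp <- magnitude_spectrum(signal)
  inb <- sp$freq >= band$low & sp$freq <= band$high
  if (!any(inb)) stop("no frequency bins inside the band", call. = FALSE)
  sub <- sp[inb, ]
  f_d <- sub$freq[which.max(sub$magnitude)]
  out <- tibble::tibble(bpm = 60 * f_d, dominant_freq = f_d,
                        method = attr(signal, "method") %||% NA_character_)
  class(out) <- c("hr_estimate", class(out))
  out
}

#' Extract a pulse signal by name
#'
#' Dispatch helper used by the pipeline and baseline comparison: runs one of
#' the four extraction methods followed (optionally) by the bandpass filter.
#'
#' @param trace An [rgb_trace()].
#' @param method One of `"pos"`, `"green"`, `"chrom"`, `"ica"`.
#' @param filter A [filter_spec()] applied after extraction, or `NULL` to
#'   skip filtering.
#' @param seed Seed forwarded to [ica_signal()].
#' @param window_l Forwarded to [pos_project()].
#' @return A [pulse_signal()].
#' @export
extract_pulse <- function(trace, method = c("pos", "green", "chrom", "ica"),
                          filter = filter_spec(), seed = 1L, window_l = NULL) {
  method <- match.arg(method)
  p <- switch(method,
    pos = pos_project(trace, window_l = window_l),
    green = green_signal(trace),
    chrom = chrom_signal(trace),
    ica = ica_signal(trace, seed = seed)
  )
  if (is.null(filter)) p else bandpass(p, filter)
}
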
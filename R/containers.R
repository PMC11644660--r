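#' Per-frame mean RGB trace
#'
#' The basic container for a spatially averaged facial video: one row per
#' frame with the mean red, green and blue intensity over the region of
#' interest, plus the camera frame rate. This is the `C(n)` array that pulse
#' extraction operates on.
#'
#' @param r,g,b Numeric vectors of equal length: per-frame mean channel
#'   intensities (arbitrary nonnegative units).
#' @param fps Sampling rate in frames per second.
#' @return A tibble of class `rgb_trace` with columns `frame` (0-based),
#'   `time` (seconds), `r`, `g`, `b`, and an `fps` attribute.
#' @examples
#' tr <- rgb_trace(r = 120 + sin(1:90), g = 100 + sin(1:90), b = 80 + sin(1:90), fps = 30)
#' trace_fps(tr)
#' @export
rgb_trace <- function(r, g, b, fps) {
  if (length(r) != length(g) || length(g) != length(b)) {
    stop("channels must have equal length", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(c(r, g, b)))) stop("trace intensities must be finite", call. = FALSE)
  if (any(c(r, g, b) < 0)) stop("trace intensities must be nonnegative", call. = FALSE)
  n <- length(r)
  out <- tibble::tibble(
    frame = seq_len(n) - 1L,
    time = (seq_len(n) - 1L) / fps,
    r = as.numeric(r), g = as.numeric(g), b = as.numeric(b)
  )
  attr(out, "fps") <- fps
  class(out) <- c("rgb_trace", class(out))
  out
}

#' @rdname rgb_trace
#' @param x An `rgb_trace` or `pulse_signal`.
#' @export
trace_fps <- function(x) {
  fps <- attr(x, "fps")
  if (is.null(fps)) stop("object carries no `fps` attribute", call. = FALSE)
  fps
}

#' A one-dimensional pulse signal
#'
#' Holds a blood-volume-pulse estimate (or any 1-D physiological signal)
#' sampled at `fps` Hz, with the extraction method recorded for provenance.
#'
#' @param samples Numeric vector of signal amplitudes (unitless).
#' @param fps Sampling rate in Hz.
#' @param method Optional name of the producing method
#'   (`"pos"`, `"green"`, `"chrom"`, `"ica"`, ...).
#' @return A tibble of class `pulse_signal` with columns `time` and `value`,
#'   and attributes `fps` and `method`.
#' @export
pulse_signal <- function(samples, fps, method = NA_character_) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(samples))) stop("pulse samples must be finite", call. = FALSE)
  n <- length(samples)
  out <- tibble::tibble(time = (seq_len(n) - 1L) / fps, value = as.numeric(samples))
  attr(out, "fps") <- fps
  attr(out, "method") <- method
  class(out) <- c("pulse_signal", class(out))
  out
}

pulse_values <- function(signal) {
  if (is.data.frame(signal)) {
    if (!"value" %in% names(signal)) stop("expected a `value` column", call. = FALSE)
    signal$value
  } else {
    as.numeric(signal)
  }
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace: %d frames @ %g fps (%.1f s)>\n",
              nrow(x), trace_fps(x), nrow(x) / trace_fps(x)))
  NextMethod()
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("<pulse_signal: %d samples @ %g fps, method = %s>\n",
              nrow(x), trace_fps(x), attr(x, "method") %||% NA))
  NextMethod()
}
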
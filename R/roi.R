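#' @title Facial region-of-interest masking
#' @description Build a binary skin mask from 68-point facial landmarks and
#'   reduce frames to a single mean RGB value per frame.
#' @name roi
NULL

# Landmark index groups excluded from the skin mask, as 1-based indices into
# the 68-point set. Each group is filled as a polygon through the listed
# points in listed order.
ROI_EXCLUDED_GROUPS <- list(
  left_eye  = c(36, 39, 40, 41),
  right_eye = c(42, 45, 46, 47),
  nose      = c(32, 33, 34, 35, 36),
  lips      = 49:60
)

#' Construct a landmark set from raw coordinates
#'
#' @param points A two-column matrix or data frame of 68 `(x, y)` pixel
#'   coordinates (0-based, x rightwards, y downwards), ordered by landmark
#'   index 1..68.
#' @param frame_shape `c(height, width)` in pixels.
#' @return A tibble of class `landmark_set` with columns `idx`, `x`, `y`.
#' @export
landmark_set <- function(points, frame_shape) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L) {
    stop("a landmark set must contain exactly 68 (x, y) points", call. = FALSE)
  }
  h <- frame_shape[1]; w <- frame_shape[2]
  if (any(points[, 1] < 0 | points[, 1] >= w | points[, 2] < 0 | points[, 2] >= h)) {
    stop("all landmarks must lie within the frame bounds", call. = FALSE)
  }
  out <- tibble::tibble(idx = 1:68, x = as.numeric(points[, 1]), y = as.numeric(points[, 2]))
  attr(out, "frame_shape") <- frame_shape
  class(out) <- c("landmark_set", class(out))
  out
}

# Even-odd scanline polygon fill on a 0-based pixel grid. A pixel (ix, iy)
# is included when its centre (ix + 0.5, iy + 0.5) is inside the polygon;
# edges are treated half-open (y1 <= yc < y2) so shared borders are not
# double counted.
.fill_polygon <- function(px, py, frame_shape) {
  h <- frame_shape[1]; w <- frame_shape[2]
  mask <- matrix(0L, nrow = h, ncol = w)
  n <- length(px)
  if (n < 3L) return(mask)
  for (iy in seq_len(h) - 1L) {
    yc <- iy + 0.5
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- py[i]; y2 <- py[j]
      if ((y1 <= yc && yc < y2) || (y2 <= yc && yc < y1)) {
        xs <- c(xs, px[i] + (yc - y1) / (y2 - y1) * (px[j] - px[i]))
      }
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        ix0 <- max(ceiling(xs[k] - 0.5), 0L)
        ix1 <- min(ceiling(xs[k + 1L] - 0.5) - 1L, w - 1L)
        if (ix1 >= ix0) mask[iy + 1L, (ix0:ix1) + 1L] <- 1L
      }
    }
  }
  mask
}

#' Build the skin region-of-interest mask
#'
#' The mask covers the face region (by default the convex hull of all 68
#' landmarks; optionally the jawline-and-brow outline) with the eye, nose
#' and lip polygons removed, so that spatial averaging sees facial skin
#' only. The masked features can instead be painted black and kept inside
#' the averaging region via `paint_black` for compatibility with pipelines
#' that zero them out rather than excluding them.
#'
#' @param landmarks A [landmark_set()] (68 points).
#' @param frame_shape `c(height, width)`; defaults to the landmark set's own.
#' @param boundary `"hull"` (convex hull of all points) or `"jawline"`
#'   (polygon through the jaw and brow points).
#' @param paint_black If `TRUE`, excluded features stay inside the mask and
#'   are recorded for zero-painting instead of being removed from it.
#' @return A list of class `roi_mask`: `mask` (0/1 integer matrix),
#'   `frame_shape`, `excluded_regions`, `paint_black`, and `paint_mask`
#'   (pixels to zero when `paint_black = TRUE`).
#' @examples
#' lm <- landmark_template(c(120, 160))
#' m <- build_roi_mask(lm)
#' sum(m$mask)  # included skin pixels
#' @export
build_roi_mask <- function(landmarks,
                           frame_shape = attr(landmarks, "frame_shape"),
                           boundary = c("hull", "jawline"),
                           paint_black = FALSE) {
  boundary <- match.arg(boundary)
  if (is.null(frame_shape)) stop("`frame_shape` is required", call. = FALSE)
  if (nrow(landmarks) != 68L) stop("expected 68 landmarks", call. = FALSE)

  if (boundary == "hull") {
    hull <- grDevices::chull(landmarks$x, landmarks$y)
    if (length(hull) < 3L) stop("degenerate (collinear) face polygon", call. = FALSE)
    face <- .fill_polygon(landmarks$x[hull], landmarks$y[hull], frame_shape)
  } else {
    # jaw (1..17) up one side, brows (27..18) back across the top
    idx <- c(1:17, 27:18)
    face <- .fill_polygon(landmarks$x[idx], landmarks$y[idx], frame_shape)
  }
  if (sum(face) == 0L) stop("degenerate (collinear) face polygon", call. = FALSE)

  excl <- matrix(0L, nrow = frame_shape[1], ncol = frame_shape[2])
  for (grp in ROI_EXCLUDED_GROUPS) {
    excl <- pmax(excl, .fill_polygon(landmarks$x[grp], landmarks$y[grp], frame_shape))
  }

  mask <- if (paint_black) face else face * (1L - excl)
  if (sum(mask) == 0L) stop("mask contains no included pixels", call. = FALSE)
  structure(list(
    mask = mask,
    frame_shape = frame_shape,
    excluded_regions = names(ROI_EXCLUDED_GROUPS),
    paint_black = paint_black,
    paint_mask = face * excl
  ), class = "roi_mask")
}

#' Spatially average frames over a mask
#'
#' Reduces each frame to the arithmetic mean of every channel over the
#' included pixels, producing the per-frame RGB trace that pulse extraction
#' consumes. With a paint-black mask, excluded feature pixels are set to
#' zero and kept in the average.
#'
#' @param frames A list of `height x width x 3` numeric arrays.
#' @param mask An [build_roi_mask()] result (or any `roi_mask`).
#' @param fps Frame rate of the sequence, Hz.
#' @return An [rgb_trace()] with one row per frame.
#' @export
spatial_mean_rgb <- function(frames, mask, fps = 30) {
  stopifnot(inherits(mask, "roi_mask"))
  if (length(frames) == 0L) stop("no frames supplied", call. = FALSE)
  m <- mask$mask
  if (sum(m) == 0L) stop("mask contains no included pixels", call. = FALSE)
  sel <- which(m == 1L)
  paint_sel <- which(mask$paint_mask == 1L)

  vals <- vapply(frames, function(fr) {
    if (!all(dim(fr)[1:2] == mask$frame_shape)) {
      stop("frame shape does not match the mask", call. = FALSE)
    }
    vapply(1:3, function(c_i) {
      plane <- fr[, , c_i]
      if (mask$paint_black && length(paint_sel)) plane[paint_sel] <- 0
      mean(plane[sel])
    }, numeric(1))
  }, numeric(3))

  rgb_trace(r = vals[1, ], g = vals[2, ], b = vals[3, ], fps = fps)
}
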
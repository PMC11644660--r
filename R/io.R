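#' @title Reading and writing pipeline artifacts
#' @description Plain-text CSV/JSON dialects for cohorts, traces, pulse
#'   signals, landmarks and feature tables, so every stage can be re-run
#'   from saved intermediates.
#' @name pulsemodal_io
NULL

#' Write / read a cohort table
#'
#' CSV with header `subject_id,age,gender,height,weight,bmi,hr_reference`.
#'
#' @param cohort A [sample_cohort()] tibble.
#' @param path Output CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("subject_id", "age", "gender", "height", "weight", "bmi", "hr_reference")
  utils::write.csv(as.data.frame(cohort[cols]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read an RGB trace
#'
#' CSV with header `t,r,g,b` (`t` is the frame index) plus a JSON sidecar
#' `<path>.json` recording the frame rate and, when available, the
#' generating specification.
#'
#' @param trace An [rgb_trace()].
#' @param path Output CSV path.
#' @param spec Optional [trace_spec()] stored in the sidecar.
#' @export
write_trace <- function(trace, path, spec = NULL) {
  utils::write.csv(
    data.frame(t = trace$frame, r = trace$r, g = trace$g, b = trace$b),
    path, row.names = FALSE, quote = FALSE
  )
  meta <- list(fps = trace_fps(trace))
  if (!is.null(spec)) meta$spec <- unclass(spec)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @param fps Frame rate used when no sidecar is present.
#' @export
read_trace <- function(path, fps = NULL) {
  d <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (is.null(fps)) {
    if (!file.exists(side)) stop("no fps given and no JSON sidecar found", call. = FALSE)
    fps <- jsonlite::read_json(side)$fps
  }
  rgb_trace(d$r, d$g, d$b, fps = fps)
}

#' Write / read a pulse signal
#'
#' CSV with header `t,value` plus a JSON sidecar holding the frame rate,
#' extraction method and filter specification.
#'
#' @param pulse A [pulse_signal()].
#' @param path Output CSV path.
#' @export
write_pulse <- function(pulse, path) {
  utils::write.csv(
    data.frame(t = seq_len(nrow(pulse)) - 1L, value = pulse$value),
    path, row.names = FALSE, quote = FALSE
  )
  meta <- list(fps = trace_fps(pulse), method = attr(pulse, "method"))
  fl <- attr(pulse, "filter")
  if (!is.null(fl)) meta$filter <- unclass(fl)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pulse
#' @param fps Frame rate used when no sidecar is present.
#' @export
read_pulse <- function(path, fps = NULL) {
  d <- utils::read.csv(path)
  side <- paste0(path, ".json")
  method <- NA_character_
  if (is.null(fps) || is.null(method)) {
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side)
      if (is.null(fps)) fps <- meta$fps
      if (!is.null(meta$method)) method <- meta$method
    }
  }
  if (is.null(fps)) stop("no fps given and no JSON sidecar found", call. = FALSE)
  pulse_signal(d$value, fps = fps, method = method)
}

#' Read 68-point landmarks
#'
#' Accepts JSON (`{"points": [[x, y], ...]}`, 68 pairs) or CSV with columns
#' `idx,x,y`. Coordinates from 0-based detectors can be used directly; the
#' `offset` argument shifts detector indices to the package's 1-based
#' convention when a CSV carries 0-based `idx`.
#'
#' @param path JSON or CSV file.
#' @param frame_shape `c(height, width)` in pixels.
#' @param offset Added to CSV `idx` values (use 1 for 0-based detectors).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, frame_shape, offset = 0L) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pts <- jsonlite::read_json(path, simplifyVector = TRUE)$points
    if (is.null(pts)) stop("JSON landmarks must contain a `points` array", call. = FALSE)
    landmark_set(pts, frame_shape)
  } else {
    d <- utils::read.csv(path)
    d$idx <- d$idx + offset
    d <- d[order(d$idx), ]
    if (!identical(as.integer(d$idx), 1:68)) {
      stop("CSV landmarks must cover indices 1..68 after applying `offset`",
           call. = FALSE)
    }
    landmark_set(cbind(d$x, d$y), frame_shape)
  }
}

#' Write a per-subject feature table
#'
#' @param features Tibble with `subject_id` and the eleven canonical
#'   signal-feature columns.
#' @param path Output CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
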
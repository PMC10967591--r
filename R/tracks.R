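#' Track containers and MOTChallenge I/O
#'
#' Detections are stored in a single data frame (one row per detection)
#' grouped by `track_id` into identity trajectories; this mirrors the flat
#' MOTChallenge CSV layout used by essentially every multi-object tracker.
#' Frames are 0-based in memory and 1-based on disk, following the
#' MOTChallenge convention.
#'
#' @name tracks
NULL

.det_cols <- c("frame", "track_id", "x", "y", "w", "h", "conf", "cx", "cy")

#' Construct a track set
#'
#' @param detections data frame with columns `frame` (0-based integer),
#'   `track_id` (positive integer), `x`, `y`, `w`, `h` (bounding box, px; may
#'   be `NA` when only centroids are known), `conf` (confidence in `[0, 1]`
#'   or `NA`) and `cx`, `cy` (centroid, px). Missing `cx`/`cy` are filled
#'   from the box centre.
#' @param fps recording frame rate, Hz.
#' @param frame_size integer (width, height) of the video frame in pixels,
#'   or `NULL` when unknown.
#' @return An object of class `"track_set"`.
#' @export
track_set <- function(detections = NULL, fps = 18, frame_size = NULL) {
  if (is.null(detections) || nrow(detections) == 0L) {
    detections <- data.frame(frame = integer(), track_id = integer(),
                             x = numeric(), y = numeric(), w = numeric(),
                             h = numeric(), conf = numeric(),
                             cx = numeric(), cy = numeric())
  }
  detections <- as.data.frame(detections)
  if (!all(c("frame", "track_id") %in% names(detections))) {
    stop("detections need `frame` and `track_id` columns", call. = FALSE)
  }
  for (col in setdiff(.det_cols, names(detections))) detections[[col]] <- NA_real_
  no_c <- is.na(detections$cx) | is.na(detections$cy)
  detections$cx[no_c] <- detections$x[no_c] + detections$w[no_c] / 2
  detections$cy[no_c] <- detections$y[no_c] + detections$h[no_c] / 2
  detections <- detections[.det_cols]

  if (any(detections$frame < 0)) stop("frame indices must be >= 0", call. = FALSE)
  if (any(detections$track_id < 1)) {
    stop("track ids must be >= 1 (anonymous detections are not tracks)",
         call. = FALSE)
  }
  bad_box <- !is.na(detections$w) & (detections$w <= 0 | detections$h <= 0)
  if (any(bad_box)) stop("bounding boxes must have positive extent", call. = FALSE)
  if (anyDuplicated(detections[c("frame", "track_id")])) {
    stop("duplicate (frame, track_id) pair", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  detections <- detections[order(detections$frame, detections$track_id), ]
  rownames(detections) <- NULL
  structure(list(detections = detections, fps = fps, frame_size = frame_size),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat("Track set:", nrow(x$detections), "detections,",
      length(unique(x$detections$track_id)), "tracks,",
      "fps", x$fps)
  if (!is.null(x$frame_size)) {
    cat(",", x$frame_size[1L], "x", x$frame_size[2L], "px")
  }
  cat("\n")
  invisible(x)
}

#' Number of detections in a track set
#' @param x a `"track_set"`.
#' @export
n_detections <- function(x) nrow(x$detections)

#' Split a track set into per-identity trajectories
#'
#' @param ts a `"track_set"`.
#' @return Named list of data frames, one per track id, rows ordered by frame.
#' @export
trajectories <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  split(ts$detections, ts$detections$track_id)
}

#' Read tracks in MOTChallenge CSV format
#'
#' Expects comma-separated rows `frame, id, bb_left, bb_top, bb_width,
#' bb_height[, conf, x, y, z]` with 1-based frame numbers, converted to
#' 0-based on read. The world-coordinate columns (x, y, z), used by some
#' dialects, are ignored. Rows with `id = -1` (raw detections without an
#' identity) are rejected: this reader is for tracker output.
#'
#' @param path CSV file path.
#' @param fps frame rate to attach, Hz (MOT files do not carry it).
#' @param frame_size optional (width, height) px.
#' @return A `"track_set"`.
#' @export
read_mot <- function(path, fps = 18, frame_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(track_set(fps = fps, frame_size = frame_size))
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed MOT row (fewer than 6 fields) at line ",
         which(nf < 6L)[1L], call. = FALSE)
  }
  num <- suppressWarnings(
    t(vapply(fields, function(f) as.numeric(f[1:6]), numeric(6L)))
  )
  if (anyNA(num)) {
    stop("malformed MOT row (non-numeric field) at line ",
         which(rowSums(is.na(num)) > 0)[1L], call. = FALSE)
  }
  conf <- vapply(fields, function(f) {
    if (length(f) >= 7L) suppressWarnings(as.numeric(f[7L])) else NA_real_
  }, numeric(1L))
  if (any(num[, 1L] < 1)) {
    stop("frame numbers on disk must be 1-based positive integers",
         call. = FALSE)
  }
  if (any(num[, 2L] == -1)) {
    stop("row with id = -1 at line ", which(num[, 2L] == -1)[1L],
         ": detections without identity are not accepted in tracking mode",
         call. = FALSE)
  }
  if (any(num[, 5L] <= 0 | num[, 6L] <= 0)) {
    stop("nonpositive box dimensions at line ",
         which(num[, 5L] <= 0 | num[, 6L] <= 0)[1L], call. = FALSE)
  }
  det <- data.frame(frame = as.integer(num[, 1L]) - 1L,
                    track_id = as.integer(num[, 2L]),
                    x = num[, 3L], y = num[, 4L],
                    w = num[, 5L], h = num[, 6L],
                    conf = conf)
  track_set(det, fps = fps, frame_size = frame_size)
}

#' Write tracks in MOTChallenge CSV format
#'
#' Frames are re-emitted 1-based; missing boxes are written as a 1x1 box at
#' the centroid, missing confidences as 1. Columns x, y, z are emitted as -1
#' per the MOTChallenge convention.
#'
#' @param ts a `"track_set"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  d <- ts$detections
  if (nrow(d) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  x <- ifelse(is.na(d$x), d$cx - 0.5, d$x)
  y <- ifelse(is.na(d$y), d$cy - 0.5, d$y)
  w <- ifelse(is.na(d$w), 1, d$w)
  h <- ifelse(is.na(d$h), 1, d$h)
  conf <- ifelse(is.na(d$conf), 1, d$conf)
  rows <- sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                  d$frame + 1L, d$track_id,
                  format(x, trim = TRUE, digits = 15L),
                  format(y, trim = TRUE, digits = 15L),
                  format(w, trim = TRUE, digits = 15L),
                  format(h, trim = TRUE, digits = 15L),
                  format(conf, trim = TRUE, digits = 15L))
  writeLines(rows, path)
  invisible(path)
}
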
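#' Speed estimation from rectified trajectories
#'
#' After rectification to the top-down view, one pixel corresponds to a fixed
#' physical distance W (m/px), so speed over a frame window \[N, M\] is
#'
#'   V = dY * W / ((M - N) * dt),   dt = 1 / fps
#'
#' with dY the displacement in top-down pixels. The default, camera-faithful
#' mode uses the vertical pixel displacement only (the rectification is
#' constructed so vertical shifts are proportional to distance travelled
#' along the walking surface); a planar Euclidean mode is available because
#' vertical-only displacement underestimates oblique motion.
#'
#' @name speed
NULL

#' Time between consecutive frames
#'
#' @param fps frame rate, Hz.
#' @return Frame interval in seconds (e.g. 18 FPS gives 0.05556 s, i.e.
#'   55.56 ms).
#' @export
frame_interval <- function(fps) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  1 / fps
}

#' Speed computation settings
#'
#' @param fps frame rate, Hz. Default 18.
#' @param window window length M - N in frames over which displacement is
#'   measured. Default 18 (one second at 18 FPS).
#' @param mode `"vertical"` (default): dY is the absolute vertical pixel
#'   displacement in the top-down view; `"euclidean"`: planar displacement
#'   magnitude.
#' @return A list of class `"speed_config"`.
#' @export
speed_config <- function(fps = 18, window = 18L, mode = c("vertical",
                                                          "euclidean")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("`window` must be >= 1 frame", call. = FALSE)
  }
  frame_interval(fps)  # validates fps
  structure(list(fps = fps, window = as.integer(window), mode = mode),
            class = "speed_config")
}

#' Map a track set through a homography
#'
#' Transforms every centroid into the destination (top-down) plane;
#' identities, frames, confidences and the frame rate are preserved.
#' Bounding boxes do not survive a projective map and are dropped.
#'
#' @param ts a `"track_set"` in camera pixel coordinates.
#' @param h a `"homography"` from camera pixels to the top-down view.
#' @return A `"track_set"` with centroids in top-down coordinates.
#' @export
transform_trackset <- function(ts, h) {
  stopifnot(inherits(ts, "track_set"), inherits(h, "homography"))
  d <- ts$detections
  if (nrow(d) == 0L) return(ts)
  q <- h$matrix %*% rbind(d$cx, d$cy, 1)
  w <- q[3L, ]
  bad <- abs(w) < 1e-12
  if (any(bad)) {
    warning(sum(bad), " detection(s) mapped to the line at infinity; dropped")
  }
  out <- data.frame(frame = d$frame, track_id = d$track_id,
                    cx = q[1L, ] / w, cy = q[2L, ] / w,
                    conf = d$conf)[!bad, ]
  track_set(out, fps = ts$fps, frame_size = NULL)
}

#' Windowed speed of a single trajectory
#'
#' Slides a window of `cfg$window` frames along the trajectory in one-frame
#' steps. A window is emitted only when every frame N, N+1, ..., M is
#' present: windows spanning missed detections are skipped rather than
#' interpolated, so no displacement is fabricated across gaps.
#'
#' @param traj data frame for one track (as returned by [trajectories()] on a
#'   top-down track set), with `frame`, `track_id`, `cx`, `cy`.
#' @param cfg a `"speed_config"`.
#' @param pixel_scale metres per top-down pixel (W).
#' @return Data frame with one row per window: `track_id`, `n`, `m` (frame
#'   indices), `delta_y_px`, `velocity_mps`. Zero rows (with a warning) when
#'   the trajectory is shorter than the window.
#' @export
compute_speed <- function(traj, cfg, pixel_scale) {
  stopifnot(inherits(cfg, "speed_config"))
  if (!is.numeric(pixel_scale) || pixel_scale <= 0) {
    stop("`pixel_scale` must be positive (m/px)", call. = FALSE)
  }
  empty <- data.frame(track_id = integer(), n = integer(), m = integer(),
                      delta_y_px = numeric(), velocity_mps = numeric())
  traj <- traj[order(traj$frame), ]
  if (nrow(traj) < cfg$window + 1L) {
    warning("trajectory ", traj$track_id[1L],
            " shorter than window + 1 detections; no speed samples")
    return(empty)
  }
  frames <- traj$frame
  win <- cfg$window
  # index of frame f within traj, NA when missing
  lookup <- match(frames + win, frames)
  starts <- which(!is.na(lookup))
  # require every intermediate frame present: positions must be consecutive
  contiguous <- lookup[starts] - starts == win
  starts <- starts[contiguous]
  if (!length(starts)) return(empty)
  ends <- starts + win
  dy <- abs(traj$cy[ends] - traj$cy[starts])
  disp <- if (cfg$mode == "euclidean") {
    sqrt((traj$cx[ends] - traj$cx[starts])^2 + dy^2)
  } else {
    dy
  }
  dt <- win * frame_interval(cfg$fps)
  data.frame(track_id = traj$track_id[1L],
             n = frames[starts], m = frames[ends],
             delta_y_px = disp,
             velocity_mps = disp * pixel_scale / dt)
}

#' Windowed speeds for every track in a set
#'
#' @param ts a `"track_set"` already in top-down coordinates (see
#'   [transform_trackset()]).
#' @param cfg a `"speed_config"`.
#' @param pixel_scale metres per top-down pixel.
#' @return Data frame of speed samples across tracks (see [compute_speed()]).
#'   Tracks too short for the window contribute no rows.
#' @export
compute_speeds <- function(ts, cfg, pixel_scale) {
  stopifnot(inherits(ts, "track_set"))
  out <- lapply(trajectories(ts), function(tr) {
    suppressWarnings(compute_speed(tr, cfg, pixel_scale))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- compute_speed(ts$detections[0, ], cfg, pixel_scale)
  rownames(res) <- NULL
  res
}

#' Summarize speed samples per track and for the cohort
#'
#' @param samples data frame of speed samples (from [compute_speeds()]).
#' @return List with `per_track` (data frame: track_id, n_samples, mean, min,
#'   max in m/s) and `cohort` (n_samples, mean, min, max), the cohort range
#'   being `[min over tracks, max over tracks]`.
#' @export
summarize_speeds <- function(samples) {
  if (is.null(samples) || nrow(samples) == 0L) {
    stop("no speed samples to summarize", call. = FALSE)
  }
  v <- split(samples$velocity_mps, samples$track_id)
  per_track <- data.frame(
    track_id = as.integer(names(v)),
    n_samples = lengths(v),
    mean_mps = vapply(v, mean, numeric(1L)),
    min_mps = vapply(v, min, numeric(1L)),
    max_mps = vapply(v, max, numeric(1L))
  )
  rownames(per_track) <- NULL
  list(per_track = per_track,
       cohort = list(n_samples = nrow(samples),
                     mean_mps = mean(samples$velocity_mps),
                     min_mps = min(samples$velocity_mps),
                     max_mps = max(samples$velocity_mps)))
}
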
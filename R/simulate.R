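#' Synthetic flock simulator
#'
#' Generates flocks with known ground-truth kinematics so the calibration,
#' speed and evaluation machinery can be validated end-to-end without video.
#' Birds follow a correlated random walk (persistent heading plus wrapped
#' Gaussian turning noise) with a mean-reverting speed process clipped to a
#' configured range, inside a rectangular arena with reflective walls. The
#' world tracks are projected into camera pixels through a homography fitted
#' from the arena rectangle to a configurable 4-corner camera quad — the
#' exact inverse of the calibration the geometry module recovers — and can
#' be degraded into realistic tracker output (centroid jitter, missed
#' detections, false positives, identity swaps).
#'
#' @name simulate
NULL

#' Observation noise model
#'
#' The two presets mirror an easy and a hard tracking condition: birds
#' marked with high-contrast dye are tracked with less jitter and fewer
#' identity errors than unmarked, visually similar birds. Magnitudes are
#' package choices that reproduce the qualitative ordering between the two
#' conditions, not any measured values.
#'
#' @param preset `"dyed"` (low noise), `"undyed"` (elevated noise), or
#'   `"none"` (noiseless pass-through).
#' @param centroid_jitter_sigma isotropic Gaussian jitter on centroids, px.
#' @param miss_prob per-detection probability of a missed detection.
#' @param false_positive_rate expected spurious detections per frame
#'   (Poisson).
#' @param id_swap_prob per-frame probability that the two nearest birds
#'   exchange identities in that frame (momentary occlusion-style
#'   confusion).
#' @return List of class `"observation_model"`.
#' @export
observation_model <- function(preset = c("custom", "dyed", "undyed", "none"),
                              centroid_jitter_sigma = 0,
                              miss_prob = 0,
                              false_positive_rate = 0,
                              id_swap_prob = 0) {
  preset <- match.arg(preset)
  par <- switch(preset,
    dyed = list(sigma = 1, miss = 0.02, fp = 0.02, swap = 0.001),
    undyed = list(sigma = 2, miss = 0.05, fp = 0.05, swap = 0.005),
    none = list(sigma = 0, miss = 0, fp = 0, swap = 0),
    custom = list(sigma = centroid_jitter_sigma, miss = miss_prob,
                  fp = false_positive_rate, swap = id_swap_prob)
  )
  stopifnot(par$sigma >= 0, par$miss >= 0, par$miss <= 1, par$fp >= 0,
            par$swap >= 0, par$swap <= 1)
  structure(list(preset = preset, centroid_jitter_sigma = par$sigma,
                 miss_prob = par$miss, false_positive_rate = par$fp,
                 id_swap_prob = par$swap),
            class = "observation_model")
}

#' Simulation configuration
#'
#' Defaults describe a small floor pen observed by a ceiling camera: an
#' 18 FPS, 1440 x 1080 recording of birds whose long-run mean walking speed
#' is 0.05 m/s within a 0.00-0.21 m/s range.
#'
#' @param arena (width, height) of the arena rectangle, metres.
#' @param n_birds number of birds, 1-20.
#' @param duration_frames number of frames to simulate.
#' @param fps frame rate, Hz.
#' @param frame_size camera frame (width, height), px.
#' @param mean_speed long-run mean speed, m/s.
#' @param speed_bounds (min, max) speed, m/s; must contain `mean_speed`.
#' @param kappa heading persistence in `[0, 1]`; 1 = straight-line motion.
#' @param turn_sd std. dev. of the per-frame turning noise, radians
#'   (scaled by `1 - kappa`).
#' @param speed_sd std. dev. of the per-frame speed innovation, m/s; 0 gives
#'   constant speed `mean_speed`.
#' @param speed_reversion mean-reversion rate of the speed process per
#'   frame, in `[0, 1]`.
#' @param camera_quad 4x2 matrix: pixel corners of the arena rectangle as
#'   seen by the camera, in cyclic order from the arena origin; `NULL` gives
#'   a mildly oblique default quad inside `frame_size`.
#' @param topdown_width_px width of the rectified top-down raster, px;
#'   fixes the pixel scale W = arena width / topdown width.
#' @param init_heading single heading in radians applied to every bird
#'   (0 = +x, pi/2 = +y i.e. downward in the top-down view), or `NULL` for
#'   random headings.
#' @param noise an `"observation_model"` applied by [degrade()].
#' @param seed integer seed; every random draw derives from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(arena = c(4, 3), n_birds = 10, duration_frames = 360,
                       fps = 18, frame_size = c(1440L, 1080L),
                       mean_speed = 0.05, speed_bounds = c(0, 0.21),
                       kappa = 0.8, turn_sd = 0.5, speed_sd = 0.01,
                       speed_reversion = 0.05,
                       camera_quad = NULL, topdown_width_px = 1000,
                       init_heading = NULL,
                       noise = observation_model("none"), seed = 1L) {
  stopifnot(length(arena) == 2L, all(arena > 0),
            length(speed_bounds) == 2L, speed_bounds[1L] <= speed_bounds[2L],
            mean_speed >= speed_bounds[1L], mean_speed <= speed_bounds[2L],
            kappa >= 0, kappa <= 1, turn_sd >= 0, speed_sd >= 0,
            speed_reversion >= 0, speed_reversion <= 1,
            duration_frames >= 1, fps > 0, topdown_width_px > 0,
            inherits(noise, "observation_model"))
  if (n_birds < 1 || n_birds > 20) {
    stop("`n_birds` must be between 1 and 20", call. = FALSE)
  }
  # rough packing bound: a bird occupies ~0.08 m^2 of floor
  if (n_birds * 0.08 > prod(arena)) {
    stop("arena too small for ", n_birds, " birds", call. = FALSE)
  }
  if (is.null(camera_quad)) {
    w <- frame_size[1L]; h <- frame_size[2L]
    camera_quad <- rbind(c(0.15 * w, 0.12 * h), c(0.88 * w, 0.10 * h),
                         c(0.95 * w, 0.92 * h), c(0.08 * w, 0.95 * h))
  }
  camera_quad <- .as_points4(camera_quad, "camera_quad")
  .check_general_position(camera_quad, "camera quad")
  structure(list(arena = arena, n_birds = as.integer(n_birds),
                 duration_frames = as.integer(duration_frames), fps = fps,
                 frame_size = as.integer(frame_size),
                 mean_speed = mean_speed, speed_bounds = speed_bounds,
                 kappa = kappa, turn_sd = turn_sd, speed_sd = speed_sd,
                 speed_reversion = speed_reversion,
                 camera_quad = camera_quad,
                 topdown_width_px = topdown_width_px,
                 init_heading = init_heading,
                 noise = noise, seed = as.integer(seed)),
            class = "sim_config")
}

#' Pixel scale implied by a simulation configuration
#' @param cfg a `"sim_config"`.
#' @return Metres per top-down pixel.
#' @export
sim_pixel_scale <- function(cfg) {
  compute_pixel_scale(cfg$arena[1L], cfg$topdown_width_px)
}

#' Corners of the arena rectangle in top-down pixels
#' @param cfg a `"sim_config"`.
#' @export
sim_topdown_corners <- function(cfg) {
  s <- sim_pixel_scale(cfg)
  wpx <- cfg$arena[1L] / s
  hpx <- cfg$arena[2L] / s
  rbind(c(0, 0), c(wpx, 0), c(wpx, hpx), c(0, hpx))
}

# One bird's correlated random walk; consumes its own RNG substream so
# adding birds never perturbs existing trajectories.
.walk_bird <- function(cfg, bird) {
  set.seed(cfg$seed + bird * 10007L)
  t_n <- cfg$duration_frames
  dt <- 1 / cfg$fps
  margin <- 0.05 * min(cfg$arena)
  pos <- c(stats::runif(1, margin, cfg$arena[1L] - margin),
           stats::runif(1, margin, cfg$arena[2L] - margin))
  theta <- if (is.null(cfg$init_heading)) stats::runif(1, 0, 2 * pi) else
    cfg$init_heading
  s <- if (cfg$speed_sd == 0) cfg$mean_speed else
    min(max(stats::rnorm(1, cfg$mean_speed, cfg$speed_sd),
            cfg$speed_bounds[1L]), cfg$speed_bounds[2L])
  xs <- ys <- sp <- hd <- numeric(t_n)
  for (t in seq_len(t_n)) {
    xs[t] <- pos[1L]; ys[t] <- pos[2L]; sp[t] <- s; hd[t] <- theta
    step <- s * dt * c(cos(theta), sin(theta))
    nxt <- pos + step
    # reflective walls: fold position back in and mirror the heading
    # (steps are far shorter than the arena, so one fold suffices)
    if (nxt[1L] < 0) {
      nxt[1L] <- -nxt[1L]; theta <- pi - theta
    } else if (nxt[1L] > cfg$arena[1L]) {
      nxt[1L] <- 2 * cfg$arena[1L] - nxt[1L]; theta <- pi - theta
    }
    if (nxt[2L] < 0) {
      nxt[2L] <- -nxt[2L]; theta <- -theta
    } else if (nxt[2L] > cfg$arena[2L]) {
      nxt[2L] <- 2 * cfg$arena[2L] - nxt[2L]; theta <- -theta
    }
    pos <- nxt
    theta <- theta + (1 - cfg$kappa) * stats::rnorm(1, 0, cfg$turn_sd)
    if (cfg$speed_sd > 0 || cfg$speed_reversion > 0) {
      s <- s + cfg$speed_reversion * (cfg$mean_speed - s) +
        if (cfg$speed_sd > 0) stats::rnorm(1, 0, cfg$speed_sd) else 0
      s <- min(max(s, cfg$speed_bounds[1L]), cfg$speed_bounds[2L])
    }
  }
  data.frame(frame = seq_len(t_n) - 1L, track_id = bird,
             x_m = xs, y_m = ys, speed_mps = sp, heading = hd)
}

#' Simulate a flock with known ground truth
#'
#' @param cfg a `"sim_config"`.
#' @return List of class `"ground_truth"` with `world` (data frame: frame,
#'   track_id, x_m, y_m, speed_mps, heading), `pixels` (the camera-view
#'   `"track_set"`, via [project_to_pixels()]), `pixel_scale` (m per
#'   top-down px) and `config`. Deterministic given `cfg$seed`.
#' @export
simulate_flock <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  world <- do.call(rbind, lapply(seq_len(cfg$n_birds), .walk_bird,
                                 cfg = cfg))
  rownames(world) <- NULL
  pixels <- project_to_pixels(world, cfg)
  structure(list(world = world, pixels = pixels,
                 pixel_scale = sim_pixel_scale(cfg), config = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", x$config$n_birds, "birds x",
      x$config$duration_frames, "frames, pixel scale",
      format(x$pixel_scale), "m/px\n")
  invisible(x)
}

#' Project world trajectories into camera pixels
#'
#' World coordinates (metres) are first expressed in top-down pixels using
#' the configured pixel scale, then mapped through the homography fitted
#' from the arena's top-down corners to the camera quad — the exact inverse
#' of the map recovered by calibrating on that same quad.
#'
#' @param world data frame with `frame`, `track_id`, `x_m`, `y_m`.
#' @param cfg a `"sim_config"` (supplies camera quad, arena and scale).
#' @return A `"track_set"` in camera pixel coordinates.
#' @export
project_to_pixels <- function(world, cfg) {
  s <- sim_pixel_scale(cfg)
  h <- fit_homography(sim_topdown_corners(cfg), cfg$camera_quad,
                      pixel_scale = s)
  td <- cbind(world$x_m / s, world$y_m / s)
  px <- apply_homography(h, td)
  track_set(data.frame(frame = world$frame, track_id = world$track_id,
                       cx = px[, 1L], cy = px[, 2L]),
            fps = cfg$fps, frame_size = cfg$frame_size)
}

#' Calibration record matching a simulation's camera
#'
#' Returns the calibration (camera quad + arena dimensions) that
#' [read_calibration()] would consume to undo [project_to_pixels()].
#'
#' @param cfg a `"sim_config"`.
#' @return Calibration list as accepted by [write_calibration()].
#' @export
sim_calibration <- function(cfg) {
  list(src_points = cfg$camera_quad, rect_width_m = cfg$arena[1L],
       rect_height_m = cfg$arena[2L],
       topdown_width_px = cfg$topdown_width_px)
}

#' Degrade ground-truth tracks into realistic tracker output
#'
#' Applies, in order: momentary identity swaps between the two nearest
#' birds (per frame, with the model's swap probability), deletion of each
#' detection with the miss probability, isotropic Gaussian centroid jitter,
#' and Poisson false positives placed uniformly in the frame under fresh
#' identities. Reproducible given `seed`.
#'
#' @param ts ground-truth `"track_set"` in camera pixels.
#' @param model an `"observation_model"`.
#' @param seed integer seed for the degradation stream.
#' @return A degraded `"track_set"`.
#' @export
degrade <- function(ts, model, seed = 1L) {
  stopifnot(inherits(ts, "track_set"), inherits(model, "observation_model"))
  d <- ts$detections
  if (model$centroid_jitter_sigma == 0 && model$miss_prob == 0 &&
      model$false_positive_rate == 0 && model$id_swap_prob == 0) {
    return(ts)
  }
  set.seed(seed)
  frames <- sort(unique(d$frame))

  # momentary identity swaps: with the model's probability per frame, the
  # two nearest birds exchange ids in that frame only, emulating
  # occlusion-induced confusion from which the tracker recovers
  if (model$id_swap_prob > 0) {
    for (f in frames) {
      if (stats::runif(1) < model$id_swap_prob) {
        rows <- which(d$frame == f)
        if (length(rows) >= 2L) {
          dm <- as.matrix(stats::dist(d[rows, c("cx", "cy")]))
          diag(dm) <- Inf
          nearest <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
          a <- rows[nearest[1L]]; b <- rows[nearest[2L]]
          tmp <- d$track_id[a]
          d$track_id[a] <- d$track_id[b]
          d$track_id[b] <- tmp
        }
      }
    }
  }

  if (model$miss_prob > 0) {
    d <- d[stats::runif(nrow(d)) >= model$miss_prob, , drop = FALSE]
  }
  if (model$centroid_jitter_sigma > 0 && nrow(d)) {
    d$cx <- d$cx + stats::rnorm(nrow(d), 0, model$centroid_jitter_sigma)
    d$cy <- d$cy + stats::rnorm(nrow(d), 0, model$centroid_jitter_sigma)
  }
  if (model$false_positive_rate > 0) {
    n_fp <- stats::rpois(length(frames), model$false_positive_rate)
    total <- sum(n_fp)
    if (total > 0L) {
      fs <- if (is.null(ts$frame_size)) c(1440L, 1080L) else ts$frame_size
      next_id <- max(ts$detections$track_id) + 1000L
      fp <- data.frame(frame = rep(frames, n_fp),
                       track_id = next_id + seq_len(total) - 1L,
                       cx = stats::runif(total, 0, fs[1L]),
                       cy = stats::runif(total, 0, fs[2L]))
      d <- rbind(d[c("frame", "track_id", "cx", "cy")],
                 fp)
    }
  }
  track_set(d[c("frame", "track_id", "cx", "cy")], fps = ts$fps,
            frame_size = ts$frame_size)
}

#' Render elliptical body masks for simulated birds
#'
#' Draws a filled ellipse per bird per frame, centred on the bird's pixel
#' centroid and oriented along its apparent (pixel-space) motion direction.
#' Ellipses reaching outside the frame are clipped with a message.
#'
#' @param gt a `"ground_truth"` (from [simulate_flock()]).
#' @param semi_axes (a, b) ellipse semi-axes in pixels, along and across the
#'   heading.
#' @param frames 0-based frame indices to render (default: all).
#' @return List of `"mask_rle"`, one per bird per rendered frame.
#' @export
render_masks <- function(gt, semi_axes = c(25, 15), frames = NULL) {
  stopifnot(inherits(gt, "ground_truth"), all(semi_axes > 0))
  d <- gt$pixels$detections
  if (is.null(frames)) frames <- sort(unique(d$frame))
  fs <- gt$config$frame_size
  a <- semi_axes[1L]; b <- semi_axes[2L]
  out <- list()
  clipped <- 0L
  d <- d[order(d$track_id, d$frame), ]
  for (id in unique(d$track_id)) {
    tr <- d[d$track_id == id, ]
    for (f in frames) {
      i <- match(f, tr$frame)
      if (is.na(i)) next
      cx <- tr$cx[i]; cy <- tr$cy[i]
      j <- if (i < nrow(tr)) i + 1L else i - 1L
      dx <- tr$cx[j] - tr$cx[i]; dy <- tr$cy[j] - tr$cy[i]
      ang <- if (dx == 0 && dy == 0) 0 else atan2(dy, dx)
      r <- max(a, b)
      x0 <- floor(cx - r); x1 <- ceiling(cx + r)
      y0 <- floor(cy - r); y1 <- ceiling(cy + r)
      if (x0 < 0 || y0 < 0 || x1 > fs[1L] - 1L || y1 > fs[2L] - 1L) {
        clipped <- clipped + 1L
      }
      xs <- max(0, x0):min(fs[1L] - 1L, x1)
      ys <- max(0, y0):min(fs[2L] - 1L, y1)
      ex <- outer(rep(1, length(ys)), xs) - cx
      ey <- outer(ys, rep(1, length(xs))) - cy
      inside <- ((ex * cos(ang) + ey * sin(ang)) / a)^2 +
        ((-ex * sin(ang) + ey * cos(ang)) / b)^2 <= 1
      raster <- matrix(FALSE, fs[2L], fs[1L])
      raster[cbind(rep(ys + 1L, length(xs))[as.vector(inside)],
                   rep(xs + 1L, each = length(ys))[as.vector(inside)])] <- TRUE
      out[[length(out) + 1L]] <- encode_rle(raster, frame = f, track_id = id)
    }
  }
  if (clipped > 0L) message(clipped, " ellipse(s) clipped at frame edge")
  out
}
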
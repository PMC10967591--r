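# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

# random invertible homography with bounded perspective terms, normalized
random_homography <- function() {
  repeat {
    m <- matrix(c(stats::runif(2, 0.5, 2), stats::runif(1, -0.3, 0.3),
                  stats::runif(1, -0.3, 0.3), stats::runif(2, 0.5, 2),
                  stats::runif(2, -1e-3, 1e-3), 1),
                3L, 3L, byrow = TRUE)
    m[1L, 2L] <- stats::runif(1, -0.3, 0.3)
    m[2L, 1L] <- stats::runif(1, -0.3, 0.3)
    m[1L, 3L] <- stats::runif(1, -50, 50)
    m[2L, 3L] <- stats::runif(1, -50, 50)
    if (abs(det(m)) > 1e-3) return(homography(m))
  }
}

# four points in general position in [0, span]^2
random_quad <- function(span = 100) {
  repeat {
    p <- matrix(stats::runif(8, 0, span), 4L, 2L)
    ok <- tryCatch({
      flockmotion:::.check_general_position(p, "test")
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(p)
  }
}

# small track set: n_tracks random walks over n_frames in a box
random_trackset <- function(n_tracks, n_frames, frame_size = c(200L, 150L),
                            step_sd = 3) {
  det <- do.call(rbind, lapply(seq_len(n_tracks), function(id) {
    x <- cumsum(c(stats::runif(1, 20, frame_size[1L] - 20),
                  stats::rnorm(n_frames - 1L, 0, step_sd)))
    y <- cumsum(c(stats::runif(1, 20, frame_size[2L] - 20),
                  stats::rnorm(n_frames - 1L, 0, step_sd)))
    data.frame(frame = seq_len(n_frames) - 1L, track_id = id,
               cx = pmin(pmax(x, 0), frame_size[1L]),
               cy = pmin(pmax(y, 0), frame_size[2L]))
  }))
  track_set(det, fps = 18, frame_size = frame_size)
}

# perturb a track set into plausible tracker output using plain R draws
# (deliberately not via degrade(), so simulator and metrics tests stay
# independent)
perturb_trackset <- function(ts, jitter = 2, drop_prob = 0.1,
                             fp_per_frame = 0.1, swap_frames = integer()) {
  d <- ts$detections
  for (f in swap_frames) {
    rows <- which(d$frame >= f)
    ids <- sort(unique(d$track_id))
    if (length(ids) >= 2L) {
      pick <- sample(ids, 2L)
      a <- rows[d$track_id[rows] == pick[1L]]
      b <- rows[d$track_id[rows] == pick[2L]]
      d$track_id[a] <- pick[2L]; d$track_id[b] <- pick[1L]
    }
  }
  keep <- stats::runif(nrow(d)) >= drop_prob
  d <- d[keep, ]
  d$cx <- d$cx + stats::rnorm(nrow(d), 0, jitter)
  d$cy <- d$cy + stats::rnorm(nrow(d), 0, jitter)
  frames <- sort(unique(ts$detections$frame))
  nfp <- stats::rpois(length(frames), fp_per_frame)
  if (sum(nfp) > 0) {
    fp <- data.frame(frame = rep(frames, nfp),
                     track_id = 500L + seq_len(sum(nfp)),
                     cx = stats::runif(sum(nfp), 0, ts$frame_size[1L]),
                     cy = stats::runif(sum(nfp), 0, ts$frame_size[2L]))
    d <- rbind(d[c("frame", "track_id", "cx", "cy")], fp)
  }
  track_set(d[c("frame", "track_id", "cx", "cy")], fps = ts$fps,
            frame_size = ts$frame_size)
}

# random blob raster for mask tests
random_raster <- function(h = 12L, w = 16L, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}
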
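test_that("simulation is deterministic and birds have independent streams", {
  cfg <- sim_config(n_birds = 5, duration_frames = 50, seed = 123)
  a <- simulate_flock(cfg)
  b <- simulate_flock(cfg)
  expect_identical(a$world, b$world)
  expect_identical(a$pixels$detections, b$pixels$detections)

  # adding a bird must not perturb existing trajectories
  cfg6 <- sim_config(n_birds = 6, duration_frames = 50, seed = 123)
  c6 <- simulate_flock(cfg6)
  expect_identical(c6$world[c6$world$track_id <= 5, ], a$world)
})

test_that("kappa = 1 with zero speed noise gives straight constant motion", {
  cfg <- sim_config(n_birds = 1, duration_frames = 30, kappa = 1,
                    turn_sd = 0, speed_sd = 0, speed_reversion = 0,
                    mean_speed = 0.05, init_heading = pi / 4, seed = 5)
  gt <- simulate_flock(cfg)
  w <- gt$world
  expect_true(all(w$speed_mps == 0.05))
  # consecutive displacement vectors are identical until a wall is met
  dx <- diff(w$x_m); dy <- diff(w$y_m)
  step <- 0.05 / cfg$fps
  expect_equal(sqrt(dx^2 + dy^2), rep(step, 29), tolerance = 1e-12)
  hit_wall <- any(abs(diff(sign(dx))) > 0) || any(abs(diff(sign(dy))) > 0)
  if (!hit_wall) {
    expect_lt(max(abs(dx - dx[1])), 1e-12)
    expect_lt(max(abs(dy - dy[1])), 1e-12)
  }
})

test_that("speeds stay in bounds, positions in the arena", {
  cfg <- sim_config(n_birds = 8, duration_frames = 300, seed = 31)
  gt <- simulate_flock(cfg)
  expect_true(all(gt$world$speed_mps >= cfg$speed_bounds[1]))
  expect_true(all(gt$world$speed_mps <= cfg$speed_bounds[2]))
  expect_true(all(gt$world$x_m >= 0 & gt$world$x_m <= cfg$arena[1]))
  expect_true(all(gt$world$y_m >= 0 & gt$world$y_m <= cfg$arena[2]))
})

test_that("long-run mean speed approaches the configured mean", {
  cfg <- sim_config(n_birds = 10, duration_frames = 1000, seed = 77)
  gt <- simulate_flock(cfg)
  bird_means <- tapply(gt$world$speed_mps, gt$world$track_id, mean)
  se <- stats::sd(bird_means) / sqrt(length(bird_means))
  expect_lt(abs(mean(bird_means) - cfg$mean_speed), 3 * se)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_birds = 21), "between 1 and 20")
  expect_error(sim_config(n_birds = 0), "between 1 and 20")
  expect_error(sim_config(arena = c(0.3, 0.3), n_birds = 20), "too small")
  expect_error(sim_config(camera_quad = rbind(c(0, 0), c(1, 1), c(2, 2),
                                              c(0, 5))), "collinear")
})

test_that("axis-aligned camera reduces projection to pure scaling", {
  cfg <- sim_config(n_birds = 3, duration_frames = 20, seed = 9,
                    arena = c(4, 3), topdown_width_px = 1000,
                    camera_quad = rbind(c(0, 0), c(1000, 0), c(1000, 750),
                                        c(0, 750)))
  gt <- simulate_flock(cfg)
  s <- sim_pixel_scale(cfg)
  w <- gt$world[order(gt$world$frame, gt$world$track_id), ]
  expect_equal(gt$pixels$detections$cx, w$x_m / s, tolerance = 1e-9)
  expect_equal(gt$pixels$detections$cy, w$y_m / s, tolerance = 1e-9)
})

test_that("projection keeps straight world lines straight", {
  cfg <- sim_config(n_birds = 1, duration_frames = 5, seed = 3)
  line <- data.frame(frame = 0:9, track_id = 1L,
                     x_m = seq(0.5, 3.5, length.out = 10),
                     y_m = seq(0.4, 2.6, length.out = 10))
  px <- project_to_pixels(line, cfg)$detections
  # collinearity: all cross products with the first segment vanish
  v1 <- c(px$cx[2] - px$cx[1], px$cy[2] - px$cy[1])
  for (i in 3:10) {
    vi <- c(px$cx[i] - px$cx[1], px$cy[i] - px$cy[1])
    expect_lt(abs(v1[1] * vi[2] - v1[2] * vi[1]) /
                (sqrt(sum(v1^2)) * sqrt(sum(vi^2))), 1e-9)
  }
})

test_that("zero noise degrades to the identical track set", {
  cfg <- sim_config(n_birds = 4, duration_frames = 30, seed = 11)
  gt <- simulate_flock(cfg)
  out <- degrade(gt$pixels, observation_model("none"), seed = 4)
  expect_identical(out$detections, gt$pixels$detections)
})

test_that("deletion fraction concentrates around miss_prob", {
  cfg <- sim_config(n_birds = 10, duration_frames = 1000, seed = 13)
  gt <- simulate_flock(cfg)
  n <- n_detections(gt$pixels)  # 10000 detections
  model <- observation_model("custom", miss_prob = 0.2)
  out <- degrade(gt$pixels, model, seed = 21)
  frac <- 1 - n_detections(out) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("identity swaps surface as identity switches in evaluation", {
  cfg <- sim_config(n_birds = 6, duration_frames = 400, seed = 17)
  gt <- simulate_flock(cfg)
  model <- observation_model("custom", id_swap_prob = 0.05)
  out <- degrade(gt$pixels, model, seed = 19)
  m <- match_tracks(gt$pixels, out)
  expect_gt(m$counts$identity_switches, 0L)
})

test_that("degradation is reproducible from its seed", {
  cfg <- sim_config(n_birds = 5, duration_frames = 60, seed = 23)
  gt <- simulate_flock(cfg)
  model <- observation_model("undyed")
  a <- degrade(gt$pixels, model, seed = 29)
  b <- degrade(gt$pixels, model, seed = 29)
  expect_identical(a$detections, b$detections)
})

test_that("rendered ellipse masks sit on the bird with the right area", {
  cfg <- sim_config(n_birds = 3, duration_frames = 6, seed = 37,
                    frame_size = c(400L, 300L), arena = c(2, 1.5),
                    topdown_width_px = 400,
                    camera_quad = rbind(c(40, 30), c(360, 40), c(380, 270),
                                        c(20, 280)))
  gt <- simulate_flock(cfg)
  masks <- suppressMessages(render_masks(gt, semi_axes = c(25, 15),
                                         frames = 0:2))
  expect_identical(length(masks), 9L)
  det <- gt$pixels$detections
  for (m in masks) {
    row <- det[det$frame == m$frame & det$track_id == m$track_id, ]
    cen <- mask_centroid(m)
    expect_lt(abs(cen["u"] - row$cx), 0.5)
    expect_lt(abs(cen["v"] - row$cy), 0.5)
    # area within 2% of pi*a*b (discretization), unless clipped
    if (row$cx > 30 && row$cx < 370 && row$cy > 30 && row$cy < 270) {
      expect_lt(abs(mask_area(m) - pi * 25 * 15) / (pi * 25 * 15), 0.02)
    }
  }
  # distinct birds far apart have IoU 0
  same_frame <- Filter(function(m) m$frame == 0L, masks)
  d01 <- sqrt((det$cx[det$frame == 0][1] - det$cx[det$frame == 0][2])^2 +
              (det$cy[det$frame == 0][1] - det$cy[det$frame == 0][2])^2)
  if (d01 > 30) {
    expect_identical(iou(same_frame[[1]], same_frame[[2]]), 0)
  }
})
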
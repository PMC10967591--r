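test_that("perfect tracking yields perfect counts and scores", {
  set.seed(41)
  gt <- random_trackset(4, 30)
  m <- match_tracks(gt, gt)
  expect_identical(m$counts$true_positives, n_detections(gt))
  expect_identical(m$counts$false_positives, 0L)
  expect_identical(m$counts$misses, 0L)
  expect_identical(m$counts$identity_switches, 0L)
  expect_identical(mota(m$counts), 1)
  idm <- identification_metrics(gt, gt)
  expect_identical(c(idm$idp, idm$idr, idm$idf1), c(1, 1, 1))
})

test_that("a single removed detection is one miss", {
  set.seed(43)
  gt <- random_trackset(3, 20)
  pred <- gt
  pred$detections <- pred$detections[-7, ]
  m <- match_tracks(gt, pred)
  expect_identical(m$counts$misses, 1L)
  expect_identical(m$counts$false_positives, 0L)
  expect_equal(mota(m$counts), 1 - 1 / n_detections(gt))
})

test_that("mota reproduces its formula on randomized counts", {
  expect_equal(mota(list(false_positives = 1, misses = 1,
                         identity_switches = 1, total_gt = 10)), 0.7)
  set.seed(47)
  for (i in 1:200) {
    c <- list(false_positives = sample(0:50, 1), misses = sample(0:50, 1),
              identity_switches = sample(0:20, 1),
              total_gt = sample(1:100, 1))
    expect_equal(mota(c),
                 1 - (c$false_positives + c$misses + c$identity_switches) /
                   c$total_gt, tolerance = 1e-15)
  }
  expect_error(mota(list(false_positives = 0, misses = 0,
                         identity_switches = 0, total_gt = 0)), "undefined")
})

test_that("idf1 is the harmonic mean of idp and idr", {
  expect_equal(round(idf1(0.8, 0.5), 4), 0.6154)
  expect_identical(idf1(0, 0), 0)
  set.seed(53)
  p <- stats::runif(1000); r <- stats::runif(1000)
  expect_equal(idf1(p, r), 2 * p * r / (p + r), tolerance = 1e-15)
})

test_that("iou handles identical, disjoint and half-overlapping shapes", {
  r1 <- matrix(FALSE, 20, 20); r1[1:10, 1:10] <- TRUE
  m1 <- encode_rle(r1)
  expect_identical(iou(m1, m1), 1)
  r2 <- matrix(FALSE, 20, 20); r2[11:20, 11:20] <- TRUE
  expect_identical(iou(m1, encode_rle(r2)), 0)
  # equal squares overlapping by half their area: 0.5A / 1.5A = 1/3
  r3 <- matrix(FALSE, 20, 20); r3[1:10, 6:15] <- TRUE
  expect_equal(iou(m1, encode_rle(r3)), 1 / 3)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 10, 10)), 1 / 3)
  expect_warning(v <- iou(encode_rle(matrix(FALSE, 3, 3)),
                          encode_rle(matrix(FALSE, 3, 3))), "empty")
  expect_identical(v, 0)
  expect_error(iou(m1, encode_rle(matrix(FALSE, 5, 5))), "frame size")
})

test_that("iou is symmetric and matches brute-force set computation", {
  set.seed(59)
  for (i in 1:100) {
    a <- random_raster(10, 14, stats::runif(1, 0.1, 0.9))
    b <- random_raster(10, 14, stats::runif(1, 0.1, 0.9))
    if (!any(a | b)) next
    ma <- encode_rle(a); mb <- encode_rle(b)
    want <- sum(a & b) / sum(a | b)
    expect_equal(iou(ma, mb), want, tolerance = 1e-15)
    expect_identical(iou(ma, mb), iou(mb, ma))
  }
})

test_that("miou averages per-class IoU and excludes absent classes", {
  full <- encode_rle(matrix(TRUE, 8, 8))
  empty_r <- matrix(FALSE, 8, 8); empty_r[1, 1] <- TRUE
  off <- matrix(FALSE, 8, 8); off[8, 8] <- TRUE
  expect_identical(miou(list(a = list(full)), list(a = list(full))), 1)
  expect_equal(miou(list(a = list(full), b = list(encode_rle(empty_r))),
                    list(a = list(full), b = list(encode_rle(off)))), 0.5)
  expect_warning(
    v <- miou(list(a = list(full), ghost = list()),
              list(a = list(full), ghost = list())), "neither")
  expect_identical(v, 1)
  # multi-instance classes are unioned before comparison
  i1 <- matrix(FALSE, 8, 8); i1[1:4, ] <- TRUE
  i2 <- matrix(FALSE, 8, 8); i2[5:8, ] <- TRUE
  expect_identical(
    miou(list(a = list(encode_rle(i1), encode_rle(i2))),
         list(a = list(full))), 1)
})

test_that("rmse matches its definition and edge cases", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(signif(rmse(c(0, 0), c(0.03, 0.04)), 4), 0.03536)
  set.seed(61)
  y <- stats::rnorm(50)
  expect_equal(rmse(y, y + 0.7), 0.7, tolerance = 1e-12)
  for (i in 1:50) {
    a <- stats::rnorm(20); b <- stats::rnorm(20)
    expect_equal(rmse(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-15)
    expect_identical(rmse(a, b) == 0, all(a == b))
  }
  expect_error(rmse(numeric(), numeric()), "nonzero")
  expect_error(rmse(1:3, 1:2), "equal")
})

test_that("fps throughput is frames over elapsed seconds", {
  expect_identical(fps_throughput(180, 10), 18)
  expect_identical(fps_throughput(0, 10), 0)
  expect_error(fps_throughput(10, 0), "positive")
})

test_that("clear-mot counts match the brute-force reference", {
  set.seed(67)
  for (i in 1:15) {
    gt <- random_trackset(sample(2:5, 1), sample(20:40, 1))
    pred <- perturb_trackset(gt, jitter = 2, drop_prob = 0.1,
                             fp_per_frame = 0.1,
                             swap_frames = sample(5:15, sample(0:2, 1)))
    thr <- 15
    m <- match_tracks(gt, pred, threshold = thr)
    ref <- oracle_clearmot(gt, pred, thr)
    expect_identical(m$counts$true_positives, ref$tp)
    expect_identical(m$counts$false_positives, ref$fp)
    expect_identical(m$counts$misses, ref$miss)
    expect_identical(m$counts$identity_switches, ref$ids)
    expect_equal(mota(m$counts), ref$mota, tolerance = 1e-12)

    idm <- identification_metrics(gt, pred, threshold = thr)
    refi <- oracle_idmetrics(gt, pred, thr)
    expect_equal(idm$idtp, refi$idtp)
    expect_equal(idm$idf1, refi$idf1, tolerance = 1e-12)
  }
})

test_that("injected identity swaps never raise mota or idf1", {
  set.seed(71)
  gt <- random_trackset(4, 60)
  base <- perturb_trackset(gt, jitter = 1, drop_prob = 0.02,
                           fp_per_frame = 0.02)
  prev_mota <- mota(match_tracks(gt, base, threshold = 15)$counts)
  prev_idf1 <- identification_metrics(gt, base, threshold = 15)$idf1
  cur <- base
  for (f in c(15, 30, 45)) {
    d <- cur$detections
    rows <- which(d$frame >= f)
    a <- rows[d$track_id[rows] == 1L]
    b <- rows[d$track_id[rows] == 2L]
    d$track_id[a] <- 2L; d$track_id[b] <- 1L
    cur <- track_set(d, fps = cur$fps, frame_size = cur$frame_size)
    cur_mota <- mota(match_tracks(gt, cur, threshold = 15)$counts)
    cur_idf1 <- identification_metrics(gt, cur, threshold = 15)$idf1
    expect_lte(cur_mota, prev_mota + 1e-12)
    expect_lte(cur_idf1, prev_idf1 + 1e-12)
    prev_mota <- cur_mota; prev_idf1 <- cur_idf1
  }
})

test_that("mismatched frame rates and empty inputs are handled", {
  set.seed(73)
  gt <- random_trackset(2, 10)
  pred <- gt
  pred$fps <- 30
  expect_error(match_tracks(gt, pred), "fps")
  empty <- track_set(fps = 18, frame_size = c(200L, 150L))
  expect_warning(idm <- identification_metrics(empty, empty), "empty")
  expect_identical(idm$idf1, 1)
  m <- match_tracks(gt, empty)
  expect_identical(m$counts$misses, n_detections(gt))
  expect_error(mota(match_tracks(empty, gt)$counts), "undefined")
})
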
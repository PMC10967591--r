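#' Planar homography calibration
#'
#' Overhead video distorts distances: a step near the far wall spans fewer
#' pixels than the same step under the camera. The cure is to rectify the
#' floor plane to a top-down view in which one pixel corresponds to a fixed
#' physical distance. A 3x3 projective matrix (homography) between the camera
#' plane and the top-down plane is fully determined by four point
#' correspondences in general position, typically the corners of a rectangle
#' of known physical size laid on the floor.
#'
#' @name geometry
NULL

#' Construct a homography object
#'
#' @param matrix 3x3 invertible projective matrix; it is re-normalized so the
#'   bottom-right entry equals 1.
#' @param pixel_scale physical distance represented by one pixel in the
#'   top-down view, in metres per pixel. Must be positive.
#' @return An object of class `"homography"` with elements `matrix` and
#'   `pixel_scale`.
#' @export
homography <- function(matrix, pixel_scale = 1) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(3L, 3L)) ||
      !all(is.finite(matrix))) {
    stop("`matrix` must be a finite 3x3 matrix", call. = FALSE)
  }
  if (abs(det(matrix)) <= .Machine$double.eps * max(abs(matrix))^3) {
    stop("homography matrix is singular", call. = FALSE)
  }
  if (abs(matrix[3L, 3L]) < 1e-12 * max(abs(matrix))) {
    stop("cannot normalize: bottom-right entry is (near) zero", call. = FALSE)
  }
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L ||
      !is.finite(pixel_scale) || pixel_scale <= 0) {
    stop("`pixel_scale` must be a single positive number (m/px)", call. = FALSE)
  }
  m <- matrix / matrix[3L, 3L]
  m[3L, 3L] <- 1  # exact, not up to rounding
  structure(list(matrix = m, pixel_scale = pixel_scale),
            class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("Planar homography (pixel scale", format(x$pixel_scale),
      "m/px)\n")
  print(x$matrix)
  invisible(x)
}

# Similarity transform centring points on the origin with mean distance
# sqrt(2) (Hartley's preconditioning for the DLT).
.normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1L],
           0, s, -s * ctr[2L],
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

.check_general_position <- function(pts, label) {
  combs <- utils::combn(4L, 3L)
  scale2 <- max(stats::dist(pts))^2
  for (k in seq_len(ncol(combs))) {
    p <- pts[combs[, k], , drop = FALSE]
    cross <- (p[2L, 1L] - p[1L, 1L]) * (p[3L, 2L] - p[1L, 2L]) -
             (p[2L, 2L] - p[1L, 2L]) * (p[3L, 1L] - p[1L, 1L])
    if (abs(cross) <= 1e-9 * max(scale2, 1)) {
      stop("degenerate calibration: three ", label,
           " points are (near) collinear", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.as_points4 <- function(p, name) {
  p <- as.matrix(p)
  if (!is.numeric(p) || nrow(p) != 4L || ncol(p) != 2L || !all(is.finite(p))) {
    stop("`", name, "` must be 4 finite (x, y) points as a 4x2 matrix",
         call. = FALSE)
  }
  unname(p)
}

#' Fit a homography from four point correspondences
#'
#' Estimates the projective map taking each source point to its destination
#' point, by the direct linear transform on Hartley-normalized coordinates.
#' Four correspondences in general position determine the map exactly: the
#' fitted matrix reproduces the inputs to numerical precision rather than in
#' a least-squares sense.
#'
#' @param src 4x2 matrix of source points (pixel coordinates, origin top-left,
#'   v downward), one row per point.
#' @param dst 4x2 matrix of destination points (top-down pixel or metric
#'   coordinates), rows corresponding to `src` in the same cyclic order.
#' @param pixel_scale metres per pixel of the destination plane; stored on the
#'   result (see [compute_pixel_scale()]).
#' @return A `"homography"` mapping `src` onto `dst`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' fit_homography(sq, sq)  # identity
#' @export
fit_homography <- function(src, dst, pixel_scale = 1) {
  src <- .as_points4(src, "src")
  dst <- .as_points4(dst, "dst")
  .check_general_position(src, "source")
  .check_general_position(dst, "destination")

  t_src <- .normalizing_transform(src)
  t_dst <- .normalizing_transform(dst)
  ns <- t(t_src %*% rbind(t(src), 1))[, 1:2]
  nd <- t(t_dst %*% rbind(t(dst), 1))[, 1:2]

  # Two DLT rows per correspondence: A %*% h = 0 with h the stacked matrix.
  a <- matrix(0, 8L, 9L)
  for (i in 1:4) {
    x <- ns[i, 1L]; y <- ns[i, 2L]
    u <- nd[i, 1L]; v <- nd[i, 2L]
    a[2L * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    a[2L * i, ]      <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(a, nu = 0L, nv = 9L)$v[, 9L]
  hn <- matrix(h, 3L, 3L, byrow = TRUE)
  m <- solve(t_dst) %*% hn %*% t_src
  homography(m, pixel_scale = pixel_scale)
}

#' Apply a homography to points
#'
#' Maps points through the projective transform and dehomogenizes.
#'
#' @param h a `"homography"`.
#' @param p an (x, y) point or an n x 2 matrix of points.
#' @return Points of the same shape as `p`, in destination coordinates.
#' @export
apply_homography <- function(h, p) {
  stopifnot(inherits(h, "homography"))
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(p, 1L, 2L) else as.matrix(p)
  if (ncol(pm) != 2L || !all(is.finite(pm))) {
    stop("points must be finite (x, y) pairs", call. = FALSE)
  }
  q <- h$matrix %*% rbind(t(pm), 1)
  w <- q[3L, ]
  if (any(abs(w) < 1e-12)) {
    stop("point maps to the line at infinity", call. = FALSE)
  }
  out <- cbind(q[1L, ] / w, q[2L, ] / w)
  if (vec) out[1L, ] else out
}

#' Invert a homography
#'
#' @param h a `"homography"`.
#' @return The inverse map, re-normalized, carrying the same pixel scale.
#' @export
invert_homography <- function(h) {
  stopifnot(inherits(h, "homography"))
  homography(solve(h$matrix), pixel_scale = h$pixel_scale)
}

#' Metres-per-pixel scale of the top-down view
#'
#' The rectified view is constructed so a reference rectangle of known
#' physical size spans a known number of pixels; the scale W is their ratio
#' and converts pixel displacement in the top-down view to metres.
#'
#' @param physical_extent physical length of the reference edge, metres.
#' @param topdown_extent the same edge's length in the top-down raster, pixels.
#' @return Scale in metres per pixel.
#' @examples
#' compute_pixel_scale(2, 200)  # 0.01 m/px
#' @export
compute_pixel_scale <- function(physical_extent, topdown_extent) {
  if (!is.numeric(physical_extent) || length(physical_extent) != 1L ||
      !is.finite(physical_extent) || physical_extent <= 0) {
    stop("`physical_extent` must be a single positive number (m)",
         call. = FALSE)
  }
  if (!is.numeric(topdown_extent) || length(topdown_extent) != 1L ||
      !is.finite(topdown_extent) || topdown_extent <= 0) {
    stop("`topdown_extent` must be a single positive number (px)",
         call. = FALSE)
  }
  physical_extent / topdown_extent
}

#' Read and write calibration files
#'
#' A calibration file records the four pixel corners of the reference
#' rectangle as seen by the camera, the rectangle's physical width and height
#' in metres, and optionally the top-down raster width in pixels (default
#' 1000). [read_calibration()] fits the homography from the camera quad to
#' the top-down rectangle; the top-down raster is sized so the rectangle
#' fills it, giving pixel scale W = width_m / topdown_width_px.
#'
#' Corners must be listed in cyclic order starting at the world origin:
#' (0, 0), (width, 0), (width, height), (0, height).
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @param cal for [write_calibration()], a list with elements `src_points`
#'   (4x2), `rect_width_m`, `rect_height_m` and optionally `topdown_width_px`.
#' @return [read_calibration()] returns a list with the raw fields plus
#'   `homography`, the fitted `"homography"` with its pixel scale set.
#' @export
read_calibration <- function(path) {
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("src_points", "rect_width_m", "rect_height_m")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("calibration file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  src <- .as_points4(do.call(rbind, lapply(seq_len(4L), function(i) {
    p <- if (is.matrix(raw$src_points)) raw$src_points[i, ] else
      unlist(raw$src_points[[i]])
    as.numeric(p)
  })), "src_points")
  wm <- as.numeric(raw$rect_width_m)
  hm <- as.numeric(raw$rect_height_m)
  wpx <- if (is.null(raw$topdown_width_px)) 1000 else
    as.numeric(raw$topdown_width_px)
  scale <- compute_pixel_scale(wm, wpx)
  hpx <- hm / scale
  dst <- rbind(c(0, 0), c(wpx, 0), c(wpx, hpx), c(0, hpx))
  h <- fit_homography(src, dst, pixel_scale = scale)
  list(src_points = src, rect_width_m = wm, rect_height_m = hm,
       topdown_width_px = wpx, homography = h)
}

#' @rdname read_calibration
#' @export
write_calibration <- function(cal, path) {
  out <- list(
    src_points = lapply(seq_len(nrow(cal$src_points)), function(i) {
      as.numeric(cal$src_points[i, ])
    }),
    rect_width_m = cal$rect_width_m,
    rect_height_m = cal$rect_height_m,
    topdown_width_px = if (is.null(cal$topdown_width_px)) 1000 else
      cal$topdown_width_px
  )
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
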
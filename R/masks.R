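#' Run-length encoded segmentation masks
#'
#' Per-frame instance masks are stored run-length encoded: a row-major scan
#' of the frame (left to right, top to bottom) with alternating
#' background/foreground run lengths, starting with background. Label PNG
#' images (pixel value = track id, 0 = background) are supported as an
#' interchange format; RLE is the canonical in-memory form.
#'
#' @name masks
NULL

#' Construct an RLE mask
#'
#' @param frame 0-based frame index.
#' @param track_id positive integer identity.
#' @param size integer (height, width) of the frame, px.
#' @param counts integer run lengths, row-major, alternating background and
#'   foreground starting with background; must sum to `prod(size)`.
#' @return An object of class `"mask_rle"`.
#' @export
mask_rle <- function(frame, track_id, size, counts) {
  size <- as.integer(size)
  counts <- as.integer(counts)
  if (length(size) != 2L || any(size <= 0L)) {
    stop("`size` must be positive (height, width)", call. = FALSE)
  }
  if (any(counts < 0L)) stop("run lengths must be >= 0", call. = FALSE)
  if (sum(counts) != prod(size)) {
    stop("run lengths sum to ", sum(counts), ", expected ", prod(size),
         call. = FALSE)
  }
  structure(list(frame = as.integer(frame), track_id = as.integer(track_id),
                 size = size, counts = counts),
            class = "mask_rle")
}

#' Decode an RLE mask to a binary raster
#'
#' @param m a `"mask_rle"`.
#' @return Logical matrix of dimension `size` (height rows, width columns);
#'   `TRUE` is foreground.
#' @export
decode_rle <- function(m) {
  stopifnot(inherits(m, "mask_rle"))
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(m$counts)), m$counts)
  matrix(vals, nrow = m$size[1L], ncol = m$size[2L], byrow = TRUE)
}

#' Encode a binary raster as a canonical RLE mask
#'
#' The encoding is canonical: no zero-length runs except a possible leading
#' zero when the raster starts with foreground, so
#' `encode_rle(decode_rle(m))` reproduces `m` exactly for canonical `m`.
#'
#' @param raster logical matrix (height rows, width columns).
#' @param frame,track_id metadata carried on the result.
#' @return A `"mask_rle"`.
#' @export
encode_rle <- function(raster, frame = 0L, track_id = 1L) {
  if (!is.matrix(raster)) stop("`raster` must be a matrix", call. = FALSE)
  scan <- as.logical(t(raster))  # row-major order
  r <- rle(scan)
  counts <- r$lengths
  if (length(counts) && r$values[1L]) counts <- c(0L, counts)
  if (!length(counts)) counts <- integer()
  mask_rle(frame, track_id, dim(raster), counts)
}

#' Centroid of a mask
#'
#' Arithmetic mean of the foreground pixel coordinates, in the 0-based pixel
#' convention (u rightward, v downward, origin at the top-left pixel).
#'
#' @param m a `"mask_rle"`.
#' @return Numeric `(u, v)` centroid in pixels.
#' @export
mask_centroid <- function(m) {
  raster <- decode_rle(m)
  idx <- which(raster, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixels", call. = FALSE)
  c(u = mean(idx[, 2L]) - 1, v = mean(idx[, 1L]) - 1)
}

#' Area (foreground pixel count) of a mask
#' @param m a `"mask_rle"`.
#' @export
mask_area <- function(m) {
  stopifnot(inherits(m, "mask_rle"))
  idx <- seq_along(m$counts)
  sum(m$counts[idx %% 2L == 0L])
}

#' Read and write RLE masks as JSON
#'
#' One JSON object per mask: `{frame, id, size: [h, w], counts: [...]}` with
#' 0-based frames; a file holds an array of such objects.
#'
#' @param path JSON file path.
#' @param masks list of `"mask_rle"` objects.
#' @return [read_masks_json()] returns a list of `"mask_rle"`.
#' @export
read_masks_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(o) {
    mask_rle(o$frame, o$id, unlist(o$size), unlist(o$counts))
  })
}

#' @rdname read_masks_json
#' @export
write_masks_json <- function(masks, path) {
  out <- lapply(masks, function(m) {
    list(frame = m$frame, id = m$track_id, size = as.integer(m$size),
         counts = as.integer(m$counts))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write label-image PNG masks
#'
#' A label image stores the track id as the 8-bit grayscale pixel value
#' (0 = background), limiting ids to 1..255. [read_mask_png()] splits the
#' label image into one RLE mask per id present.
#'
#' @param path PNG file path.
#' @param masks list of `"mask_rle"` for one frame (ids must be distinct and
#'   <= 255; overlaps resolved in favour of the higher id).
#' @param frame 0-based frame index attached to masks read from `path`.
#' @return [read_mask_png()] returns a list of `"mask_rle"`.
#' @export
read_mask_png <- function(path, frame = 0L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labels <- round(img * 255)
  ids <- sort(unique(as.integer(labels[labels > 0])))
  lapply(ids, function(id) encode_rle(labels == id, frame = frame,
                                      track_id = id))
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(masks, path) {
  stopifnot(length(masks) >= 1L)
  size <- masks[[1L]]$size
  labels <- matrix(0L, size[1L], size[2L])
  for (m in masks) {
    if (!identical(m$size, size)) stop("masks differ in frame size",
                                       call. = FALSE)
    if (m$track_id > 255L) stop("label PNG supports ids up to 255",
                                call. = FALSE)
    labels[decode_rle(m)] <- m$track_id
  }
  png::writePNG(labels / 255, path)
  invisible(path)
}
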
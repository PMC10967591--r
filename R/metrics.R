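#' Multi-object tracking and segmentation evaluation
#'
#' Implements the CLEAR-MOT protocol (per-frame gated minimum-cost matching
#' with correspondence persistence, tallying true positives, false
#' positives, misses and identity switches), the identity-level metrics
#' IDP/IDR/IDF1 under an optimal global mapping between ground-truth and
#' predicted identities, mean intersection-over-union for segmentation, and
#' RMSE for speed prediction.
#'
#' @name metrics
NULL

# Gated minimum-cost bipartite assignment. Returns an integer vector of
# column indices per row (NA = unassigned); pairs whose cost exceeds the
# gate are rejected after solving.
.gated_assignment <- function(cost, gate) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  # large enough that one extra in-gate match always beats any redistribution
  big <- gate * (max(nr, nc) + 1) + 1
  m <- pmin(cost, big)
  n <- max(nr, nc)
  sq <- matrix(big, n, n)
  sq[seq_len(nr), seq_len(nc)] <- m
  sol <- as.integer(clue::solve_LSAP(sq))
  out <- sol[seq_len(nr)]
  out[out > nc] <- NA_integer_
  keep <- !is.na(out) & cost[cbind(seq_along(out), out)] <= gate
  out[!keep] <- NA_integer_
  out
}

.frame_split <- function(ts) split(ts$detections, ts$detections$frame)

#' CLEAR-MOT matching of predicted against ground-truth tracks
#'
#' Per frame, ground-truth and predicted detections are paired by
#' minimum-cost bipartite assignment on centroid Euclidean distance, gated
#' at `threshold` pixels. Following the CLEAR-MOT protocol, an existing
#' ground-truth/prediction pairing is kept while it remains within the gate
#' (the memory survives frames where either party is absent), and only the
#' remaining detections enter the assignment; among assignments the number
#' of in-gate matches is maximized first, then total distance minimized.
#' Unmatched ground truth counts as a miss, unmatched
#' predictions as false positives, and a matched ground-truth object whose
#' paired predicted identity differs from its previous pairing (ignoring
#' gaps) is charged one identity switch at that frame.
#'
#' @param gt,pred ground-truth and predicted `"track_set"`s sharing frame
#'   rate and frame range.
#' @param threshold matching gate in pixels; defaults to 0.1 x frame height
#'   when the ground truth carries a frame size.
#' @return List of class `"mot_match"` with `counts` (a `"mot_counts"`:
#'   `true_positives`, `false_positives`, `misses`, `identity_switches`,
#'   `total_gt`) and `assignment`, a data frame of matched pairs per frame
#'   (`frame`, `gt_id`, `pred_id`, `distance`).
#' @export
match_tracks <- function(gt, pred, threshold = NULL) {
  stopifnot(inherits(gt, "track_set"), inherits(pred, "track_set"))
  if (!isTRUE(all.equal(gt$fps, pred$fps))) {
    stop("ground truth and prediction disagree on fps", call. = FALSE)
  }
  if (is.null(threshold)) {
    if (is.null(gt$frame_size)) {
      stop("no `threshold` given and ground truth has no frame size",
           call. = FALSE)
    }
    threshold <- 0.1 * gt$frame_size[2L]
  }
  gt_f <- .frame_split(gt)
  pr_f <- .frame_split(pred)
  frames <- sort(unique(c(gt$detections$frame, pred$detections$frame)))

  tp <- fp <- miss <- ids <- 0L
  # last paired pred id per gt id; persists across frames with gaps, serving
  # both correspondence persistence and switch counting
  last_match <- integer()
  assign_rows <- vector("list", length(frames))

  for (k in seq_along(frames)) {
    f <- frames[k]
    g <- gt_f[[as.character(f)]]
    p <- pr_f[[as.character(f)]]
    ng <- if (is.null(g)) 0L else nrow(g)
    np <- if (is.null(p)) 0L else nrow(p)
    pairs_g <- integer(0); pairs_p <- integer(0); pairs_d <- numeric(0)

    if (ng > 0L && np > 0L) {
      d <- sqrt(outer(g$cx, p$cx, "-")^2 + outer(g$cy, p$cy, "-")^2)
      taken_g <- rep(FALSE, ng); taken_p <- rep(FALSE, np)
      # persistence: keep remembered pairings still within the gate,
      # visiting ground truth in ascending id order
      if (length(last_match)) {
        for (gi in seq_len(ng)) {
          pid <- last_match[as.character(g$track_id[gi])]
          if (is.na(pid)) next
          pj <- match(pid, p$track_id)
          if (!is.na(pj) && !taken_p[pj] && d[gi, pj] <= threshold) {
            taken_g[gi] <- TRUE; taken_p[pj] <- TRUE
            pairs_g <- c(pairs_g, gi); pairs_p <- c(pairs_p, pj)
            pairs_d <- c(pairs_d, d[gi, pj])
          }
        }
      }
      free_g <- which(!taken_g); free_p <- which(!taken_p)
      if (length(free_g) && length(free_p)) {
        sol <- .gated_assignment(d[free_g, free_p, drop = FALSE], threshold)
        hit <- which(!is.na(sol))
        pairs_g <- c(pairs_g, free_g[hit])
        pairs_p <- c(pairs_p, free_p[sol[hit]])
        pairs_d <- c(pairs_d, d[cbind(free_g[hit], free_p[sol[hit]])])
      }
    }

    n_match <- length(pairs_g)
    tp <- tp + n_match
    fp <- fp + np - n_match
    miss <- miss + ng - n_match

    if (n_match) {
      gids <- g$track_id[pairs_g]; pids <- p$track_id[pairs_p]
      prior <- last_match[as.character(gids)]
      ids <- ids + sum(!is.na(prior) & prior != pids)
      last_match[as.character(gids)] <- pids
      assign_rows[[k]] <- data.frame(frame = f, gt_id = gids,
                                     pred_id = pids, distance = pairs_d)
    }
  }

  counts <- structure(
    list(true_positives = tp, false_positives = fp, misses = miss,
         identity_switches = ids, total_gt = nrow(gt$detections)),
    class = "mot_counts")
  assignment <- do.call(rbind, assign_rows)
  if (is.null(assignment)) {
    assignment <- data.frame(frame = integer(), gt_id = integer(),
                             pred_id = integer(), distance = numeric())
  }
  structure(list(counts = counts, assignment = assignment,
                 threshold = threshold),
            class = "mot_match")
}

#' @export
print.mot_counts <- function(x, ...) {
  cat(sprintf("MOT counts: TP %d, FP %d, miss %d, IDS %d (GT total %d)\n",
              x$true_positives, x$false_positives, x$misses,
              x$identity_switches, x$total_gt))
  invisible(x)
}

#' Multiple-object tracking accuracy
#'
#' MOTA = 1 - (FP + misses + identity switches) / total ground-truth
#' detections. Bounded above by 1; can be negative when errors outnumber
#' ground-truth objects.
#'
#' @param counts a `"mot_counts"` (from [match_tracks()]) or a list with the
#'   same fields.
#' @return MOTA, unitless.
#' @export
mota <- function(counts) {
  if (is.null(counts$total_gt) || counts$total_gt <= 0) {
    stop("MOTA is undefined with zero ground-truth objects", call. = FALSE)
  }
  1 - (counts$false_positives + counts$misses + counts$identity_switches) /
    counts$total_gt
}

#' Harmonic mean of identification precision and recall
#'
#' @param idp,idr identification precision and recall, each in `[0, 1]`.
#' @return IDF1 = 2 IDP IDR / (IDP + IDR); 0 when both are 0.
#' @export
idf1 <- function(idp, idr) {
  ifelse(idp + idr == 0, 0, 2 * idp * idr / (idp + idr))
}

#' Identity-level precision, recall and F1
#'
#' Ground-truth and predicted identities are mapped one-to-one by a
#' minimum-cost bipartite assignment over whole trajectories that maximizes
#' the number of frames in which a mapped pair is within `threshold` pixels.
#' Under that mapping, IDTP is the total number of in-gate frames of mapped
#' pairs, and IDP = IDTP / total predicted detections, IDR = IDTP / total
#' ground-truth detections, IDF1 the harmonic mean of the two.
#'
#' @inheritParams match_tracks
#' @return List with `idp`, `idr`, `idf1`, `idtp`.
#' @export
identification_metrics <- function(gt, pred, threshold = NULL) {
  stopifnot(inherits(gt, "track_set"), inherits(pred, "track_set"))
  if (is.null(threshold)) {
    if (is.null(gt$frame_size)) {
      stop("no `threshold` given and ground truth has no frame size",
           call. = FALSE)
    }
    threshold <- 0.1 * gt$frame_size[2L]
  }
  n_gt <- nrow(gt$detections); n_pr <- nrow(pred$detections)
  if (n_gt == 0L && n_pr == 0L) {
    warning("both track sets are empty; identity metrics defined as 1")
    return(list(idp = 1, idr = 1, idf1 = 1, idtp = 0L))
  }
  gids <- sort(unique(gt$detections$track_id))
  pids <- sort(unique(pred$detections$track_id))
  overlap <- matrix(0L, length(gids), length(pids),
                    dimnames = list(gids, pids))
  if (length(gids) && length(pids)) {
    merged <- merge(gt$detections[c("frame", "track_id", "cx", "cy")],
                    pred$detections[c("frame", "track_id", "cx", "cy")],
                    by = "frame", suffixes = c("_g", "_p"))
    if (nrow(merged)) {
      ok <- (merged$cx_g - merged$cx_p)^2 + (merged$cy_g - merged$cy_p)^2 <=
        threshold^2
      hits <- merged[ok, c("track_id_g", "track_id_p")]
      if (nrow(hits)) {
        tab <- table(factor(hits$track_id_g, levels = gids),
                     factor(hits$track_id_p, levels = pids))
        overlap <- overlap + unclass(tab)
      }
    }
    # maximize total overlap == minimize (max - overlap) on a padded square
    n <- max(dim(overlap))
    cost <- matrix(max(overlap), n, n)
    cost[seq_along(gids), seq_along(pids)] <- max(overlap) - overlap
    sol <- as.integer(clue::solve_LSAP(cost))
    sel <- cbind(seq_along(gids), sol[seq_along(gids)])
    sel <- sel[sel[, 2L] <= length(pids), , drop = FALSE]
    idtp <- sum(overlap[sel])
  } else {
    idtp <- 0L
  }
  idp <- if (n_pr > 0L) idtp / n_pr else 0
  idr <- if (n_gt > 0L) idtp / n_gt else 0
  list(idp = idp, idr = idr, idf1 = idf1(idp, idr), idtp = as.integer(idtp))
}

#' Processing throughput in frames per second
#'
#' @param total_frames number of frames processed.
#' @param total_time_s elapsed wall time, seconds; must be positive.
#' @return Frames per second.
#' @export
fps_throughput <- function(total_frames, total_time_s) {
  if (!is.numeric(total_time_s) || total_time_s <= 0) {
    stop("`total_time_s` must be positive", call. = FALSE)
  }
  total_frames / total_time_s
}

#' Intersection over union
#'
#' For two RLE masks of the same frame size, the ratio of foreground
#' intersection to union areas; for two bounding boxes `(left, top, width,
#' height)`, the rectangle overlap ratio. Two empty masks give 0 with a
#' warning (the overlap of nothing with nothing carries no evidence of
#' agreement).
#'
#' @param a,b two `"mask_rle"` masks or two numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (inherits(a, "mask_rle") && inherits(b, "mask_rle")) {
    if (!identical(a$size, b$size)) {
      stop("masks differ in frame size", call. = FALSE)
    }
    ra <- decode_rle(a); rb <- decode_rle(b)
    un <- sum(ra | rb)
    if (un == 0L) {
      warning("both masks empty; IoU defined as 0")
      return(0)
    }
    return(sum(ra & rb) / un)
  }
  if (is.numeric(a) && is.numeric(b) && length(a) == 4L && length(b) == 4L) {
    ix <- max(0, min(a[1L] + a[3L], b[1L] + b[3L]) - max(a[1L], b[1L]))
    iy <- max(0, min(a[2L] + a[4L], b[2L] + b[4L]) - max(a[2L], b[2L]))
    inter <- ix * iy
    un <- a[3L] * a[4L] + b[3L] * b[4L] - inter
    if (un <= 0) {
      warning("both boxes empty; IoU defined as 0")
      return(0)
    }
    return(inter / un)
  }
  stop("`a` and `b` must both be mask_rle objects or both length-4 boxes",
       call. = FALSE)
}

.class_union <- function(masks) {
  if (!length(masks)) return(NULL)
  r <- decode_rle(masks[[1L]])
  for (m in masks[-1L]) r <- r | decode_rle(m)
  r
}

#' Mean intersection over union across classes
#'
#' Each class's mask is the union of its instance masks; the per-class IoU
#' between prediction and ground truth is averaged without weighting.
#' Classes present in neither side are excluded from the mean with a
#' warning; a class present on one side only scores 0.
#'
#' @param pred,gt named lists, one element per class, each a list of
#'   `"mask_rle"` instance masks (possibly empty).
#' @return Mean IoU in `[0, 1]`.
#' @export
miou <- function(pred, gt) {
  classes <- union(names(pred), names(gt))
  if (!length(classes)) stop("no classes given", call. = FALSE)
  vals <- numeric(0)
  for (cl in classes) {
    rp <- .class_union(pred[[cl]])
    rg <- .class_union(gt[[cl]])
    if (is.null(rp) && is.null(rg)) {
      warning("class `", cl, "` present in neither prediction nor ground ",
              "truth; excluded from mIoU")
      next
    }
    if (is.null(rp)) rp <- matrix(FALSE, nrow(rg), ncol(rg))
    if (is.null(rg)) rg <- matrix(FALSE, nrow(rp), ncol(rp))
    un <- sum(rp | rg)
    vals <- c(vals, if (un == 0L) 0 else sum(rp & rg) / un)
  }
  if (!length(vals)) stop("no class present on either side", call. = FALSE)
  mean(vals)
}

#' Root-mean-square error between actual and predicted speeds
#'
#' @param actual,predicted paired numeric vectors of equal nonzero length,
#'   in m/s (pair by track and window before calling).
#' @return RMSE in m/s.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal nonzero length",
         call. = FALSE)
  }
  sqrt(mean((actual - predicted)^2))
}

#' Full evaluation report for a prediction against ground truth
#'
#' Convenience wrapper running [match_tracks()], [mota()] and
#' [identification_metrics()], with optional segmentation and speed-error
#' components.
#'
#' @inheritParams match_tracks
#' @param pred_masks,gt_masks optional per-class mask lists for [miou()].
#' @param actual_speeds,predicted_speeds optional paired speed vectors for
#'   [rmse()].
#' @param elapsed_s optional wall time for [fps_throughput()].
#' @return List of class `"metrics_report"` with `mota`, `idp`, `idr`,
#'   `idf1`, `ids`, `counts`, and when inputs allow, `miou`, `rmse_mps`,
#'   `fps_throughput`.
#' @export
evaluate_tracking <- function(gt, pred, threshold = NULL,
                              pred_masks = NULL, gt_masks = NULL,
                              actual_speeds = NULL, predicted_speeds = NULL,
                              elapsed_s = NULL) {
  m <- match_tracks(gt, pred, threshold = threshold)
  idm <- identification_metrics(gt, pred, threshold = m$threshold)
  rep <- list(mota = mota(m$counts), idp = idm$idp, idr = idm$idr,
              idf1 = idm$idf1, ids = m$counts$identity_switches,
              counts = m$counts)
  if (!is.null(pred_masks) && !is.null(gt_masks)) {
    rep$miou <- miou(pred_masks, gt_masks)
  }
  if (!is.null(actual_speeds)) {
    rep$rmse_mps <- rmse(actual_speeds, predicted_speeds)
  }
  if (!is.null(elapsed_s)) {
    n_frames <- length(unique(pred$detections$frame))
    rep$fps_throughput <- fps_throughput(n_frames, elapsed_s)
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MOTA  %.4f\nIDF1  %.4f  (IDP %.4f, IDR %.4f)\nIDS   %d\n",
              x$mota, x$idf1, x$idp, x$idr, x$ids))
  if (!is.null(x$miou)) cat(sprintf("mIoU  %.4f\n", x$miou))
  if (!is.null(x$rmse_mps)) cat(sprintf("RMSE  %.4f m/s\n", x$rmse_mps))
  if (!is.null(x$fps_throughput)) {
    cat(sprintf("FPS   %.2f\n", x$fps_throughput))
  }
  invisible(x)
}
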
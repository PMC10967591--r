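# Independent reference implementations used as oracles. These share no
# code with the package: assignments are solved by exhaustive bitmask
# dynamic programming instead of the Hungarian method, and the evaluation
# loops are written from the protocol definition.

# Optimal gated assignment by DP over subsets of columns. Maximizes the
# number of in-gate matches, then minimizes their total distance. Returns
# integer column per row (NA = unmatched). Exact for ncol <= ~15.
oracle_assign <- function(cost, gate) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L) return(integer(0))
  if (nc == 0L) return(rep(NA_integer_, nr))
  stopifnot(nc <= 15L)
  unit <- nr * gate + 1  # one match outweighs any total distance
  n_mask <- bitwShiftL(1L, nc)
  best <- matrix(-Inf, nr + 1L, n_mask)   # score = count*unit - dist
  best[1L, 1L] <- 0
  choice <- array(NA_integer_, c(nr + 1L, n_mask))
  from <- array(NA_integer_, c(nr + 1L, n_mask))
  for (i in seq_len(nr)) {
    for (mask in 0:(n_mask - 1L)) {
      s <- best[i, mask + 1L]
      if (!is.finite(s)) next
      # leave row i unmatched
      if (s > best[i + 1L, mask + 1L]) {
        best[i + 1L, mask + 1L] <- s
        choice[i + 1L, mask + 1L] <- 0L
        from[i + 1L, mask + 1L] <- mask
      }
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) > 0L || cost[i, j] > gate) next
        s2 <- s + unit - cost[i, j]
        m2 <- bitwOr(mask, bit)
        if (s2 > best[i + 1L, m2 + 1L]) {
          best[i + 1L, m2 + 1L] <- s2
          choice[i + 1L, m2 + 1L] <- j
          from[i + 1L, m2 + 1L] <- mask
        }
      }
    }
  }
  end_mask <- which.max(best[nr + 1L, ]) - 1L
  out <- rep(NA_integer_, nr)
  mask <- end_mask
  for (i in rev(seq_len(nr))) {
    j <- choice[i + 1L, mask + 1L]
    if (!is.na(j) && j > 0L) out[i] <- j
    mask <- from[i + 1L, mask + 1L]
  }
  out
}

# Reference CLEAR-MOT evaluation: per-frame gated optimal matching with
# persistent correspondence memory and switch counting.
oracle_clearmot <- function(gt, pred, threshold) {
  gd <- gt$detections; pd <- pred$detections
  frames <- sort(unique(c(gd$frame, pd$frame)))
  memory <- list()  # gt id (chr) -> last matched pred id
  tp <- fp <- miss <- ids <- 0L
  for (f in frames) {
    g <- gd[gd$frame == f, ]
    p <- pd[pd$frame == f, ]
    g <- g[order(g$track_id), ]; p <- p[order(p$track_id), ]
    matched_g <- integer(0); matched_p <- integer(0)
    if (nrow(g) && nrow(p)) {
      dmat <- sqrt(outer(g$cx, p$cx, "-")^2 + outer(g$cy, p$cy, "-")^2)
      used_p <- rep(FALSE, nrow(p))
      for (gi in seq_len(nrow(g))) {
        prev <- memory[[as.character(g$track_id[gi])]]
        if (is.null(prev)) next
        pj <- match(prev, p$track_id)
        if (!is.na(pj) && !used_p[pj] && dmat[gi, pj] <= threshold) {
          matched_g <- c(matched_g, gi); matched_p <- c(matched_p, pj)
          used_p[pj] <- TRUE
        }
      }
      free_g <- setdiff(seq_len(nrow(g)), matched_g)
      free_p <- which(!used_p)
      if (length(free_g) && length(free_p)) {
        sol <- oracle_assign(dmat[free_g, free_p, drop = FALSE], threshold)
        hit <- which(!is.na(sol))
        matched_g <- c(matched_g, free_g[hit])
        matched_p <- c(matched_p, free_p[sol[hit]])
      }
    }
    tp <- tp + length(matched_g)
    fp <- fp + nrow(p) - length(matched_g)
    miss <- miss + nrow(g) - length(matched_g)
    if (length(matched_g)) {
      for (k in seq_along(matched_g)) {
        gid <- as.character(g$track_id[matched_g[k]])
        pid <- p$track_id[matched_p[k]]
        if (!is.null(memory[[gid]]) && memory[[gid]] != pid) {
          ids <- ids + 1L
        }
        memory[[gid]] <- pid
      }
    }
  }
  list(tp = tp, fp = fp, miss = miss, ids = ids, total_gt = nrow(gd),
       mota = 1 - (fp + miss + ids) / nrow(gd))
}

# Reference identity metrics: overlap counting by explicit frame loop, the
# optimal identity mapping found by the same subset DP (gate = Inf on
# negated overlaps is equivalent to maximizing total overlap).
oracle_idmetrics <- function(gt, pred, threshold) {
  gd <- gt$detections; pd <- pred$detections
  gids <- sort(unique(gd$track_id)); pids <- sort(unique(pd$track_id))
  ov <- matrix(0L, length(gids), length(pids))
  for (f in sort(unique(c(gd$frame, pd$frame)))) {
    g <- gd[gd$frame == f, ]; p <- pd[pd$frame == f, ]
    if (!nrow(g) || !nrow(p)) next
    for (gi in seq_len(nrow(g))) for (pj in seq_len(nrow(p))) {
      if (sqrt((g$cx[gi] - p$cx[pj])^2 + (g$cy[gi] - p$cy[pj])^2) <=
            threshold) {
        a <- match(g$track_id[gi], gids); b <- match(p$track_id[pj], pids)
        ov[a, b] <- ov[a, b] + 1L
      }
    }
  }
  # columns with no overlap cannot contribute; drop them so the DP stays small
  keep <- which(colSums(ov) > 0L)
  idtp <- if (length(keep) && nrow(ov)) {
    ovk <- ov[, keep, drop = FALSE]
    big <- max(ovk) + 1
    sol <- oracle_assign(big - ovk, gate = big)  # maximizes total overlap
    hit <- which(!is.na(sol))
    sum(ovk[cbind(hit, sol[hit])])
  } else 0L
  idp <- if (nrow(pd)) idtp / nrow(pd) else 0
  idr <- if (nrow(gd)) idtp / nrow(gd) else 0
  list(idp = idp, idr = idr,
       idf1 = if (idp + idr == 0) 0 else 2 * idp * idr / (idp + idr),
       idtp = idtp)
}
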
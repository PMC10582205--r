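# Independent brute-force oracles used to freeze expected values.

# Laplacian variance by direct double-loop convolution with mirror padding
# (reflection across the edge, edge pixel not duplicated), population variance.
oracleLapVar <- function(g) {
  H <- nrow(g); W <- ncol(g)
  refl <- function(i, n) if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  resp <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    resp[y, x] <- g[refl(y - 1, H), x] + g[refl(y + 1, H), x] +
      g[y, refl(x - 1, W)] + g[y, refl(x + 1, W)] - 4 * g[y, x]
  }
  mean((resp - mean(resp))^2)
}

# IoU by pixel rasterization on the integer grid: pixel (i,j) (0-based) lies
# in a box iff x_min <= i < x_max and y_min <= j < y_max.
oracleIoU <- function(a, b) {
  lim <- ceiling(max(a, b)) + 1
  inBox <- function(box) {
    m <- matrix(FALSE, lim, lim)
    xs <- seq_len(lim) - 1
    m[xs >= box[1] & xs < box[3], ] <- TRUE
    m[, !(xs >= box[2] & xs < box[4])] <- FALSE
    m
  }
  A <- inBox(a); B <- inBox(b)
  u <- sum(A | B)
  if (u == 0) 0 else sum(A & B) / u
}

# All-point-interpolated AP by a per-true-positive scan: each TP at pooled
# confidence rank k contributes 1/n_gt times the maximum precision attained
# at any prefix whose recall reaches that TP's recall.
oracleAP <- function(tp_flags, confidences, n_gt) {
  ord <- order(-confidences)
  tp <- tp_flags[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  ap <- 0
  for (k in seq_along(tp)) {
    if (!tp[k]) next
    r_k <- rec[k]
    best <- 0
    for (j in seq_along(tp)) if (rec[j] >= r_k) best <- max(best, prec[j])
    ap <- ap + best / n_gt
  }
  ap
}

# detection-count state machine, written as the naive frame-by-frame
# re-scan (no shared code with segmentStream)
oracleSegments <- function(counts, gap, min_len) {
  runs <- rle(counts > 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # merge detection runs separated by short (< gap) empty runs
  segs <- list()
  cur <- NULL
  for (i in seq_along(runs$values)) {
    if (runs$values[i]) {
      if (is.null(cur)) cur <- c(starts[i], ends[i]) else cur[2] <- ends[i]
    } else if (!is.null(cur) && runs$lengths[i] >= gap) {
      segs[[length(segs) + 1]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1]] <- cur
  segs <- Filter(function(s) s[2] - s[1] + 1 >= min_len, segs)
  # report 0-based frame indices
  lapply(segs, function(s) s - 1)
}
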
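#' Greedy IoU matching of detections against ground truth
#'
#' Within each frame, detections are processed in descending confidence; a
#' detection is a true positive if its best-IoU not-yet-consumed ground-truth
#' box reaches \code{iou_thr} (that box is then consumed), otherwise a false
#' positive. Ground-truth boxes left unconsumed are false negatives.
#'
#' @param preds a \linkS4class{DetectionSet} of predictions.
#' @param gts a \linkS4class{DetectionSet} of ground-truth boxes
#'   (confidence ignored).
#' @param iou_thr IoU threshold in (0, 1).
#' @return list with \code{matches} (data.frame: \code{frame_index},
#'   \code{confidence}, \code{tp}), \code{n_gt}, \code{fn}
#' @export
matchDetections <- function(preds, gts, iou_thr = 0.5) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  pd <- detections(preds)
  gd <- detections(gts)
  frames <- union(unique(pd$frame_index), unique(gd$frame_index))
  rows <- list()
  fn <- 0L
  for (fi in frames) {
    p <- pd[pd$frame_index == fi, , drop = FALSE]
    g <- gd[gd$frame_index == fi, , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    if (nrow(p)) {
      p <- p[order(-p$confidence), , drop = FALSE]
      tp <- logical(nrow(p))
      for (i in seq_len(nrow(p))) {
        best <- 0; bj <- 0L
        for (j in seq_len(nrow(g))) {
          if (used[j]) next
          v <- boxIoU(p[i, ], g[j, ])
          if (v > best) { best <- v; bj <- j }
        }
        if (bj > 0L && best >= iou_thr) { tp[i] <- TRUE; used[bj] <- TRUE }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(frame_index = fi, confidence = p$confidence, tp = tp)
    }
    fn <- fn + sum(!used)
  }
  matches <- do.call(rbind, rows) %||%
    data.frame(frame_index = integer(0), confidence = numeric(0), tp = logical(0))
  list(matches = matches, n_gt = nrow(gd), fn = fn)
}

#' Average precision at one IoU threshold
#'
#' All detections are pooled across frames and sorted by descending
#' confidence; cumulative TP/FP counts trace a precision--recall curve
#' (recall denominator = total ground-truth boxes). AP is the area under the
#' precision envelope with all-point interpolation: the sum over recall
#' increments of the maximum precision attained at or beyond that recall.
#'
#' @inheritParams matchDetections
#' @return AP in [0, 1]
#' @export
averagePrecision <- function(preds, gts, iou_thr = 0.5) {
  m <- matchDetections(preds, gts, iou_thr)
  if (m$n_gt == 0L)
    stopf("average precision is undefined with zero ground-truth boxes")
  mt <- m$matches
  if (!nrow(mt)) return(0)
  mt <- mt[order(-mt$confidence), , drop = FALSE]
  tp <- cumsum(mt$tp)
  fp <- cumsum(!mt$tp)
  recall <- tp / m$n_gt
  precision <- tp / (tp + fp)
  env <- rev(cummax(rev(precision)))
  dr <- diff(c(0, recall))
  sum(dr * env)
}

#' Detection evaluation report: precision, recall, AP, mAP@0.5, mAP@0.5:0.95
#'
#' Computes AP at the ten IoU thresholds 0.50, 0.55, ..., 0.95;
#' \code{map50} is the AP at 0.50 and \code{map5095} their mean (the single
#' "embryo" class makes mAP equal AP). Precision and recall are reported at
#' IoU 0.5 with no confidence cutoff.
#'
#' @inheritParams matchDetections
#' @return an EvalReport: list with \code{precision}, \code{recall},
#'   \code{ap_by_threshold} (named numeric), \code{map50}, \code{map5095}
#' @export
evaluateDetections <- function(preds, gts) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap <- vapply(thresholds, function(t) averagePrecision(preds, gts, t), numeric(1))
  names(ap) <- sprintf("%.2f", thresholds)
  m <- matchDetections(preds, gts, 0.5)
  tp <- sum(m$matches$tp)
  fp <- sum(!m$matches$tp)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (m$n_gt > 0) tp / m$n_gt else NA_real_,
       ap_by_threshold = ap,
       map50 = ap[["0.50"]],
       map5095 = mean(ap))
}

#' Serialize an evaluation report to JSON
#'
#' @param report a report from \code{\link{evaluateDetections}}.
#' @param path output file; when NULL the JSON string is returned.
#' @return path (invisibly) or JSON string
#' @export
writeEvalReport <- function(report, path = NULL) {
  rep <- report
  rep$ap_by_threshold <- as.list(report$ap_by_threshold)
  if (is.null(path))
    return(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
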
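#' Partition a detection stream into growth-medium segments
#'
#' State machine over per-frame detection counts. A segment opens at the
#' first frame with at least one detection while none is open; its stop frame
#' advances on every subsequent detected frame; it closes once
#' \code{gap_frames} consecutive zero-detection frames have elapsed (or the
#' stream ends). Closed segments shorter than \code{min_len_frames} frames
#' are discarded and do not consume a drop index; survivors are numbered
#' 1..n in temporal order.
#'
#' @param detset a \linkS4class{DetectionSet} (or an integer vector of
#'   per-frame detection counts, taken to start at frame 0).
#' @param gap_frames consecutive empty frames that close a segment
#'   (default 5, i.e. 1 s at 5 fps — shorter than a typical between-drop
#'   transition).
#' @param min_len_frames minimum surviving segment length in frames
#'   (default 5); shorter runs are treated as spurious detections.
#' @return data.frame with columns \code{drop_index}, \code{first_frame},
#'   \code{last_frame} (0 rows when no detections)
#' @export
segmentStream <- function(detset, gap_frames = 5L, min_len_frames = 5L) {
  stopifnot(gap_frames >= 1, min_len_frames >= 1)
  if (is(detset, "DetectionSet")) {
    counts <- detectionCounts(detset)
    idx <- frameIndices(detset)
  } else {
    counts <- as.integer(detset)
    idx <- seq_along(counts) - 1L
  }
  segs <- list()
  open <- FALSE; first <- NA_integer_; last <- NA_integer_; gap <- 0L
  closeSeg <- function() {
    if (open && (last - first + 1L) >= min_len_frames)
      segs[[length(segs) + 1L]] <<- c(first, last)
    open <<- FALSE; gap <<- 0L
  }
  for (k in seq_along(counts)) {
    if (counts[k] > 0L) {
      if (!open) {
        open <- TRUE
        first <- idx[k]
      }
      last <- idx[k]
      gap <- 0L
    } else if (open) {
      gap <- gap + 1L
      if (gap >= gap_frames) closeSeg()
    }
  }
  closeSeg()
  if (!length(segs))
    return(data.frame(drop_index = integer(0), first_frame = integer(0),
                      last_frame = integer(0)))
  m <- do.call(rbind, segs)
  data.frame(drop_index = seq_len(nrow(m)), first_frame = m[, 1], last_frame = m[, 2])
}

#' Duration of a segment in seconds
#'
#' @param first_frame,last_frame frame indices in the downsampled stream.
#' @param fps stream rate (default 5).
#' @return \code{(last_frame - first_frame) / fps} seconds
#' @export
segmentDuration <- function(first_frame, last_frame, fps = 5) {
  (last_frame - first_frame) / fps
}

# fresh left/right running-mean state for a new segment
newSideState <- function() {
  list(left_sum = 0, left_n = 0L, right_sum = 0, right_n = 0L)
}

#' Assign frame detections to the left/right embryo slots
#'
#' With two or more detections, the top two by confidence are kept and
#' ordered by bounding-box x-center: smaller x-center is Embryo_01 (left),
#' the other Embryo_02 (right); x ties break to the smaller y-center. With a
#' single detection, it is assigned to the side whose running mean x-center
#' (over the current segment) is nearer, defaulting to left when no history
#' exists. The state is updated with the frame's assignments.
#'
#' @param dets data.frame of the frame's detections (\code{x_min},
#'   \code{y_min}, \code{x_max}, \code{y_max}, \code{confidence}); at least
#'   one row.
#' @param state side-history state (running sums); from a previous call or
#'   \code{NULL} for a fresh segment.
#' @return list with \code{assign} (data.frame: the kept detections plus an
#'   \code{embryo_index} column, 1 = left, 2 = right) and the updated
#'   \code{state}
#' @export
assignSides <- function(dets, state = NULL) {
  if (is.null(state)) state <- newSideState()
  if (!nrow(dets)) stopf("assignSides called with no detections")
  dets$cx <- (dets$x_min + dets$x_max) / 2
  dets$cy <- (dets$y_min + dets$y_max) / 2
  if (nrow(dets) >= 2L) {
    top <- dets[order(-dets$confidence), , drop = FALSE][1:2, ]
    ord <- order(top$cx, top$cy)
    top <- top[ord, , drop = FALSE]
    top$embryo_index <- c(1L, 2L)
  } else {
    top <- dets
    if (state$left_n == 0L && state$right_n == 0L) {
      top$embryo_index <- 1L
    } else {
      lm <- if (state$left_n) state$left_sum / state$left_n else Inf
      rm <- if (state$right_n) state$right_sum / state$right_n else Inf
      top$embryo_index <- if (abs(top$cx - lm) <= abs(top$cx - rm)) 1L else 2L
    }
  }
  for (i in seq_len(nrow(top))) {
    if (top$embryo_index[i] == 1L) {
      state$left_sum <- state$left_sum + top$cx[i]
      state$left_n <- state$left_n + 1L
    } else {
      state$right_sum <- state$right_sum + top$cx[i]
      state$right_n <- state$right_n + 1L
    }
  }
  top$cx <- NULL; top$cy <- NULL
  list(assign = top, state = state)
}

#' Render a Day/Patient/Medium/Embryo folder path
#'
#' Layout: \code{Day_\{day\}/D\{day\}_\{NNN\}/Medium_\{MM\}/Embryo_\{EE\}}
#' with the patient number zero-padded to 3 digits and medium/embryo indices
#' to 2 digits (widths grow when counts exceed the padding).
#'
#' @param day day of development, 3 or 5.
#' @param patient patient number (integer) or a ready-made ID string of the
#'   form \code{D\{day\}_\{NNN\}}.
#' @param medium 1-based growth-medium (drop) index.
#' @param embryo 1 (left) or 2 (right).
#' @return relative path string
#' @export
layoutPath <- function(day, patient, medium, embryo) {
  stopifnot(day %in% c(3, 5), medium >= 1, embryo >= 1)
  pid <- if (is.character(patient)) patient else
    sprintf("D%d_%03d", as.integer(day), as.integer(patient))
  file.path(sprintf("Day_%d", as.integer(day)), pid,
            sprintf("Medium_%02d", as.integer(medium)),
            sprintf("Embryo_%02d", as.integer(embryo)))
}

#' Crop a detection from a frame and save it
#'
#' The box is rounded outward to integer pixel bounds, optionally padded, and
#' clamped to the frame; the crop is written as
#' \code{image_\{seq\}.jpg} (2-digit zero-padded sequence) under \code{dir}.
#' A crop that collapses to zero area after clamping is skipped with a
#' warning.
#'
#' @param frame frame record or H x W x 3 pixel array.
#' @param box a box (data.frame row or named/plain numeric vector).
#' @param dir destination folder (created if missing).
#' @param seq 1-based, per-folder gapless image sequence number.
#' @param pad extra pixels on each side (default 0).
#' @param quality JPEG quality (default 95).
#' @return the saved path, or \code{NULL} when skipped
#' @export
cropAndSave <- function(frame, box, dir, seq, pad = 0L, quality = 95) {
  stopifnot(seq >= 1)
  px <- if (is.list(frame) && !is.data.frame(frame)) frame$pixels else frame
  H <- dim(px)[1]; W <- dim(px)[2]
  b <- boxVec(box)
  x0 <- clamp(floor(b[1]) - pad, 0, W); x1 <- clamp(ceiling(b[3]) + pad, 0, W)
  y0 <- clamp(floor(b[2]) - pad, 0, H); y1 <- clamp(ceiling(b[4]) + pad, 0, H)
  if (x1 - x0 < 1 || y1 - y0 < 1) {
    warnf("zero-area crop after clamping; skipped (box %s)", paste(round(b, 1), collapse = ","))
    return(NULL)
  }
  crop <- px[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  path <- file.path(dir, sprintf("image_%02d.jpg", as.integer(seq)))
  writeImageFile(crop, path, quality = quality)
  path
}

#' Organize a frame stream into the per-embryo folder tree
#'
#' End-to-end organization stage: partitions the detection stream into
#' growth-medium segments (\code{\link{segmentStream}}), maps surviving
#' segments to \code{Medium_01..Medium_n}, assigns each in-segment frame's
#' detections to the left/right embryo folders (\code{\link{assignSides}};
#' side history is reset at each new drop, since the embryo pair changes),
#' and saves one crop per assigned detection. Frames inside a segment with
#' zero detections contribute nothing.
#'
#' @param video an \linkS4class{EmbryoVideo}.
#' @param detset a \linkS4class{DetectionSet} aligned with the stream.
#' @param day day of development, 3 or 5.
#' @param patient patient number or ID string (see \code{\link{layoutPath}}).
#' @param out_root output tree root.
#' @param gap_frames,min_len_frames see \code{\link{segmentStream}}.
#' @param pad crop padding in pixels.
#' @param quality JPEG quality.
#' @return an OrganizeReport: list with \code{day}, \code{patient_id},
#'   \code{segments} (data.frame incl. \code{duration_s}),
#'   \code{folder_counts} (named vector of crops per embryo folder) and
#'   \code{crops_total}
#' @export
organizeVideo <- function(video, detset, day, patient, out_root,
                         gap_frames = 5L, min_len_frames = 5L,
                         pad = 0L, quality = 95) {
  stopifnot(day %in% c(3, 5))
  segs <- segmentStream(detset, gap_frames, min_len_frames)
  fps <- videoMeta(video)$target_fps
  det <- detections(detset)
  byIndex <- setNames(video@frames,
                      vapply(video@frames, function(f) as.character(f$index), character(1)))
  counters <- list()
  for (s in seq_len(nrow(segs))) {
    state <- newSideState()
    for (fi in segs$first_frame[s]:segs$last_frame[s]) {
      d <- det[det$frame_index == fi, , drop = FALSE]
      if (!nrow(d)) next
      fr <- byIndex[[as.character(fi)]]
      if (is.null(fr)) next
      res <- assignSides(d, state)
      state <- res$state
      for (i in seq_len(nrow(res$assign))) {
        rel <- layoutPath(day, patient, segs$drop_index[s], res$assign$embryo_index[i])
        counters[[rel]] <- (counters[[rel]] %||% 0L) + 1L
        cropAndSave(fr, res$assign[i, ], file.path(out_root, rel),
                    counters[[rel]], pad = pad, quality = quality)
      }
    }
  }
  segs$duration_s <- segmentDuration(segs$first_frame, segs$last_frame, fps)
  pid <- if (is.character(patient)) patient else
    sprintf("D%d_%03d", as.integer(day), as.integer(patient))
  list(day = day, patient_id = pid, segments = segs,
       folder_counts = unlist(counters) %||% integer(0),
       crops_total = sum(unlist(counters) %||% 0L))
}

#' Serialize an organize report to JSON
#'
#' @param report a report from \code{\link{organizeVideo}}.
#' @param path output file; when NULL the JSON string is returned.
#' @return path (invisibly) or JSON string
#' @export
writeOrganizeReport <- function(report, path = NULL) {
  rep <- report
  rep$folder_counts <- as.list(report$folder_counts)
  if (is.null(path))
    return(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
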
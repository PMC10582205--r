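#' EmbryoVideo: a downsampled microscopy frame stream
#'
#' Container for an ordered sequence of decoded frames together with the
#' stream metadata. Each frame is a list with fields \code{index} (position in
#' the downsampled stream, 0-based), \code{source_index} (position in the
#' original stream), \code{timestamp_s} (\code{index / target_fps}) and
#' \code{pixels}, an H x W x 3 integer array of 8-bit intensities with origin
#' top-left (row = y downward, column = x rightward).
#'
#' @slot frames list of frame records as described above.
#' @slot meta list with \code{source_fps}, \code{target_fps}, \code{width},
#'   \code{height}, \code{n_source_frames}, \code{n_kept_frames}.
#'
#' @exportClass EmbryoVideo
setClass("EmbryoVideo", representation(frames = "list", meta = "list"))

setValidity("EmbryoVideo", function(object) {
  m <- object@meta
  need <- c("source_fps", "target_fps", "width", "height",
            "n_source_frames", "n_kept_frames")
  if (!all(need %in% names(m)))
    return(paste("meta must contain:", paste(need, collapse = ", ")))
  if (m$target_fps > m$source_fps)
    return("target_fps must not exceed source_fps")
  if (length(object@frames) != m$n_kept_frames)
    return("n_kept_frames does not match the number of stored frames")
  if (length(object@frames)) {
    ts <- vapply(object@frames, function(f) f$timestamp_s, numeric(1))
    if (any(ts < 0) || is.unsorted(ts, strictly = TRUE))
      return("timestamps must be non-negative and strictly increasing")
    d <- dim(object@frames[[1]]$pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("frame pixels must be H x W x 3 arrays")
    if (d[1] != m$height || d[2] != m$width)
      return("frame dimensions disagree with meta width/height")
  }
  TRUE
})

#' @describeIn EmbryoVideo number of kept frames
#' @param x an \code{EmbryoVideo}
#' @export
nFrames <- function(x) length(x@frames)

#' @describeIn EmbryoVideo stream metadata list
#' @export
videoMeta <- function(x) x@meta

#' @describeIn EmbryoVideo frame record at 1-based position \code{i}
#' @param i 1-based position in the kept stream
#' @export
getFrame <- function(x, i) {
  stopifnot(i >= 1, i <= length(x@frames))
  x@frames[[i]]
}

setMethod("show", "EmbryoVideo", function(object) {
  m <- object@meta
  cat(sprintf("EmbryoVideo: %d frames (%dx%d), %g fps (downsampled from %g fps, %d source frames)\n",
              length(object@frames), m$width, m$height, m$target_fps,
              m$source_fps, m$n_source_frames))
})

#' DetectionSet: per-frame embryo detections
#'
#' One row per detection with continuous pixel bounding-box corners (origin
#' top-left, 0-based) and a confidence in [0, 1]. The \code{frames} slot lists
#' every frame index covered by the set, including frames with zero
#' detections (transition frames), so detection counts per frame are well
#' defined.
#'
#' @slot det data.frame with columns \code{frame_index}, \code{x_min},
#'   \code{y_min}, \code{x_max}, \code{y_max}, \code{confidence}.
#' @slot frames integer vector of covered frame indices (sorted).
#' @slot width,height frame dimensions in pixels.
#'
#' @exportClass DetectionSet
setClass("DetectionSet", representation(det = "data.frame", frames = "integer",
                                        width = "numeric", height = "numeric"))

setValidity("DetectionSet", function(object) {
  d <- object@det
  need <- c("frame_index", "x_min", "y_min", "x_max", "y_max", "confidence")
  if (!all(need %in% names(d)))
    return(paste("det must contain columns:", paste(need, collapse = ", ")))
  if (nrow(d)) {
    if (any(d$x_min >= d$x_max) || any(d$y_min >= d$y_max))
      return("degenerate bounding box (x_min >= x_max or y_min >= y_max)")
    if (any(d$confidence < 0 | d$confidence > 1))
      return("confidence must lie in [0, 1]")
    if (any(d$x_min < 0) || any(d$y_min < 0) ||
        any(d$x_max > object@width) || any(d$y_max > object@height))
      return("boxes must lie within [0,W] x [0,H]")
    if (!all(d$frame_index %in% object@frames))
      return("det references frame indices missing from frames")
  }
  if (is.unsorted(object@frames, strictly = TRUE))
    return("frames must be strictly increasing")
  TRUE
})

#' Construct a DetectionSet
#'
#' @param det data.frame of detections (see \linkS4class{DetectionSet}); may
#'   be empty.
#' @param frames integer vector of all covered frame indices.
#' @param width,height frame dimensions in pixels.
#' @return a \linkS4class{DetectionSet}
#' @export
DetectionSet <- function(det = emptyDetDF(), frames = integer(0), width, height) {
  det <- as.data.frame(det)
  if (nrow(det) == 0) det <- emptyDetDF()
  new("DetectionSet", det = det, frames = as.integer(sort(unique(frames))),
      width = width, height = height)
}

#' @describeIn DetectionSet the detection table
#' @param x a \code{DetectionSet}
#' @export
detections <- function(x) x@det

#' @describeIn DetectionSet covered frame indices
#' @export
frameIndices <- function(x) x@frames

#' @describeIn DetectionSet named vector: detections per covered frame
#' @export
detectionCounts <- function(x) {
  n <- setNames(integer(length(x@frames)), as.character(x@frames))
  if (nrow(x@det)) {
    tb <- table(factor(as.character(x@det$frame_index), levels = names(n)))
    n[] <- as.integer(tb)
  }
  n
}

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet: %d detections over %d frames (%gx%g px)\n",
              nrow(object@det), length(object@frames), object@width, object@height))
})

#' SceneManifest: per-frame ground truth from the synthetic generator
#'
#' Records, for every generated frame, the scene phase (\code{setup},
#' \code{ramp}, \code{clear}, \code{transition}), the Gaussian blur sigma
#' applied, and the true embryo bounding boxes with drop index and side.
#' Boxes are present exactly on clear-phase frames and (flagged by their
#' phase) on focus-ramp frames.
#'
#' @slot frames data.frame with columns \code{frame_index}, \code{phase},
#'   \code{sigma}, \code{drop_index} (NA outside drops).
#' @slot boxes data.frame with columns \code{frame_index}, \code{drop_index},
#'   \code{side} ("left"/"right"), \code{phase}, \code{x_min}, \code{y_min},
#'   \code{x_max}, \code{y_max}.
#' @slot fps frames per second of the generated stream.
#' @slot width,height frame dimensions.
#' @slot day day of development (3 or 5).
#' @slot n_drops number of growth-medium drops in the scene.
#'
#' @exportClass SceneManifest
setClass("SceneManifest",
         representation(frames = "data.frame", boxes = "data.frame",
                        fps = "numeric", width = "numeric", height = "numeric",
                        day = "numeric", n_drops = "numeric"))

setValidity("SceneManifest", function(object) {
  if (!all(c("frame_index", "phase", "sigma", "drop_index") %in% names(object@frames)))
    return("frames must have frame_index, phase, sigma, drop_index")
  if (nrow(object@boxes)) {
    b <- object@boxes
    if (any(b$x_min >= b$x_max) || any(b$y_min >= b$y_max))
      return("degenerate manifest box")
    if (!all(b$phase %in% c("clear", "ramp")))
      return("manifest boxes may only occur on clear or ramp frames")
  }
  TRUE
})

#' @describeIn SceneManifest per-frame phase table
#' @param x a \code{SceneManifest}
#' @export
manifestFrames <- function(x) x@frames

#' @describeIn SceneManifest ground-truth box table
#' @export
manifestBoxes <- function(x) x@boxes

setMethod("show", "SceneManifest", function(object) {
  ph <- table(object@frames$phase)
  cat(sprintf("SceneManifest: %d frames, %d drops, day %d (%s)\n",
              nrow(object@frames), object@n_drops, object@day,
              paste(sprintf("%s=%d", names(ph), as.integer(ph)), collapse = ", ")))
})
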
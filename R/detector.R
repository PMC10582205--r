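#' Default settings for the classical embryo detector
#'
#' Area bounds are fractions of the frame area; \code{c_min} is the minimum
#' circularity \eqn{4\pi A / P^2} a component must reach to count as an
#' embryo; \code{sigma} is the Gaussian pre-smoothing width in pixels;
#' \code{sd_window} the side of the local-standard-deviation window;
#' \code{close_radius} the disc radius of the morphological closing.
#'
#' @return a named list of detector parameters
#' @export
detectorDefaults <- function() {
  list(area_min_frac = 0.005, area_max_frac = 0.25, c_min = 0.6,
       sigma = 2, sd_window = 9L, close_radius = 5L)
}

#' Weight-free classical embryo detector
#'
#' Detects textured roughly-circular objects (embryos) in a single frame
#' without any trained model: grayscale -> Gaussian smoothing -> local
#' standard-deviation contrast map -> Otsu threshold -> morphological closing
#' -> connected components -> area and circularity filter. Each surviving
#' component yields a tight bounding box; confidence is the component's
#' circularity clamped to [0, 1]. Results are sorted by descending
#' confidence. A structureless (constant) frame yields zero detections.
#'
#' @param frame frame record, H x W x 3 array, or grayscale matrix.
#' @param params detector settings, see \code{\link{detectorDefaults}}.
#' @return data.frame with columns \code{x_min}, \code{y_min}, \code{x_max},
#'   \code{y_max}, \code{confidence} (possibly 0 rows)
#' @export
detectClassical <- function(frame, params = detectorDefaults()) {
  g <- toGrayscale(frame)
  H <- nrow(g); W <- ncol(g)
  empty <- emptyDetDF()[, -1]
  img <- EBImage::Image(t(g) / 255)                     # [x, y]
  sm <- EBImage::gblur(img, sigma = params$sigma)
  w <- params$sd_window
  box <- matrix(1 / w^2, w, w)
  mu <- EBImage::filter2(sm, box, boundary = "replicate")
  mu2 <- EBImage::filter2(sm^2, box, boundary = "replicate")
  sdm <- sqrt(pmax(EBImage::imageData(mu2) - EBImage::imageData(mu)^2, 0))
  mx <- max(sdm)
  if (mx <= 0) return(empty)
  sdn <- sdm / mx
  thr <- EBImage::otsu(EBImage::Image(sdn))
  bw <- sdn > thr
  bw <- EBImage::closing(bw, EBImage::makeBrush(2L * params$close_radius + 1L, "disc"))
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  ft <- EBImage::computeFeatures.shape(lab)
  area <- ft[, "s.area"]
  per <- pmax(ft[, "s.perimeter"], 1)
  circ <- 4 * pi * area / per^2
  amin <- params$area_min_frac * W * H
  amax <- params$area_max_frac * W * H
  keep <- which(area >= amin & area <= amax & circ >= params$c_min)
  if (!length(keep)) return(empty)
  labm <- EBImage::imageData(lab)                       # [x, y] label matrix
  out <- do.call(rbind, lapply(keep, function(i) {
    idx <- which(labm == i, arr.ind = TRUE)             # row = x, col = y
    data.frame(x_min = min(idx[, 1]) - 1, y_min = min(idx[, 2]) - 1,
               x_max = max(idx[, 1]), y_max = max(idx[, 2]),
               confidence = min(circ[i], 1))
  }))
  out[order(-out$confidence), , drop = FALSE]
}

#' Run the classical detector over a frame stream
#'
#' @param video an \linkS4class{EmbryoVideo}.
#' @param params detector settings.
#' @return a \linkS4class{DetectionSet} covering every frame of the stream
#' @export
detectVideo <- function(video, params = detectorDefaults()) {
  m <- videoMeta(video)
  rows <- lapply(video@frames, function(f) {
    d <- detectClassical(f, params)
    if (nrow(d)) cbind(frame_index = f$index, d) else NULL
  })
  det <- do.call(rbind, rows)
  DetectionSet(det %||% emptyDetDF(),
               frames = vapply(video@frames, function(f) f$index, integer(1)),
               width = m$width, height = m$height)
}

#' Read one normalized YOLO-format detection file
#'
#' Each line is \code{"class cx cy w h [conf]"} with \code{cx, cy, w, h}
#' normalized to [0, 1]; a missing confidence defaults to 1. Center/size
#' coordinates are converted to pixel corners
#' (\code{x_min = (cx - w/2) * W}, ...) and clamped to the frame.
#'
#' @param path detection text file; one object per line, may be empty.
#' @param image_w,image_h frame dimensions in pixels.
#' @return data.frame with \code{x_min}, \code{y_min}, \code{x_max},
#'   \code{y_max}, \code{confidence}
#' @export
readDetections <- function(path, image_w, image_h) {
  if (!file.exists(path)) stopf("detection file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emptyDetDF()[, -1])
  out <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!(length(tok) %in% c(5L, 6L)))
      stopf("%s line %d: expected 'class cx cy w h [conf]', got %d fields",
            path, i, length(tok))
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      stopf("%s line %d: non-numeric field", path, i)
    vals <- v[2:length(v)]
    if (any(vals < 0 | vals > 1))
      stopf("%s line %d: normalized values outside [0,1]", path, i)
    cx <- v[2]; cy <- v[3]; w <- v[4]; h <- v[5]
    conf <- if (length(v) == 6L) v[6] else 1.0
    data.frame(x_min = clamp((cx - w / 2) * image_w, 0, image_w),
               y_min = clamp((cy - h / 2) * image_h, 0, image_h),
               x_max = clamp((cx + w / 2) * image_w, 0, image_w),
               y_max = clamp((cy + h / 2) * image_h, 0, image_h),
               confidence = conf)
  })
  do.call(rbind, out)
}

#' Read a directory of per-frame detection files
#'
#' Files are named \code{frame_\%06d.txt}; the digits give the frame index.
#' Frames listed in \code{frames} but lacking a file are treated as having
#' zero detections.
#'
#' @param dir directory of detection text files.
#' @param image_w,image_h frame dimensions in pixels.
#' @param frames optional integer vector of covered frame indices; defaults
#'   to the indices present as files.
#' @return a \linkS4class{DetectionSet}
#' @export
readDetectionsDir <- function(dir, image_w, image_h, frames = NULL) {
  if (!dir.exists(dir)) stopf("detections directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  idx <- as.integer(gsub("\\D", "", basename(files)))
  rows <- lapply(seq_along(files), function(k) {
    d <- readDetections(files[k], image_w, image_h)
    if (nrow(d)) cbind(frame_index = idx[k], d) else NULL
  })
  DetectionSet(do.call(rbind, rows) %||% emptyDetDF(),
               frames = frames %||% idx, width = image_w, height = image_h)
}

#' Intersection over union of two boxes
#'
#' Computed on continuous areas; 0 for disjoint boxes.
#'
#' @param a,b numeric vectors \code{c(x_min, y_min, x_max, y_max)} (extra
#'   elements ignored; named data.frame rows accepted).
#' @return IoU in [0, 1]
#' @export
boxIoU <- function(a, b) {
  a <- boxVec(a); b <- boxVec(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

# coerce a box given as data.frame row, named or plain vector to c(x0,y0,x1,y1)
boxVec <- function(x) {
  nm <- c("x_min", "y_min", "x_max", "y_max")
  if (is.data.frame(x)) return(as.numeric(x[1, nm]))
  if (!is.null(names(x)) && all(nm %in% names(x))) return(as.numeric(x[nm]))
  as.numeric(x[1:4])
}
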
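#' Read a frame stream with temporal downsampling
#'
#' Decodes an ordered image sequence into an \linkS4class{EmbryoVideo},
#' keeping every \code{stride}-th source frame starting at source index 0,
#' where \code{stride = round(source_fps / target_fps)}. Clinical capture runs
#' at 25 fps; analysis uses a 5 fps stream, so the default stride is 5.
#'
#' Input is a directory of numbered PNG/JPEG frames (e.g.
#' \code{frame_000000.png}); ordering is the numeric sort of the digits in the
#' filenames. If the directory contains a \code{meta.json} with an \code{fps}
#' field (as written by \code{\link{writeSyntheticVideo}}) it supplies
#' \code{source_fps} when the argument is missing. A path to a single file is
#' rejected: frame extraction from encoded containers is delegated to external
#' tooling, and the package consumes the extracted frames.
#'
#' @param path directory of numbered image frames.
#' @param target_fps desired output rate (frames/second); default 5.
#' @param source_fps capture rate of the stored frames; default 25 unless a
#'   \code{meta.json} in \code{path} declares it.
#' @return an \linkS4class{EmbryoVideo}
#' @export
readFrames <- function(path, target_fps = 5, source_fps = NULL) {
  if (!file.exists(path))
    stopf("input path does not exist: %s", path)
  if (!dir.exists(path))
    stopf("cannot decode '%s': not a frame directory (extract frames to a directory of numbered images first)", path)
  metaf <- file.path(path, "meta.json")
  if (is.null(source_fps)) {
    source_fps <- if (file.exists(metaf))
      jsonlite::read_json(metaf)$fps %||% 25 else 25
  }
  files <- list.files(path, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files))
    stopf("no decodable frames found in %s", path)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  num[is.na(num)] <- Inf
  files <- files[order(num, basename(files))]
  framesFromImages(files, source_fps = source_fps, target_fps = target_fps)
}

# core downsampling over an ordered list of image paths
framesFromImages <- function(files, source_fps, target_fps) {
  stopifnot(source_fps > 0, target_fps > 0)
  if (target_fps > source_fps)
    stopf("target_fps (%g) exceeds source_fps (%g)", target_fps, source_fps)
  ratio <- source_fps / target_fps
  stride <- as.integer(round(ratio))
  if (abs(ratio - stride) > 1e-9)
    warnf("source_fps/target_fps = %g is not an integer; using stride %d", ratio, stride)
  n_src <- length(files)
  keep <- which((seq_len(n_src) - 1L) %% stride == 0L)
  frames <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    px <- readImageArray(files[keep[k]])
    frames[[k]] <- list(index = k - 1L, source_index = keep[k] - 1L,
                        timestamp_s = (k - 1L) / target_fps, pixels = px)
  }
  d <- if (length(frames)) dim(frames[[1]]$pixels) else c(0L, 0L, 3L)
  new("EmbryoVideo", frames = frames,
      meta = list(source_fps = source_fps, target_fps = target_fps,
                  width = d[2], height = d[1],
                  n_source_frames = n_src, n_kept_frames = length(frames)))
}

# Build an EmbryoVideo from in-memory pixel arrays (no downsampling).
videoFromArrays <- function(pixelList, fps, source_fps = fps) {
  frames <- lapply(seq_along(pixelList), function(k) {
    list(index = k - 1L, source_index = k - 1L,
         timestamp_s = (k - 1L) / fps, pixels = pixelList[[k]])
  })
  d <- if (length(frames)) dim(frames[[1]]$pixels) else c(0L, 0L, 3L)
  new("EmbryoVideo", frames = frames,
      meta = list(source_fps = source_fps, target_fps = fps,
                  width = d[2], height = d[1],
                  n_source_frames = length(frames), n_kept_frames = length(frames)))
}

# Read one image file into an H x W x 3 integer array of 8-bit values.
readImageArray <- function(file) {
  img <- EBImage::readImage(file)
  a <- EBImage::imageData(img)           # [x, y(, c)] in [0, 1]
  if (length(dim(a)) == 2L) {
    g <- t(a)
    a <- array(g, dim = c(dim(g), 3L))
  } else {
    a <- aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  }
  array(as.integer(round(clamp(a, 0, 1) * 255)), dim = dim(a))
}

#' Convert a frame to 8-bit grayscale
#'
#' BT.601 luma: \code{gray = round(0.299 R + 0.587 G + 0.114 B)}, clamped to
#' [0, 255].
#'
#' @param frame a frame record from an \linkS4class{EmbryoVideo}, or an
#'   H x W x 3 array, or an already-gray H x W matrix (returned unchanged).
#' @return H x W integer matrix of 8-bit intensities
#' @export
toGrayscale <- function(frame) {
  px <- if (is.list(frame)) frame$pixels else frame
  if (is.matrix(px)) return(px)
  stopifnot(length(dim(px)) == 3L, dim(px)[3] >= 3L)
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  matrix(as.integer(clamp(round(g), 0, 255)), nrow = dim(px)[1])
}

#' Write an image grid to a JPEG file
#'
#' Grayscale matrices are written single-channel; H x W x 3 arrays are written
#' as color. The parent directory is created if missing.
#'
#' @param pixels H x W matrix or H x W x 3 array of 8-bit values.
#' @param path output file path.
#' @param quality JPEG quality, integer in 1..100 (default 95).
#' @return the written path, invisibly
#' @export
writeImageFile <- function(pixels, path, quality = 95) {
  if (!is.numeric(quality) || length(quality) != 1 || quality < 1 || quality > 100)
    stopf("quality must be a single integer in 1..100, got %s", paste(quality, collapse = ","))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(path)))
    stopf("cannot create directory for %s", path)
  img <- pixelsToImage(pixels)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    EBImage::writeImage(img, path, quality = as.integer(quality))
  } else {
    EBImage::writeImage(img, path)
  }
  invisible(path)
}

# H x W (x3) 8-bit array -> EBImage Image
pixelsToImage <- function(pixels) {
  if (is.matrix(pixels)) {
    EBImage::Image(t(pixels) / 255)
  } else {
    stopifnot(length(dim(pixels)) == 3L)
    EBImage::Image(aperm(pixels, c(2L, 1L, 3L)) / 255, colormode = "Color")
  }
}
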
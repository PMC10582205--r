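# Small in-code fixtures; everything is generated at test time.

# short scene for unit tests (the full-length defaults are exercised in the
# acceptance suite)
shortScript <- function(n_drops = 1, day = 3) {
  defaultScript(n_drops, day = day, setup_s = 2, ramp_s = 1.2,
                transition_s = 1.6, clear_s = c(3, 2.4))
}

shortGen <- function(seed = 0, n_drops = 1, day = 3, width = 160, height = 120) {
  generateVideo(shortScript(n_drops, day), seed = seed,
                width = width, height = height)
}

# constant-color frame record
flatFrame <- function(value = 128, H = 40, W = 60) {
  list(index = 0L, source_index = 0L, timestamp_s = 0,
       pixels = array(as.integer(value), dim = c(H, W, 3L)))
}

# random valid integer-coordinate box within [0, lim]^2
randomIntBox <- function(lim = 20) {
  x <- sort(sample(0:lim, 2)); y <- sort(sample(0:lim, 2))
  if (x[1] == x[2]) x[2] <- x[2] + 1
  if (y[1] == y[2]) y[2] <- y[2] + 1
  c(x_min = x[1], y_min = y[1], x_max = x[2], y_max = y[2])
}

# random per-frame ground-truth boxes (n_frames x per_frame), seeded
mkBoxes <- function(n_frames, per_frame = 2, seed = 0, lim = 100) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_frames) - 1L, function(fi) {
    do.call(rbind, lapply(seq_len(per_frame), function(i) {
      x0 <- runif(1, 0, lim - 20); y0 <- runif(1, 0, lim - 20)
      data.frame(frame_index = fi, x_min = x0, y_min = y0,
                 x_max = x0 + runif(1, 5, 20), y_max = y0 + runif(1, 5, 20))
    }))
  }))
}

# DetectionSet from a data.frame of boxes (+ optional confidence)
detsetFromBoxes <- function(df, frames = NULL, width = 100, height = 100) {
  if (!"confidence" %in% names(df)) df$confidence <- rep(1.0, nrow(df))
  DetectionSet(df, frames = frames %||% sort(unique(df$frame_index)),
               width = width, height = height)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian blur on an 8-bit matrix, kernel capped at the image size
blur8 <- function(g, sigma) {
  if (sigma == 0) return(g)
  r <- min(2 * ceiling(3 * sigma) + 1, min(dim(g)) - 1 - (min(dim(g)) %% 2 == 0))
  if (r %% 2 == 0) r <- r - 1
  img <- EBImage::gblur(EBImage::Image(t(g) / 255), sigma = sigma, radius = r)
  round(t(EBImage::imageData(img)) * 255)
}

# write one normalized YOLO detection file
writeDetFile <- function(path, lines) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  path
}

# directory digest for idempotence checks: relative path -> md5
treeDigest <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  setNames(tools::md5sum(files), sub(paste0("^", root, "/?"), "", files))
}
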
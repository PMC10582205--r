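#' Default scene script for a grouped-embryo observation video
#'
#' Emulates the structure of a clinical observation session: a long blurry
#' setup period while the microscope is prepared, then for each
#' growth-medium drop a short focus ramp (blurry frames that already show the
#' embryo pair), a clear evaluation phase, and a blurry embryo-free
#' transition while the stage moves to the next drop. Clear-phase durations
#' cycle through 15 s, 4 s and 7.2 s — a thorough evaluation, a quickly
#' dismissed pair, and an intermediate one. The day of development selects
#' the embryo texture scale (cleavage-stage day-3 embryos carry coarser
#' internal contrast than day-5 blastocysts), which is what places clear-crop
#' sharpness scores inside the day's default blur band.
#'
#' @param n_drops number of growth-medium drops (>= 1).
#' @param day day of development, 3 or 5 (default 3).
#' @param setup_s,ramp_s,transition_s phase durations in seconds.
#' @param clear_s recycled vector of clear-phase durations in seconds.
#' @return a SceneScript: list of phase descriptors with attributes
#'   \code{day}
#' @export
defaultScript <- function(n_drops, day = 3, setup_s = 16, ramp_s = 2,
                          transition_s = 2, clear_s = c(15, 4, 7.2)) {
  stopifnot(n_drops >= 1, day %in% c(3, 5))
  phases <- list(list(type = "setup", duration_s = setup_s, sigma_range = c(4, 7)))
  for (d in seq_len(n_drops)) {
    phases <- c(phases, list(
      list(type = "ramp", duration_s = ramp_s, sigma_from = 6, sigma_to = 2, drop = d),
      list(type = "clear", duration_s = clear_s[(d - 1L) %% length(clear_s) + 1L], drop = d),
      list(type = "transition", duration_s = transition_s, sigma_range = c(4, 6))
    ))
  }
  structure(phases, day = day, n_drops = n_drops, class = "SceneScript")
}

# rendering constants: background level, embryo interior level, rim
# darkening, sensor noise sd, texture amplitude by day (chosen so the default
# blur bands hold at the default 256x192 scale) and the optical blur floor
# applied even to in-focus frames
sceneDefaults <- function(day) {
  list(bg = 180, interior = 150, rim = 45, noise_sd = 2,
       tex_amp = if (day == 3) 50 else 28, tex_sigma = 1.1,
       radius_frac = c(0.12, 0.15), optics_sigma = 0.7)
}

#' Generate a synthetic microscopy video with ground truth
#'
#' Renders the scripted scene at a fixed seed: embryos are disks with a dark
#' rim and granular internal texture (a thresholded smoothed-noise field, so
#' clear crops carry high-frequency content) on a near-uniform background
#' with mild sensor noise; each frame is Gaussian-blurred with the phase's
#' scripted sigma. Identical (script, seed) pairs produce bit-identical
#' frames and manifest. Embryo geometry (centers, radii, slow drift) is drawn
#' once per drop; the left embryo's x-center is always smaller than the
#' right's.
#'
#' @param script a SceneScript from \code{\link{defaultScript}}.
#' @param seed integer seed for all randomness.
#' @param fps frames per second of the generated stream (default 5, the
#'   downsampled analysis rate).
#' @param width,height frame size in pixels.
#' @return list with \code{video} (\linkS4class{EmbryoVideo}) and
#'   \code{manifest} (\linkS4class{SceneManifest})
#' @export
generateVideo <- function(script, seed, fps = 5, width = 256, height = 192) {
  day <- attr(script, "day") %||% 3
  n_drops <- attr(script, "n_drops") %||%
    max(c(0, vapply(script, function(p) p$drop %||% 0, numeric(1))))
  sc <- sceneDefaults(day)
  withSeed(seed, {
    drops <- lapply(seq_len(max(n_drops, 1L)), function(d)
      sampleDrop(width, height, sc))
    pixelList <- list()
    frameRows <- list()
    boxRows <- list()
    k <- 0L
    for (ph in script) {
      n <- max(1L, as.integer(round(ph$duration_s * fps)))
      for (j in seq_len(n)) {
        sigma <- switch(ph$type,
          setup = runif(1, ph$sigma_range[1], ph$sigma_range[2]),
          transition = runif(1, ph$sigma_range[1], ph$sigma_range[2]),
          ramp = ph$sigma_from + (ph$sigma_to - ph$sigma_from) *
            (if (n > 1) (j - 1) / (n - 1) else 1),
          clear = sc$optics_sigma)
        emb <- if (ph$type %in% c("ramp", "clear")) drops[[ph$drop]] else NULL
        t_in <- if (!is.null(emb)) {
          # frames elapsed inside this drop so far (ramp precedes clear)
          if (ph$type == "ramp") j - 1L else emb$ramp_frames + j - 1L
        } else 0L
        if (!is.null(emb) && ph$type == "ramp" && j == 1L)
          drops[[ph$drop]]$ramp_frames <- n
        g <- renderFrame(width, height, emb, t_in, sigma, sc)
        k <- k + 1L
        pixelList[[k]] <- array(as.integer(g), dim = c(height, width, 3L))
        frameRows[[k]] <- data.frame(frame_index = k - 1L, phase = ph$type,
                                     sigma = sigma,
                                     drop_index = if (is.null(emb)) NA_integer_ else ph$drop)
        if (!is.null(emb)) {
          for (side in c("left", "right")) {
            e <- emb[[side]]
            cx <- e$cx + e$vx * t_in; cy <- e$cy + e$vy * t_in
            boxRows[[length(boxRows) + 1L]] <- data.frame(
              frame_index = k - 1L, drop_index = ph$drop, side = side,
              phase = ph$type,
              x_min = cx - e$r, y_min = cy - e$r,
              x_max = cx + e$r, y_max = cy + e$r)
          }
        }
      }
    }
    frames <- do.call(rbind, frameRows)
    boxes <- do.call(rbind, boxRows) %||%
      data.frame(frame_index = integer(0), drop_index = integer(0),
                 side = character(0), phase = character(0),
                 x_min = numeric(0), y_min = numeric(0),
                 x_max = numeric(0), y_max = numeric(0))
    manifest <- new("SceneManifest", frames = frames, boxes = boxes,
                    fps = fps, width = width, height = height,
                    day = day, n_drops = n_drops)
    list(video = videoFromArrays(pixelList, fps), manifest = manifest)
  })
}

# draw the geometry and texture of one drop's embryo pair
sampleDrop <- function(W, H, sc) {
  r <- round(runif(1, sc$radius_frac[1], sc$radius_frac[2]) * min(W, H))
  margin <- r + 6
  mk <- function(xlo, xhi) {
    cx <- runif(1, xlo * W, xhi * W)
    cy <- runif(1, 0.42 * H, 0.58 * H)
    list(cx = clamp(cx, margin, W - margin), cy = clamp(cy, margin, H - margin),
         r = r, vx = runif(1, -0.02, 0.02), vy = runif(1, -0.02, 0.02),
         tex = makeTexture(r, sc))
  }
  left <- mk(0.22, 0.32)
  right <- mk(0.68, 0.78)
  if (left$cx >= right$cx) stop("embryo geometry out of order")  # unreachable by construction
  list(left = left, right = right, ramp_frames = 0L)
}

# granular internal texture: thresholded smoothed noise over the disk patch
makeTexture <- function(r, sc) {
  n <- 2L * r + 1L
  field <- matrix(runif(n * n), n, n)
  field <- EBImage::imageData(EBImage::gblur(EBImage::Image(field), sigma = sc$tex_sigma))
  gran <- (field > stats::median(field)) * 2 - 1
  sc$interior + sc$tex_amp * gran
}

# render one grayscale frame (H x W, 8-bit values)
renderFrame <- function(W, H, emb, t_in, sigma, sc) {
  g <- matrix(sc$bg + rnorm(H * W, 0, sc$noise_sd), H, W)
  if (!is.null(emb)) {
    for (side in c("left", "right")) {
      e <- emb[[side]]
      cx <- e$cx + e$vx * t_in; cy <- e$cy + e$vy * t_in
      x0 <- round(cx) - e$r; y0 <- round(cy) - e$r
      n <- 2L * e$r + 1L
      xs <- x0:(x0 + n - 1L); ys <- y0:(y0 + n - 1L)
      dx <- matrix(xs - cx, n, n, byrow = TRUE)   # varies along columns
      dy <- matrix(ys - cy, n, n)                 # varies along rows
      dist <- sqrt(dx^2 + dy^2)
      patch <- g[ys + 1L, xs + 1L]
      inside <- dist <= e$r
      rim <- dist <= e$r & dist > e$r - 2.5
      patch[inside] <- e$tex[inside]
      patch[rim] <- sc$interior - sc$rim
      g[ys + 1L, xs + 1L] <- patch
    }
  }
  if (sigma > 0.05) {
    img <- EBImage::gblur(EBImage::Image(t(g) / 255), sigma = sigma)
    g <- t(EBImage::imageData(img)) * 255
  }
  matrix(as.integer(clamp(round(g), 0, 255)), H, W)
}

#' Ground-truth detections from a manifest
#'
#' Converts the manifest's true boxes into a \linkS4class{DetectionSet} with
#' confidence 1, covering every manifest frame. Focus-ramp boxes (blurred but
#' visible embryos) can be included or excluded explicitly.
#'
#' @param manifest a \linkS4class{SceneManifest}.
#' @param include_ramp include boxes on focus-ramp frames (default TRUE).
#' @return a \linkS4class{DetectionSet}
#' @export
manifestDetections <- function(manifest, include_ramp = TRUE) {
  b <- manifestBoxes(manifest)
  if (!include_ramp) b <- b[b$phase == "clear", , drop = FALSE]
  det <- if (nrow(b))
    data.frame(frame_index = b$frame_index,
               x_min = clamp(b$x_min, 0, manifest@width),
               y_min = clamp(b$y_min, 0, manifest@height),
               x_max = clamp(b$x_max, 0, manifest@width),
               y_max = clamp(b$y_max, 0, manifest@height),
               confidence = 1.0)
  else emptyDetDF()
  DetectionSet(det, frames = manifestFrames(manifest)$frame_index,
               width = manifest@width, height = manifest@height)
}

#' Sharpness scores of the manifest's crops
#'
#' Crops each manifest box (rounded outward) from its frame and scores it
#' with \code{\link{laplacianVariance}}.
#'
#' @param video the generated \linkS4class{EmbryoVideo}.
#' @param manifest the matching \linkS4class{SceneManifest}.
#' @param phases which box phases to score ("clear", "ramp").
#' @return numeric vector of scores
#' @export
cropScores <- function(video, manifest, phases = "clear") {
  b <- manifestBoxes(manifest)
  b <- b[b$phase %in% phases, , drop = FALSE]
  if (!nrow(b)) return(numeric(0))
  W <- manifest@width; H <- manifest@height
  vapply(seq_len(nrow(b)), function(i) {
    fr <- getFrame(video, b$frame_index[i] + 1L)
    x0 <- clamp(floor(b$x_min[i]), 0, W); x1 <- clamp(ceiling(b$x_max[i]), 0, W)
    y0 <- clamp(floor(b$y_min[i]), 0, H); y1 <- clamp(ceiling(b$y_max[i]), 0, H)
    laplacianVariance(toGrayscale(fr$pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]))
  }, numeric(1))
}

#' Calibrate a clear/blur variance band from ground truth
#'
#' Reproduces the experimental threshold-setting procedure on synthetic
#' ground truth: clear-phase crop scores define the band (0.5th--99.5th
#' percentile, widened by a 20\% safety margin) and focus-ramp (blurred) crop
#' scores validate it. Calibration fails when the classes are not separable
#' — i.e. when more than 5\% of blurred crops fall inside the candidate band
#' or less than 99\% of clear crops do.
#'
#' @param video generated video, or a list of \code{list(video, manifest)}
#'   pairs to pool scores across seeds.
#' @param manifest matching manifest (ignored when \code{video} is a list of
#'   pairs).
#' @return numeric \code{c(lower, upper)}
#' @export
calibrateBand <- function(video, manifest = NULL) {
  pairs <- if (is.list(video) && is.null(manifest)) video
           else list(list(video = video, manifest = manifest))
  clear <- unlist(lapply(pairs, function(p) cropScores(p$video, p$manifest, "clear")))
  blur <- unlist(lapply(pairs, function(p) cropScores(p$video, p$manifest, "ramp")))
  if (length(clear) < 10L || length(blur) < 10L)
    stopf("calibration needs at least 10 crops per class (got %d clear, %d blurred)",
          length(clear), length(blur))
  q <- quantile(clear, c(0.005, 0.995), names = FALSE)
  band <- c(q[1] * 0.8, q[2] * 1.2)
  inClear <- mean(clear >= band[1] & clear <= band[2])
  inBlur <- mean(blur >= band[1] & blur <= band[2])
  if (inClear < 0.99 || inBlur > 0.05)
    stopf("calibration failed: classes not separable (%.1f%% clear and %.1f%% blurred crops inside the candidate band)",
          100 * inClear, 100 * inBlur)
  band
}

#' Write a generated video to disk
#'
#' Frames are written as \code{frame_\%06d.png} (readable back with
#' \code{\link{readFrames}}), the manifest as \code{manifest.json}, and a
#' \code{meta.json} declaring the fps.
#'
#' @param gen a \code{list(video, manifest)} from \code{\link{generateVideo}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly
#' @export
writeSyntheticVideo <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in gen$video@frames) {
    path <- file.path(dir, sprintf("frame_%06d.png", f$index))
    writeImageFile(f$pixels, path)
  }
  m <- gen$manifest
  jsonlite::write_json(
    list(fps = m@fps, width = m@width, height = m@height, day = m@day,
         n_drops = m@n_drops, frames = m@frames, boxes = m@boxes),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(fps = m@fps), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a manifest written by \code{\link{writeSyntheticVideo}}
#'
#' @param dir directory containing \code{manifest.json}.
#' @return a \linkS4class{SceneManifest}
#' @export
readManifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  boxes <- as.data.frame(j$boxes)
  if (!nrow(boxes))
    boxes <- data.frame(frame_index = integer(0), drop_index = integer(0),
                        side = character(0), phase = character(0),
                        x_min = numeric(0), y_min = numeric(0),
                        x_max = numeric(0), y_max = numeric(0))
  fr <- as.data.frame(j$frames)
  fr$drop_index <- as.integer(fr$drop_index)
  new("SceneManifest", frames = fr, boxes = boxes, fps = j$fps,
      width = j$width, height = j$height, day = j$day, n_drops = j$n_drops)
}
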
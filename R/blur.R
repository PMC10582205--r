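#' Day-specific clear/blur variance bands
#'
#' Inclusive [lower, upper] Laplacian-variance intervals inside which a crop
#' is accepted as clear: day 3 (cleavage stage) 500--2000, day 5 (blastocyst
#' stage) 300--900. Note the upper bound: unusually high variance is also
#' rejected, departing from the common one-sided variance blur test.
#'
#' @param day3,day5 length-2 numeric \code{c(lower, upper)} overrides.
#' @return list mapping day ("3", "5") to \code{c(lower, upper)}
#' @export
blurBands <- function(day3 = c(500, 2000), day5 = c(300, 900)) {
  stopifnot(length(day3) == 2, length(day5) == 2,
            day3[1] >= 0, day3[1] < day3[2], day5[1] >= 0, day5[1] < day5[2])
  list(`3` = as.numeric(day3), `5` = as.numeric(day5))
}

#' Variance-of-Laplacian sharpness score
#'
#' Convolves the grayscale image with the 3x3 Laplacian kernel
#' \code{[[0,1,0],[1,-4,1],[0,1,0]]} under mirror padding (reflection that
#' does not duplicate the edge pixel) and returns the population variance
#' (divide by N = H*W) of the signed response. Sharp textured images score
#' high; blurred or flat images score low; a constant image scores exactly 0.
#'
#' @param gray H x W matrix of 8-bit intensities (an H x W x 3 frame is
#'   converted with \code{\link{toGrayscale}} first).
#' @return non-negative sharpness score
#' @export
laplacianVariance <- function(gray) {
  g <- toGrayscale(gray)
  H <- nrow(g); W <- ncol(g)
  if (H < 3 || W < 3) stopf("image too small for the 3x3 Laplacian (%dx%d)", H, W)
  g <- matrix(as.numeric(g), H, W)
  p <- rbind(g[2, ], g, g[H - 1, ])        # mirror rows across the edge
  p <- cbind(p[, 2], p, p[, W - 1])        # mirror columns
  resp <- p[1:H, 2:(W + 1)] + p[3:(H + 2), 2:(W + 1)] +
    p[2:(H + 1), 1:W] + p[2:(H + 1), 3:(W + 2)] - 4 * p[2:(H + 1), 2:(W + 1)]
  mean((resp - mean(resp))^2)
}

#' Classify a sharpness score as clear or blurry
#'
#' A score is clear iff it lies inside the day's inclusive band
#' \code{lower <= score <= upper}; anything else (too flat or too noisy) is
#' blurry.
#'
#' @param score a \code{\link{laplacianVariance}} score.
#' @param day day of development, 3 or 5.
#' @param bands band configuration from \code{\link{blurBands}}.
#' @return "clear" or "blurry"
#' @export
classifyBlur <- function(score, day, bands = blurBands()) {
  b <- bands[[as.character(day)]]
  if (is.null(b)) stopf("no blur band configured for day %s", day)
  ifelse(score >= b[1] & score <= b[2], "clear", "blurry")
}

#' Filter an organized crop tree by sharpness
#'
#' Scores every \code{image_*.jpg} under the embryo folders of an organized
#' output tree and removes (or quarantines, or merely reports) the blurry
#' ones. Surviving clear images are renumbered gaplessly
#' \code{image_01.jpg..image_k.jpg}. A second pass over an already-filtered
#' tree removes nothing.
#'
#' @param root tree root as written by \code{\link{organizeVideo}} (or any
#'   directory whose leaf folders hold \code{image_*.jpg} files).
#' @param day day of development, 3 or 5 (selects the band).
#' @param bands band configuration, see \code{\link{blurBands}}.
#' @param mode "delete" removes blurry files, "quarantine" moves them to a
#'   \code{_blurry} sibling folder, "dry_run" only reports.
#' @return a FilterReport: list with \code{mode}, \code{day}, \code{band},
#'   \code{folders} (per folder: file, score, label, action), \code{kept},
#'   \code{removed}, \code{unreadable}
#' @export
filterTree <- function(root, day, bands = blurBands(), mode = c("delete", "quarantine", "dry_run")) {
  mode <- match.arg(mode)
  if (!dir.exists(root)) stopf("no such directory: %s", root)
  band <- bands[[as.character(day)]]
  if (is.null(band)) stopf("no blur band configured for day %s", day)
  dirs <- unique(dirname(list.files(root, pattern = "^image_\\d+\\.jpg$",
                                    recursive = TRUE, full.names = TRUE)))
  folders <- list(); kept <- 0L; removed <- 0L; unreadable <- 0L
  for (d in sort(dirs)) {
    files <- list.files(d, pattern = "^image_\\d+\\.jpg$", full.names = TRUE)
    files <- files[order(as.integer(gsub("\\D", "", basename(files))))]
    entries <- data.frame(file = basename(files), score = NA_real_,
                          label = NA_character_, action = NA_character_)
    surv <- character(0)
    for (i in seq_along(files)) {
      px <- tryCatch(readImageArray(files[i]), error = function(e) NULL)
      if (is.null(px)) {
        unreadable <- unreadable + 1L
        entries$action[i] <- "unreadable"
        next
      }
      sc <- laplacianVariance(toGrayscale(px))
      lab <- classifyBlur(sc, day, bands)
      entries$score[i] <- sc
      entries$label[i] <- lab
      if (lab == "clear") {
        kept <- kept + 1L
        entries$action[i] <- "kept"
        surv <- c(surv, files[i])
      } else {
        removed <- removed + 1L
        entries$action[i] <- switch(mode, delete = "deleted",
                                    quarantine = "quarantined", dry_run = "flagged")
        if (mode == "delete") {
          unlink(files[i])
        } else if (mode == "quarantine") {
          qd <- file.path(dirname(d), paste0(basename(d), "_blurry"))
          dir.create(qd, showWarnings = FALSE, recursive = TRUE)
          file.rename(files[i], file.path(qd, basename(files[i])))
        }
      }
    }
    if (mode != "dry_run") renumberImages(d, surv)
    folders[[relPath(d, root)]] <- entries
  }
  list(mode = mode, day = day, band = band, folders = folders,
       kept = kept, removed = removed, unreadable = unreadable)
}

# rename survivors to image_01..image_k without collisions
renumberImages <- function(dir, files) {
  if (!length(files)) return(invisible())
  width <- max(2L, nchar(length(files)))
  tmp <- file.path(dir, sprintf(".tmp_%04d.jpg", seq_along(files)))
  file.rename(files, tmp)
  file.rename(tmp, file.path(dir, sprintf(paste0("image_%0", width, "d.jpg"),
                                          seq_along(files))))
  invisible()
}

relPath <- function(path, root) {
  sub("^/*", "", sub(normalizePath(root, mustWork = FALSE), "",
                     normalizePath(path, mustWork = FALSE), fixed = TRUE))
}

#' Serialize a filter report to JSON
#'
#' @param report a report from \code{\link{filterTree}}.
#' @param path output file; when NULL the JSON string is returned.
#' @return path (invisibly) or JSON string
#' @export
writeFilterReport <- function(report, path = NULL) {
  if (is.null(path))
    return(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
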
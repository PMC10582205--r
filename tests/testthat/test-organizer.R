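test_that("segment state machine matches the hand-traced example and the run-merging oracle", {
  segs <- segmentStream(c(0L, 0L, 2L, 2L, 2L, 0L, 0L, 0L, 2L, 2L, 0L),
                        gap_frames = 2, min_len_frames = 2)
  expect_equal(segs$first_frame, c(2L, 8L))
  expect_equal(segs$last_frame, c(4L, 9L))
  expect_equal(segs$drop_index, 1:2)

  expect_equal(nrow(segmentStream(rep(0L, 30), 5, 5)), 0)

  all2 <- segmentStream(rep(2L, 40), 5, 5)   # no gap ever reached
  expect_equal(nrow(all2), 1)
  expect_equal(c(all2$first_frame, all2$last_frame), c(0L, 39L))

  # property: random count streams agree with the independent rle-based oracle
  set.seed(5)
  for (i in 1:50) {
    counts <- sample(0:2, 60, replace = TRUE, prob = c(0.5, 0.2, 0.3))
    gap <- sample(1:5, 1); ml <- sample(1:6, 1)
    got <- segmentStream(counts, gap, ml)
    want <- oracleSegments(counts, gap, ml)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$first_frame[k], want[[k]][1])
      expect_equal(got$last_frame[k], want[[k]][2])
    }
  }
})

test_that("short segments are discarded without consuming a drop index", {
  segs <- segmentStream(c(2L, 0L, 0L, rep(2L, 8L)), gap_frames = 2, min_len_frames = 3)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$drop_index, 1L)
  expect_equal(segs$first_frame, 3L)
})

test_that("left/right assignment orders by x-center with confidence top-2 and nearest-mean fallback", {
  mkdet <- function(cx, conf = 1, cy = 50) {
    data.frame(x_min = cx - 10, y_min = cy - 10, x_max = cx + 10, y_max = cy + 10,
               confidence = conf)
  }
  two <- rbind(mkdet(300), mkdet(100))
  r <- assignSides(two)
  expect_equal(r$assign$embryo_index[order((r$assign$x_min + r$assign$x_max) / 2)],
               c(1L, 2L))

  # lowest-confidence of three is dropped before ordering
  three <- rbind(mkdet(100, 0.9), mkdet(300, 0.8), mkdet(200, 0.3))
  r <- assignSides(three)
  expect_equal(nrow(r$assign), 2)
  cx <- (r$assign$x_min + r$assign$x_max) / 2
  expect_setequal(cx, c(100, 300))

  # tie on x-center breaks to smaller y-center -> left
  tie <- rbind(mkdet(150, cy = 80), mkdet(150, cy = 20))
  r <- assignSides(tie)
  expect_equal(r$assign$embryo_index[r$assign$y_min == 10], 1L)

  # single detection goes to the nearer running mean
  st <- NULL
  r <- assignSides(rbind(mkdet(105), mkdet(290)), st)
  r2 <- assignSides(mkdet(110), r$state)
  expect_equal(r2$assign$embryo_index, 1L)
  r3 <- assignSides(mkdet(280), r2$state)
  expect_equal(r3$assign$embryo_index, 2L)
  # no history defaults to left
  r4 <- assignSides(mkdet(500))
  expect_equal(r4$assign$embryo_index, 1L)
  expect_error(assignSides(mkdet(1)[0, ]), "no detections")
})

test_that("folder layout renders the Day/Patient/Medium/Embryo scheme", {
  expect_equal(layoutPath(3, 1, 1, 1), "Day_3/D3_001/Medium_01/Embryo_01")
  expect_equal(layoutPath(5, 12, 3, 2), "Day_5/D5_012/Medium_03/Embryo_02")
  expect_equal(layoutPath(3, "D3_777", 100, 1), "Day_3/D3_777/Medium_100/Embryo_01")
})

test_that("crops are rounded outward, clamped at edges, and named image_NN.jpg", {
  d <- withr::local_tempdir()
  fr <- flatFrame(120, H = 100, W = 100)
  p <- cropAndSave(fr, c(40, 40, 60, 60), d, seq = 1)
  expect_equal(basename(p), "image_01.jpg")
  px <- embryovision:::readImageArray(p)
  expect_equal(dim(px)[1:2], c(20L, 20L))
  # box past the right edge is clamped, still saved
  p2 <- cropAndSave(fr, c(90, 10, 130, 30), d, seq = 2)
  expect_equal(dim(embryovision:::readImageArray(p2))[1:2], c(20L, 10L))
  # degenerate after clamping: skipped with a warning
  expect_warning(p3 <- cropAndSave(fr, c(99.9, 120, 130, 140), d, seq = 3),
                 "zero-area")
  expect_null(p3)
})

test_that("organize builds one Medium folder per drop and two embryo folders each", {
  gen <- shortGen(seed = 1, n_drops = 3)
  out <- withr::local_tempdir()
  rep <- organizeVideo(gen$video, manifestDetections(gen$manifest),
                       day = 3, patient = 1, out_root = out)
  expect_equal(nrow(rep$segments), 3)
  media <- list.dirs(file.path(out, "Day_3", "D3_001"), recursive = FALSE)
  expect_equal(basename(media), c("Medium_01", "Medium_02", "Medium_03"))
  embryos <- list.dirs(media, recursive = FALSE)
  expect_equal(length(embryos), 6)
  expect_equal(sum(rep$folder_counts), rep$crops_total)
  # every embryo folder is gaplessly numbered from image_01
  for (e in embryos) {
    files <- sort(list.files(e, pattern = "^image_"))
    expect_equal(files, sprintf("image_%02d.jpg", seq_along(files)))
  }
})

test_that("organize on an empty detection stream writes nothing", {
  gen <- shortGen(seed = 2, n_drops = 1)
  m <- videoMeta(gen$video)
  empty <- DetectionSet(frames = seq_len(nFrames(gen$video)) - 1L,
                        width = m$width, height = m$height)
  out <- withr::local_tempdir()
  rep <- organizeVideo(gen$video, empty, day = 3, patient = 1, out_root = out)
  expect_equal(rep$crops_total, 0)
  expect_equal(nrow(rep$segments), 0)
  expect_equal(length(list.files(out, recursive = TRUE)), 0)
})

test_that("left folder always crops the smaller x-center box; rerun is byte-identical", {
  gen <- shortGen(seed = 4, n_drops = 1)
  det <- manifestDetections(gen$manifest)
  b <- manifestBoxes(gen$manifest)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  organizeVideo(gen$video, det, day = 3, patient = 1, out_root = out1)
  organizeVideo(gen$video, det, day = 3, patient = 1, out_root = out2)
  expect_identical(unname(treeDigest(out1)), unname(treeDigest(out2)))
  expect_identical(names(treeDigest(out1)), names(treeDigest(out2)))
  # left/right consistency against the manifest sides
  left <- b[b$side == "left", ]; right <- b[b$side == "right", ]
  expect_true(all((left$x_min + left$x_max) / 2 < (right$x_min + right$x_max) / 2))
  n_frames_with_boxes <- length(unique(b$frame_index))
  counts <- treeDigest(out1)
  expect_equal(length(grep("Embryo_01", names(counts))), n_frames_with_boxes)
  expect_equal(length(grep("Embryo_02", names(counts))), n_frames_with_boxes)
})

test_that("segment boundaries recover the manifest clear phases and report durations", {
  gen <- shortGen(seed = 6, n_drops = 2)
  det <- manifestDetections(gen$manifest, include_ramp = FALSE)
  segs <- segmentStream(det, gap_frames = 5, min_len_frames = 5)
  mf <- manifestFrames(gen$manifest)
  expect_equal(nrow(segs), 2)
  for (d in 1:2) {
    clear <- mf$frame_index[mf$phase == "clear" & mf$drop_index == d]
    expect_lte(abs(segs$first_frame[d] - min(clear)), 5)
    expect_lte(abs(segs$last_frame[d] - max(clear)), 5)
  }
  expect_equal(segmentDuration(79, 154, fps = 5), 15)
})
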
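test_that("Laplacian variance matches the double-loop convolution oracle", {
  # constant image: zero response everywhere
  expect_equal(laplacianVariance(matrix(200, 10, 10)), 0)
  # single bright center pixel on a 5x5 zero image
  g <- matrix(0, 5, 5); g[3, 3] <- 255
  expect_equal(laplacianVariance(g), oracleLapVar(g))
  expect_equal(laplacianVariance(g), 52020)  # {-1020, 255 x4, 0 x20} variance
  # random 8-bit images up to 32x32, relative error <= 1e-6
  set.seed(9)
  for (i in 1:20) {
    H <- sample(3:32, 1); W <- sample(3:32, 1)
    g <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
    a <- laplacianVariance(g); b <- oracleLapVar(g)
    expect_lte(abs(a - b), 1e-6 * max(b, 1))
  }
  expect_error(laplacianVariance(matrix(0, 2, 5)), "too small")
})

test_that("sharpness score decreases under Gaussian blur", {
  checker <- 255 * outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  expect_gt(laplacianVariance(checker), laplacianVariance(blur8(checker, 3)))
  # non-increasing across sigma in {0,1,2,4,8} on textured synthetic crops
  for (seed in 0:2) {
    set.seed(seed)
    tex <- matrix(sample(c(100, 200), 64 * 64, replace = TRUE), 64, 64)
    scores <- vapply(c(0, 1, 2, 4, 8), function(s) laplacianVariance(blur8(tex, s)),
                     numeric(1))
    expect_true(all(diff(scores) <= 0))
  }
})

test_that("classification is the inclusive printed band, exhaustive and exclusive", {
  expect_equal(classifyBlur(1000, 3), "clear")
  expect_equal(classifyBlur(100, 3), "blurry")
  expect_equal(classifyBlur(950, 5), "blurry")
  # inclusive edges
  expect_equal(classifyBlur(500, 3), "clear")
  expect_equal(classifyBlur(2000, 3), "clear")
  expect_equal(classifyBlur(300, 5), "clear")
  expect_equal(classifyBlur(900, 5), "clear")
  expect_error(classifyBlur(1000, 4), "no blur band")
  # every finite score maps to exactly one label
  for (s in c(0, 1, 299, 300, 900.0001, 1e6))
    expect_true(classifyBlur(s, 5) %in% c("clear", "blurry"))
  expect_error(blurBands(day3 = c(10, 5)))
})

test_that("filter_tree keeps clear crops, removes blurry ones, renumbers gaplessly, and is idempotent", {
  gen <- shortGen(seed = 8, n_drops = 1, width = 256, height = 192)
  out <- withr::local_tempdir()
  organizeVideo(gen$video, manifestDetections(gen$manifest),
                day = 3, patient = 1, out_root = out)
  band <- calibrateBand(gen$video, gen$manifest)
  bands <- blurBands(day3 = band)
  mf <- manifestFrames(gen$manifest)
  n_ramp <- sum(mf$phase == "ramp")
  n_clear <- sum(mf$phase == "clear")

  rep <- filterTree(out, day = 3, bands = bands, mode = "delete")
  expect_equal(rep$kept + rep$removed, 2 * (n_ramp + n_clear))
  # kept set = exactly the clear-phase crops (ramp crops are blurred)
  expect_equal(rep$kept, 2 * n_clear)
  expect_equal(rep$removed, 2 * n_ramp)
  for (e in grep("Embryo", names(rep$folders), value = TRUE)) {
    files <- sort(list.files(file.path(out, e), pattern = "^image_"))
    expect_equal(files, sprintf("image_%02d.jpg", seq_along(files)))
  }
  # second pass removes nothing
  rep2 <- filterTree(out, day = 3, bands = bands, mode = "delete")
  expect_equal(rep2$removed, 0)
  expect_equal(rep2$kept, rep$kept)
})

test_that("dry_run leaves the tree untouched and reports like quarantine; quarantine moves files", {
  gen <- shortGen(seed = 9, n_drops = 1, width = 256, height = 192)
  outA <- withr::local_tempdir(); outB <- withr::local_tempdir()
  det <- manifestDetections(gen$manifest)
  organizeVideo(gen$video, det, day = 3, patient = 1, out_root = outA)
  organizeVideo(gen$video, det, day = 3, patient = 1, out_root = outB)
  band <- calibrateBand(gen$video, gen$manifest)
  bands <- blurBands(day3 = band)

  before <- treeDigest(outA)
  dr <- filterTree(outA, day = 3, bands = bands, mode = "dry_run")
  expect_identical(treeDigest(outA), before)

  qr <- filterTree(outB, day = 3, bands = bands, mode = "quarantine")
  expect_equal(dr$kept, qr$kept)
  expect_equal(dr$removed, qr$removed)
  for (nm in names(dr$folders)) {
    expect_equal(dr$folders[[nm]]$score, qr$folders[[nm]]$score)
    expect_equal(dr$folders[[nm]]$label, qr$folders[[nm]]$label)
  }
  # quarantined files are moved, never deleted
  moved <- list.files(outB, pattern = "^image_", recursive = TRUE)
  expect_equal(length(moved), dr$kept + dr$removed)
  expect_equal(sum(grepl("_blurry", list.dirs(outB))), 2)
  # a folder whose images all sit inside the band loses nothing
  wide <- filterTree(outA, day = 3, bands = blurBands(day3 = c(0, 1e9)), mode = "dry_run")
  expect_equal(wide$removed, 0)
})

test_that("filter report JSON round-trips totals", {
  gen <- shortGen(seed = 10, n_drops = 1)
  out <- withr::local_tempdir()
  organizeVideo(gen$video, manifestDetections(gen$manifest, include_ramp = FALSE),
                day = 3, patient = 2, out_root = out)
  rep <- filterTree(out, day = 3, bands = blurBands(day3 = c(0, 1e9)), mode = "dry_run")
  f <- withr::local_tempfile(fileext = ".json")
  writeFilterReport(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$kept, rep$kept)
  expect_equal(back$band, rep$band)
})
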
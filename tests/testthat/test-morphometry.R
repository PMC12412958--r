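test_that("particle quantification counts and filters correctly", {
  # blank image: empty set, warning, not an error
  expect_warning(ps0 <- quantifyParticles(matrix(0.5, 64, 64), 0.1),
                 "constant")
  expect_equal(ps0@count, 0L)
  expect_equal(ps0@totalArea, 0)
  # 10 disjoint ellipses of ~1 um^2 at 0.1 um/px
  fa <- genFaImage(10, meanArea = 1.0, areaCV = 0,
                   spec = GeneratorSpec(seed = 3, pixelSize = 0.1,
                                        noiseSigma = 0))
  ps <- quantifyParticles(fa$image, 0.1)
  expect_equal(ps@count, 10L)
  expect_equal(ps@meanArea, 1.0, tolerance = 0.05)
  # same image, min_area above every particle -> empty
  psBig <- quantifyParticles(fa$image, 0.1, minArea = 2)
  expect_equal(psBig@count, 0L)
})

test_that("particle bookkeeping and invariances hold", {
  fa <- genFaImage(25, meanArea = 0.977,
                   spec = GeneratorSpec(seed = 9, pixelSize = 0.1))
  ps <- quantifyParticles(fa$image, 0.1)
  # mean * count == total exactly
  expect_equal(ps@meanArea * ps@count, ps@totalArea, tolerance = 1e-12)
  # affine intensity rescaling leaves the particles unchanged (noise-free)
  fa2 <- genFaImage(25, meanArea = 0.977,
                    spec = GeneratorSpec(seed = 9, pixelSize = 0.1,
                                         noiseSigma = 0))
  psA <- quantifyParticles(fa2$image, 0.1)
  psB <- quantifyParticles(0.2 + 2.5 * fa2$image, 0.1)
  expect_equal(psA@count, psB@count)
  expect_equal(psA@particles$area_um2, psB@particles$area_um2)
  # count is monotone non-increasing in min_area
  counts <- vapply(c(0, 0.3, 0.6, 1, 2),
                   function(m) quantifyParticles(fa$image, 0.1,
                                                 minArea = m)@count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("shape metrics match analytic disks and ellipses", {
  n <- 256
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  disk <- (rr - 128.5)^2 + (cc - 128.5)^2 <= (20 / 0.2)^2
  sh <- cellShapeMetrics(disk, 0.2)
  expect_equal(sh@spreadingArea, pi * 20^2, tolerance = 0.02)
  expect_lte(sh@aspectRatio, 1.05)
  expect_gte(sh@circularity, 0.95)
  expect_lte(sh@circularity, 1.05)
  # 2:1 ellipse: aspect ratio from second moments
  ell <- ((rr - 128.5) / 100)^2 + ((cc - 128.5) / 50)^2 <= 1
  sh2 <- cellShapeMetrics(ell, 0.2)
  expect_equal(sh2@aspectRatio, 2, tolerance = 0.05)
  expect_error(cellShapeMetrics(matrix(FALSE, 8, 8), 0.2), "16")
})

test_that("rasterized-disk circularity approaches 1 with resolution", {
  circ <- vapply(c(20, 50, 120), function(rpx) {
    n <- 2 * rpx + 21
    rr <- matrix(seq_len(n), n, n); cc <- t(rr)
    ctr <- (n + 1) / 2
    mask <- (rr - ctr)^2 + (cc - ctr)^2 <= rpx^2
    cellShapeMetrics(mask, 0.2)@circularity
  }, numeric(1))
  expect_true(all(abs(circ - 1) < 0.06))
  expect_lt(abs(circ[3] - 1), abs(circ[1] - 1) + 0.005)
})

test_that("filament measurement recovers painted line lengths", {
  # single straight 20 um line -> one path within 5%
  ang <- 30 * pi / 180; L <- 20 / 0.2
  p1 <- c(128 - L / 2 * sin(ang), 128 - L / 2 * cos(ang))
  p2 <- c(128 + L / 2 * sin(ang), 128 + L / 2 * cos(ang))
  img <- lineImage(256, p1, p2)
  fs <- measureFilaments(img, 0.2)
  expect_equal(length(fs@lengths), 1)
  expect_equal(fs@meanLength, 20, tolerance = 0.05)
  # blank image: flagged empty set
  expect_warning(f0 <- measureFilaments(matrix(0.2, 64, 64), 0.2),
                 "constant")
  expect_equal(length(f0@lengths), 0)
  expect_true(is.na(f0@meanLength))
})

test_that("generator round trip recovers the mean filament length", {
  fi <- genFilamentImage(30, 19.1, spec = GeneratorSpec(seed = 5))
  fs <- measureFilaments(fi$image, 0.2)
  expect_equal(length(fs@lengths), 30)
  expect_equal(fs@meanLength, fi$truth$mean_length_um, tolerance = 0.1)
})

test_that("batch morphometry combines particles, shape and filaments", {
  dir <- withr::local_tempdir()
  fa <- genFaImage(20, meanArea = 0.977,
                   spec = GeneratorSpec(seed = 7, pixelSize = 0.1))
  fap <- file.path(dir, "fa.tif")
  writeGrayTIFF(fa$image, fap)
  n <- 256
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  mask <- (rr - 128.5)^2 + (cc - 128.5)^2 <= 100^2
  mp <- file.path(dir, "mask.tif")
  writeGrayTIFF(mask * 1, mp)
  manifest <- data.frame(cell_id = "c1", fa_image_path = fap,
                         cell_mask_path = mp, pixel_size_um = 0.1,
                         stringsAsFactors = FALSE)
  out <- batchMorphometry(manifest)
  expect_equal(out$status, "ok")
  expect_equal(out$fa_count, 20L)
  expect_equal(out$fa_area_per_cell_area,
               out$fa_total_area_um2 / out$spreading_area_um2)
})
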
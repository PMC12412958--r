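test_that("generators are bit-reproducible under a fixed seed", {
  gel <- ElasticSubstrate(1e4, 0.5)
  spec <- GeneratorSpec(seed = 123)
  a <- genPatternPair(gel, 1000, 3, spec = spec)
  b <- genPatternPair(gel, 1000, 3, spec = spec)
  expect_identical(a$pair@reference, b$pair@reference)
  expect_identical(a$pair@deformed, b$pair@deformed)
  f1 <- genForceCurve(3.36, 0.279, 31, spec = spec)
  f2 <- genForceCurve(3.36, 0.279, 31, spec = spec)
  expect_identical(f1$curve@force, f2$curve@force)
  i1 <- genFaImage(15, spec = spec)
  i2 <- genFaImage(15, spec = spec)
  expect_identical(i1$image, i2$image)
  l1 <- genFilamentImage(10, 15, spec = spec)
  l2 <- genFilamentImage(10, 15, spec = spec)
  expect_identical(l1$image, l2$image)
  t1 <- genTracks(5, 1, 0.7, spec = spec)
  t2 <- genTracks(5, 1, 0.7, spec = spec)
  expect_identical(t1$tracks[[3]]@positions, t2$tracks[[3]]@positions)
  s1 <- genTracks(2, 1, 0.7, duration = 60, spec = spec)
  s2 <- genTracks(2, 1, 0.7, duration = 60, spec = spec)
  m1 <- genChannelMovie(s1$tracks, spec = spec)
  m2 <- genChannelMovie(s2$tracks, spec = spec)
  expect_identical(m1$frames[[2]], m2$frames[[2]])
})

test_that("pattern-pair generator respects its energy contract", {
  gel <- ElasticSubstrate(1e4, 0.5)
  # zero energy -> identical areas
  g0 <- genPatternPair(gel, 1000, 0, spec = GeneratorSpec(seed = 1))
  expect_equal(g0$truth$area_final_um2, 1000)
  # requested energy reproduced by the forward formula on truth areas
  g <- genPatternPair(gel, 1000, 4.907, spec = GeneratorSpec(seed = 2))
  u <- contractileEnergy(gel, PatternDeformation(g$truth$area_initial_um2,
                                                 g$truth$area_final_um2))
  expect_equal(as.numeric(u) * 1e12, 4.907, tolerance = 1e-9)
  # infeasible energy refused (beyond the A_f = 0 bound)
  expect_error(genPatternPair(gel, 1000, 1e4, spec = GeneratorSpec(seed = 1)),
               "infeasible")
})

test_that("force-curve generator matches its analytic targets", {
  fc <- genForceCurve(3.36, 0.279, 31, nRandomSteps = 3,
                      spec = GeneratorSpec(seed = 6), dz = 0.002)
  h <- fc$curve@height
  d <- h - fc$truth$contact_um
  f0 <- fc$truth$force0_nN
  # noise-free analytic integral equals the requested work (residual is
  # quadrature error of this check, O(dz^2))
  num <- -pracma::trapz(d[d >= 0], pmin(0, f0[d >= 0])) / 1000
  expect_equal(num, 3.36, tolerance = 1e-4)
  expect_equal(min(f0), -279)
  # force returns to zero exactly at the requested rupture
  expect_equal(max(d[f0 < 0]), 31, tolerance = 0.005)
  # zero targets: flat noisy baseline
  f0c <- genForceCurve(0, 0, 0, spec = GeneratorSpec(seed = 7))
  expect_true(all(f0c$truth$force0_nN == 0))
  # inconsistent triple: energy too large for the requested force/rupture
  expect_error(genForceCurve(20, 0.279, 31, spec = GeneratorSpec(seed = 8)),
               "inconsistent")
  expect_error(genForceCurve(3.36, 0.279, 60, spec = GeneratorSpec(seed = 8)),
               "retract range")
})

test_that("focal-adhesion generator bookkeeping is exact", {
  fa <- genFaImage(0, spec = GeneratorSpec(seed = 1))
  expect_equal(fa$truth$count, 0L)
  expect_true(all(!fa$mask))
  fa2 <- genFaImage(30, meanArea = 0.977,
                    spec = GeneratorSpec(seed = 2, pixelSize = 0.1))
  # painted areas sum exactly to the mask pixel count x pixel area
  expect_identical(sum(fa2$truth$areas_painted_um2),
                   sum(fa2$mask) * 0.1^2)
  expect_equal(length(fa2$truth$areas_painted_um2), 30)
  # requested-mean matching
  expect_equal(mean(fa2$truth$areas_requested_um2), 0.977, tolerance = 1e-12)
  # infeasible packing refused
  expect_error(genFaImage(50, meanArea = 50,
                          spec = GeneratorSpec(seed = 3, pixelSize = 0.1),
                          imageSize = 128), "packing")
})

test_that("filament generator stores exact segment lengths", {
  fi <- genFilamentImage(0, spec = GeneratorSpec(seed = 1))
  expect_equal(length(fi$truth$lengths_um), 0)
  fi2 <- genFilamentImage(12, 19.1, spec = GeneratorSpec(seed = 2))
  expect_equal(length(fi2$truth$lengths_um), 12)
  expect_equal(mean(fi2$truth$lengths_um), 19.1, tolerance = 1e-9)
  lens <- vapply(fi2$truth$endpoints, function(e)
    sqrt(sum((e[2, ] - e[1, ])^2)) * 0.2, numeric(1))
  expect_equal(lens, fi2$truth$lengths_um)
})

test_that("telegraph calibration is monotone and generators respect bounds", {
  cal <- telegraphCalibration(120)
  expect_true(all(diff(cal$mean_cr) <= 0))
  expect_equal(cal$mean_cr[1], 1)
  expect_error(genTracks(3, 1, -0.1, spec = GeneratorSpec(seed = 1)),
               "persistenceTarget")
  # seeded cohort mean persistence within 0.05 of target
  gt <- genTracks(200, 1, 0.5, spec = GeneratorSpec(seed = 11))
  expect_equal(mean(gt$truth$realized_persistence), 0.5, tolerance = 0.1)
})

test_that("channel movie generator handles empty input", {
  mv <- genChannelMovie(list(), spec = GeneratorSpec(seed = 5))
  expect_equal(length(mv$truth), 0)
  expect_true(all(vapply(mv$frames, function(f) max(f) < 0.5, logical(1))))
})
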
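test_that("baseline correction removes constant offsets and linear drift", {
  h <- seq(0, 50, by = 0.01)
  flat <- ForceDistanceCurve(h, rep(5, length(h)), "retract")
  corr <- baselineCorrect(flat)
  expect_equal(max(abs(corr@force)), 0, tolerance = 1e-9)
  drift <- ForceDistanceCurve(h, 2 + 0.3 * h, "retract")
  cd <- baselineCorrect(drift)
  tail_idx <- h > 40
  expect_lt(abs(mean(cd@force[tail_idx])), 1e-9)
  expect_true(isTRUE(cd@metadata$baselineCorrected))
  short <- ForceDistanceCurve(1:5, rnorm(5), "retract")
  expect_error(baselineCorrect(short), "fewer than 10")
  expect_error(baselineCorrect(flat, tailFraction = 0.7), "tailFraction")
})

test_that("contact point finds the compressive zero crossing", {
  # contact constructed at height 0.5
  cv <- piecewiseCurve(rbind(c(0, 0), c(5, -100), c(10, 0), c(45, 0)),
                       contact = 0.5)
  cc <- baselineCorrect(cv)
  expect_equal(contactPoint(cc), 0.5, tolerance = 0.02)
  # pure-baseline curve falls back to the first sample with a warning
  h <- seq(0, 50, by = 0.01)
  withr::with_seed(1, base <- ForceDistanceCurve(h, rnorm(length(h), 0, 2),
                                                 "retract"))
  cb <- baselineCorrect(base)
  expect_warning(hc <- contactPoint(cb), "never compressive")
  expect_equal(hc, 0)
})

test_that("triangular well metrics match hand arithmetic", {
  # depth 100 nN, base 10 um: energy = 0.5 * 100 nN * 10 um = 0.5 pJ
  cv <- piecewiseCurve(rbind(c(0, 0), c(5, -100), c(10, 0), c(45, 0)),
                       contact = 0.5)
  cc <- baselineCorrect(cv)
  expect_equal(adhesionEnergy(cc), 0.5, tolerance = 0.005)
  expect_equal(adhesionForce(cc, smoothN = 1), 0.1)
  expect_equal(adhesionForce(cc), 0.1, tolerance = 0.01)
  # last above-noise excursion ends where the triangle returns to zero
  expect_equal(ruptureLength(cc), 10, tolerance = 0.05)
})

test_that("a constructed late excursion sets the rupture length", {
  nodes <- rbind(c(0, 0), c(3, -80), c(6, -20), c(25, -20), c(31, -20),
                 c(31.001, 0), c(49, 0))
  cv <- piecewiseCurve(nodes, contact = 0.5)
  cc <- baselineCorrect(cv)
  expect_equal(ruptureLength(cc), 31, tolerance = 0.05)
  # relaxing the noise tolerance never shrinks the rupture length
  r3 <- ruptureLength(cc, noiseK = 3)
  r2 <- ruptureLength(cc, noiseK = 2)
  r5 <- ruptureLength(cc, noiseK = 5)
  expect_gte(r2, r3)
  expect_gte(r3, r5)
})

test_that("all metrics vanish on a flat zero curve", {
  h <- seq(0, 50, by = 0.01)
  zero <- baselineCorrect(ForceDistanceCurve(h, numeric(length(h)),
                                             "retract"))
  expect_identical(adhesionForce(zero), 0)
  expect_identical(suppressWarnings(adhesionEnergy(zero)), 0)
  suppressWarnings({
    expect_identical(ruptureLength(zero), 0)
    expect_equal(nrow(detectSteps(zero, minJump = 1)), 0)
  })
})

test_that("step detection finds constructed staircase jumps", {
  # staircase: four 50 nN upward jumps at 12, 18, 24, 30 um
  nodes <- rbind(c(0, 0), c(2, -200), c(11.99, -200),
                 c(12.01, -150), c(17.99, -150), c(18.01, -100),
                 c(23.99, -100), c(24.01, -50), c(29.99, -50),
                 c(30.01, 0), c(49, 0))
  cv <- baselineCorrect(piecewiseCurve(nodes, contact = 0.5))
  steps <- detectSteps(cv, minJump = 25)
  expect_equal(nrow(steps), 4)
  expect_equal(steps$distance_um, c(12, 18, 24, 30), tolerance = 0.05)
  expect_equal(steps$jump_nN, rep(50, 4), tolerance = 0.1)
  # smooth single well: no steps above 3x noise
  well <- piecewiseCurve(rbind(c(0, 0), c(5, -100), c(10, 0), c(45, 0)),
                         contact = 0.5)
  wellN <- withr::with_seed(5, initialize(
    well, force = well@force + rnorm(length(well@force), 0, 2)))
  wc <- baselineCorrect(wellN)
  expect_equal(nrow(detectSteps(wc, minJump = 3 * wc@metadata$baselineNoise)),
               0)
})

test_that("adhesion energy matches a fine Riemann-sum oracle", {
  fc <- genForceCurve(3.36, 0.279, 31, spec = GeneratorSpec(seed = 2))
  cc <- baselineCorrect(fc$curve)
  E <- adhesionEnergy(cc)
  # brute-force Riemann sum on a 10x-refined interpolation over the same
  # adhesive region (contact to rupture end)
  hc <- contactPoint(cc)
  rl <- ruptureLength(cc)
  ret <- cellmech:::.retract(cc)
  d <- ret$height - hc
  keep <- d >= 0 & d <= rl
  fine <- seq(min(d[keep]), max(d[keep]), length.out = 10 * sum(keep))
  fi <- approx(d[keep], pmax(0, -ret$force[keep]), xout = fine)$y
  riemann <- sum(fi[-1] + fi[-length(fi)]) / 2 * diff(fine[1:2]) / 1000
  expect_equal(E, riemann, tolerance = 0.005)
})

test_that("adhesion force is stable under 2x resampling", {
  fc <- genForceCurve(3.36, 0.279, 31, spec = GeneratorSpec(seed = 3))
  cc <- baselineCorrect(fc$curve)
  f1 <- adhesionForce(cc)
  h2 <- seq(0, 50, by = 0.005)
  f2curve <- ForceDistanceCurve(h2, approx(cc@height, cc@force, xout = h2)$y,
                                "retract")
  md <- f2curve@metadata
  md$baselineCorrected <- TRUE
  md$baselineNoise <- cc@metadata$baselineNoise
  f2 <- adhesionForce(initialize(f2curve, metadata = md))
  expect_equal(f2, f1, tolerance = 0.01)
})

test_that("generator round trip recovers energy, force and rupture", {
  fc <- genForceCurve(3.36, 0.279, 31, nRandomSteps = 3,
                      spec = GeneratorSpec(seed = 1))
  m <- adhesionMetrics(fc$curve)
  expect_equal(m@adhesionEnergy, 3.36, tolerance = 0.01)
  expect_equal(m@adhesionForce, 0.279, tolerance = 0.01)
  expect_equal(m@ruptureLength, 31, tolerance = 0.5 / 31)
  expect_equal(m@nSteps, fc$truth$n_steps)
})

test_that("seeded step recall is high for well-resolved jumps", {
  hits <- 0; total <- 0
  for (s in 1:8) {
    fc <- genForceCurve(3.36, 0.279, 31, nRandomSteps = 3,
                        spec = GeneratorSpec(seed = 100 + s))
    cc <- baselineCorrect(fc$curve)
    noise <- cc@metadata$baselineNoise
    truthPos <- fc$truth$step_positions_um[fc$truth$step_jumps_nN >=
                                             5 * noise]
    steps <- detectSteps(cc)
    total <- total + length(truthPos)
    hits <- hits + sum(vapply(truthPos, function(p)
      any(abs(steps$distance_um - p) < 0.5), logical(1)))
  }
  expect_gte(hits / total, 0.9)
})

test_that("curve TSV round trip and batch metrics work", {
  dir <- withr::local_tempdir()
  fc <- genForceCurve(3.36, 0.279, 31, spec = GeneratorSpec(seed = 4))
  p1 <- file.path(dir, "cell1.tsv")
  writeForceCurve(fc$curve, p1)
  back <- readForceCurve(p1)
  expect_equal(back@height, fc$curve@height)
  expect_equal(back@force, fc$curve@force, tolerance = 1e-6)
  writeLines("height_um\tbogus", file.path(dir, "bad.tsv"))
  out <- batchScfs(dir)
  expect_equal(nrow(out), 2)
  ok <- out[out$status == "ok", ]
  expect_equal(nrow(ok), 1)
  expect_equal(ok$adhesion_energy_pJ, 3.36, tolerance = 0.02)
})
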
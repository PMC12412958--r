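test_that("sigma prefactor has the derived grouping and domain", {
  # sub-expressions at sigma = 0.5: (1-s)(1+s) = 0.75, (2(1-s)+s)^2 - s^2 = 2
  s <- 0.5
  expect_equal((1 - s) * (1 + s), 0.75)
  expect_equal((2 * (1 - s) + s)^2 - s^2, 2)
  # grouping fixed by the elastostatic derivation: g = 4 / (1 + sigma)
  for (s in seq(0, 0.5, by = 0.05)) {
    g <- sigmaPrefactor(s)
    expect_equal(g, ((2 * (1 - s) + s)^2 - s^2) / ((1 - s) * (1 + s)))
    expect_equal(g, 4 / (1 + s))
    expect_gt(g, 0)
  }
  expect_equal(sigmaPrefactor(0.5), 8 / 3)
  expect_equal(sigmaPrefactor(0), 4)
  expect_error(sigmaPrefactor(-0.01), "0, 0.5")
  expect_error(sigmaPrefactor(0.6), "0, 0.5")
})

test_that("contractile energy obeys its exact scaling laws", {
  gel <- ElasticSubstrate(1e4, 0.5)
  # zero deformation -> exactly zero for any substrate
  for (E in c(1e3, 1e4, 3e4)) for (s in c(0, 0.3, 0.5)) {
    u <- contractileEnergy(ElasticSubstrate(E, s), PatternDeformation(800, 800))
    expect_identical(as.numeric(u), 0)
  }
  def <- PatternDeformation(1000, 700)
  u1 <- as.numeric(contractileEnergy(gel, def))
  # exactly linear in the Young's modulus
  u2 <- as.numeric(contractileEnergy(ElasticSubstrate(2e4, 0.5), def))
  expect_identical(u2, 2 * u1)
  # areas scaled by lambda^2 -> energy scaled by lambda^3
  lam <- 1.7
  def2 <- PatternDeformation(1000 * lam^2, 700 * lam^2)
  expect_equal(as.numeric(contractileEnergy(gel, def2)), lam^3 * u1,
               tolerance = 1e-12)
})

test_that("expansion is flagged by default and rejectable", {
  gel <- ElasticSubstrate(1e4, 0.5)
  u <- contractileEnergy(gel, PatternDeformation(900, 1000))
  expect_lt(as.numeric(u), 0)
  expect_true(attr(u, "expansion"))
  u2 <- contractileEnergy(gel, PatternDeformation(1000, 900))
  expect_false(attr(u2, "expansion"))
  expect_error(
    contractileEnergy(gel, PatternDeformation(900, 1000),
                      allowExpansion = FALSE), "expansion")
})

test_that("energy inversion is the exact right inverse", {
  gel <- ElasticSubstrate(1e4, 0.5)
  ai <- 1e-9
  expect_equal(invertEnergyToFinalArea(gel, ai, 0), ai)
  bound <- as.numeric(contractileEnergy(
    gel, new("PatternDeformation", initialArea = ai, finalArea = 1e-30)))
  withr::with_seed(42, {
    for (x in runif(100, 0, bound * 0.999)) {
      af <- invertEnergyToFinalArea(gel, ai, x)
      u <- as.numeric(contractileEnergy(
        gel, PatternDeformation(ai, af, unit = "m2")))
      expect_equal(u, x, tolerance = 1e-9)
    }
  })
  expect_error(invertEnergyToFinalArea(gel, ai, bound * 1.01), "infeasible")
  expect_error(invertEnergyToFinalArea(gel, ai, -1), "non-negative")
})

test_that("the numerical radial solution reproduces u = Ar + B/r", {
  # zero boundary data -> identically zero
  f0 <- navierRadialSolution(0.5, 1e-5, 1e-4, 0, 0, nPoints = 128)
  expect_true(all(f0@displacement == 0))
  # boundary data from u = c r -> linear field recovered
  a <- 1e-5; R <- 1e-4; cc <- 0.02
  flin <- navierRadialSolution(0.3, a, R, cc * a, cc * R, nPoints = 512)
  expect_equal(flin@displacement, cc * flin@radii, tolerance = 1e-10)
  # generic boundary data vs direct 2x2 solve of the analytic family:
  # the exact scheme on the log grid reproduces the family to rounding,
  # the uniform-grid central differences converge at second order
  AB <- solve(rbind(c(a, 1 / a), c(R, 1 / R)), c(2e-6, -1e-7))
  fld <- navierRadialSolution(0.5, a, R, 2e-6, -1e-7, nPoints = 4096)
  ana <- AB[1] * fld@radii + AB[2] / fld@radii
  expect_lt(max(abs(fld@displacement - ana)) / max(abs(ana)), 1e-8)
  flu <- navierRadialSolution(0.5, a, R, 2e-6, -1e-7, nPoints = 4096,
                              grid = "uniform")
  anu <- AB[1] * flu@radii + AB[2] / flu@radii
  expect_lt(max(abs(flu@displacement - anu)) / max(abs(anu)), 1e-5)
  expect_error(navierRadialSolution(0.5, 1e-4, 1e-5, 0, 0), "innerRadius")
  expect_error(navierRadialSolution(0.5, 1e-5, 1e-4, 0, 0, nPoints = 8),
               "nPoints")
})

test_that("strain-energy quadrature matches closed forms and converges", {
  gel <- ElasticSubstrate(1e4, 0.3)
  a <- 1e-5; R <- 5e-5
  # zero field -> zero energy
  f0 <- navierRadialSolution(0.3, a, R, 0, 0, nPoints = 256)
  expect_equal(strainEnergyQuadrature(f0, gel), 0)
  # u = c r on a constant-thickness sheet: err = ett = c,
  # w = E c^2 / (1 - s), U = w * h * pi (R^2 - a^2)
  cc <- 0.01; h <- 2e-6; s <- 0.3
  flin <- navierRadialSolution(s, a, R, cc * a, cc * R, nPoints = 2048,
                               grid = "uniform")
  U <- strainEnergyQuadrature(flin, gel, "plane_stress_sheet",
                              sheetThickness = h)
  Uana <- 1e4 * cc^2 / (1 - s) * h * pi * (R^2 - a^2)
  expect_equal(U, Uana, tolerance = 1e-6)
  # second-order convergence on a generic field (observed order >= 1.8)
  en <- vapply(c(128, 256, 512), function(n) {
    fld <- navierRadialSolution(s, a, R, 2e-6, 0, nPoints = n,
                                grid = "uniform")
    strainEnergyQuadrature(fld, gel)
  }, numeric(1))
  # Richardson reference from the two finest grids assuming order 2
  ref <- en[3] + (en[3] - en[2]) / 3
  order <- log2(abs(en[1] - ref) / abs(en[2] - ref))
  expect_gte(order, 1.8)
  # mismatched Poisson ratio is refused
  expect_error(strainEnergyQuadrature(flin, ElasticSubstrate(1e4, 0.5)),
               "disagree")
})

test_that("closed-form energy agrees with the quadrature oracle", {
  # dual route: contractile energy vs Navier solution + strain-energy
  # quadrature (half-space depth scaling, cutoff extrapolated to infinity)
  for (s in c(0, 0.25, 0.5)) {
    gel <- ElasticSubstrate(1e4, s)
    for (areas in list(c(1000, 830), c(1000, 976.5), c(500, 200))) {
      def <- PatternDeformation(areas[1], areas[2])
      closed <- as.numeric(contractileEnergy(gel, def))
      oracle <- contractileEnergyOracle(gel, def, outerFactor = 32,
                                        nPoints = 1024)
      expect_equal(oracle, closed, tolerance = 1e-3)
    }
  }
})
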
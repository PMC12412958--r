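#' @include AllClasses.R AllGenerics.R
NULL

# Geometric depth constant of the half-space scaling model: the effective
# depth of substrate recruited by a surface deformation of lateral scale r is
# kappa * r. Jointly with the closed form's 3*sqrt(pi)/32 this makes the
# quadrature route reproduce the closed form exactly in the infinite-substrate
# limit (see the methods vignette for the derivation).
.kDepth <- 3 * pi / 16

#' Dimensionless Poisson-ratio prefactor of the contractile-energy formula
#'
#' The contractile energy of a cell contracting a circular micropattern on an
#' elastic substrate is
#' \deqn{U = g(\sigma)\, E \, \frac{3\sqrt{\pi}}{32} \left(A_i^{3/2} - A_f^{3/2}\right)}
#' where \eqn{g(\sigma)} combines the sub-expressions
#' \eqn{(1-\sigma)(1+\sigma)} and \eqn{(2(1-\sigma)+\sigma)^2 - \sigma^2}.
#' The grouping implemented here,
#' \deqn{g(\sigma) = \frac{(2(1-\sigma)+\sigma)^2 - \sigma^2}{(1-\sigma)(1+\sigma)} = \frac{4}{1+\sigma},}
#' is the one consistent with the underlying elastostatics: the substrate
#' deformation far from the pattern is shear-dominated, so the stored energy
#' scales with the shear modulus \eqn{E/(2(1+\sigma))}. It is validated
#' against the numerical quadrature oracle
#' (\code{\link{contractileEnergyOracle}}).
#'
#' @param poissonRatio Poisson ratio in [0, 0.5].
#' @return The dimensionless prefactor (finite, positive, continuous on the
#'   valid range). g(0.5) = 8/3, g(0) = 4.
#' @examples
#' sigmaPrefactor(0.5)
#' @export
sigmaPrefactor <- function(poissonRatio) {
  if (!is.numeric(poissonRatio) || any(!is.finite(poissonRatio)))
    stop("poissonRatio must be finite numeric")
  if (any(poissonRatio < 0) || any(poissonRatio > 0.5))
    stop("poissonRatio must lie in [0, 0.5]")
  den <- (1 - poissonRatio) * (1 + poissonRatio)
  if (any(den <= .Machine$double.eps))
    stop("prefactor denominator vanishes at this poissonRatio")
  ((2 * (1 - poissonRatio) + poissonRatio)^2 - poissonRatio^2) / den
}

#' Contractile energy from a pattern deformation
#'
#' Closed-form elastic energy a cell stores in the substrate by contracting a
#' circular micropattern from area \eqn{A_i} to \eqn{A_f}:
#' \deqn{U = g(\sigma)\,E\,\frac{3\sqrt{\pi}}{32}\,(A_i^{3/2} - A_f^{3/2})}
#' with \eqn{g(\sigma)} from \code{\link{sigmaPrefactor}}. Exactly zero for
#' an undeformed pattern, linear in the Young's modulus, and homogeneous of
#' degree 3/2 in the areas (scaling both areas by \eqn{\lambda^2} scales the
#' energy by \eqn{\lambda^3}).
#'
#' @param substrate An \linkS4class{ElasticSubstrate}.
#' @param deformation A \linkS4class{PatternDeformation} (areas in m^2).
#' @param allowExpansion If TRUE (default) a final area larger than the
#'   initial area yields a negative energy flagged via the
#'   \code{"expansion"} attribute (segmentation jitter can push A_f above
#'   A_i); if FALSE it is an error.
#' @return Energy in joules, with attribute \code{expansion} (logical).
#' @examples
#' gel <- ElasticSubstrate(1e4, 0.5)
#' contractileEnergy(gel, PatternDeformation(1000, 900))  # ~ pJ scale
#' @export
setMethod("contractileEnergy",
  signature(substrate = "ElasticSubstrate", deformation = "PatternDeformation"),
  function(substrate, deformation, allowExpansion = TRUE) {
    validObject(substrate); validObject(deformation)
    ai <- deformation@initialArea
    af <- deformation@finalArea
    if (af > ai && !allowExpansion)
      stop("final_area exceeds initial_area (expansion) and allowExpansion = FALSE")
    u <- sigmaPrefactor(substrate@poissonRatio) * substrate@youngModulus *
      (3 * sqrt(pi) / 32) * (ai^1.5 - af^1.5)
    attr(u, "expansion") <- af > ai
    u
  })

#' Invert the contractile-energy formula for the final area
#'
#' Closed-form right inverse of \code{\link{contractileEnergy}} in its final
#' area argument: given the substrate, the initial area and a target energy,
#' returns the final area that produces that energy. Used by the synthetic
#' pattern-pair generator.
#'
#' @param substrate An \linkS4class{ElasticSubstrate}.
#' @param initialArea Initial pattern area in m^2.
#' @param targetEnergy Target energy in J; must satisfy
#'   \code{0 <= targetEnergy <= contractileEnergy at A_f = 0}.
#' @return Final area in m^2.
#' @export
invertEnergyToFinalArea <- function(substrate, initialArea, targetEnergy) {
  validObject(substrate)
  if (initialArea <= 0) stop("initialArea must be positive")
  if (targetEnergy < 0) stop("targetEnergy must be non-negative")
  k <- sigmaPrefactor(substrate@poissonRatio) * substrate@youngModulus *
    (3 * sqrt(pi) / 32)
  bound <- k * initialArea^1.5
  if (targetEnergy > bound)
    stop(sprintf(
      "infeasible targetEnergy: %.4g J exceeds the A_f = 0 bound %.4g J",
      targetEnergy, bound))
  (initialArea^1.5 - targetEnergy / k)^(2 / 3)
}

#' Numerical solution of the radial elastostatic equilibrium equation
#'
#' Solves the axisymmetric Navier equilibrium equation
#' \eqn{(1-2\sigma)\Delta u + \nabla(\nabla \cdot u) = 0} for a purely radial
#' displacement field on the annulus [innerRadius, outerRadius] with
#' prescribed boundary displacements. For a radial field the equation reduces
#' to \eqn{u'' + u'/r - u/r^2 = 0} independently of \eqn{\sigma}, whose
#' solutions form the analytic family \eqn{u(r) = Ar + B/r}; the
#' finite-difference solution reproduces that family to high accuracy and
#' serves as the independent oracle for the closed-form energy.
#'
#' On the default log-spaced grid (in \eqn{t = \log r} the equation becomes
#' the constant-coefficient \eqn{u_{tt} - u = 0}) the three-point scheme
#' uses the exact discrete operator \eqn{u_{i-1} - 2\cosh(h)u_i + u_{i+1}},
#' whose characteristic roots are \eqn{e^{\pm h}} -- precisely the sampled
#' analytic family -- so the solution is exact to rounding; the uniform
#' grid uses standard second-order central differences. Both are solved
#' with the Thomas algorithm.
#'
#' @param poissonRatio Poisson ratio (recorded in the field; the radial
#'   reduction is sigma-independent).
#' @param innerRadius,outerRadius Annulus bounds in m, 0 < inner < outer.
#' @param innerDisplacement,outerDisplacement Boundary displacements in m.
#' @param nPoints Number of grid points (>= 16; default 2048).
#' @param grid `"log"` (default) or `"uniform"` spacing.
#' @return A \linkS4class{RadialDisplacementField}.
#' @examples
#' f <- navierRadialSolution(0.5, 1e-5, 1e-4, 1e-6, 0, nPoints = 64)
#' @export
navierRadialSolution <- function(poissonRatio, innerRadius, outerRadius,
                                 innerDisplacement, outerDisplacement,
                                 nPoints = 2048, grid = c("log", "uniform")) {
  grid <- match.arg(grid)
  if (!(innerRadius > 0 && outerRadius > innerRadius))
    stop("need 0 < innerRadius < outerRadius")
  if (nPoints < 16) stop("nPoints must be >= 16")
  n <- as.integer(nPoints)
  if (grid == "log") {
    t <- seq(log(innerRadius), log(outerRadius), length.out = n)
    r <- exp(t)
    h <- t[2] - t[1]
    # u_tt - u = 0  ->  u[i-1] - 2*cosh(h) u[i] + u[i+1] = 0 (exact scheme)
    a <- rep(1, n - 2)              # sub-diagonal
    b <- rep(-2 * cosh(h), n - 2)   # diagonal
    cc <- rep(1, n - 2)             # super-diagonal
  } else {
    r <- seq(innerRadius, outerRadius, length.out = n)
    h <- r[2] - r[1]
    ri <- r[2:(n - 1)]
    # u'' + u'/r - u/r^2 = 0, central differences
    a <- 1 / h^2 - 1 / (2 * h * ri)
    b <- -2 / h^2 - 1 / ri^2
    cc <- 1 / h^2 + 1 / (2 * h * ri)
    a <- a[] ; cc <- cc[]
  }
  # Thomas algorithm for the interior unknowns u[2..n-1]
  m <- n - 2
  d <- numeric(m)
  d[1] <- d[1] - a[1] * innerDisplacement
  d[m] <- d[m] - cc[m] * outerDisplacement
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
  if (m > 1) for (i in 2:m) {
    denom <- b[i] - a[i] * cp[i - 1]
    cp[i] <- cc[i] / denom
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / denom
  }
  u <- numeric(m)
  u[m] <- dp[m]
  if (m > 1) for (i in (m - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  new("RadialDisplacementField", radii = r,
      displacement = c(innerDisplacement, u, outerDisplacement),
      poissonRatio = as.numeric(poissonRatio))
}

#' Elastic strain energy of a radial displacement field by quadrature
#'
#' Integrates the plane-stress elastic energy density of an axisymmetric
#' radial field over its annulus by composite trapezoidal quadrature:
#' \deqn{U = \int 2\pi r\, h(r)\, w(r)\, dr, \quad
#'   w = \frac{E}{2(1-\sigma^2)}\left(\varepsilon_{rr}^2 +
#'   \varepsilon_{\theta\theta}^2 +
#'   2\sigma\,\varepsilon_{rr}\varepsilon_{\theta\theta}\right)}
#' with \eqn{\varepsilon_{rr} = u'(r)} (central differences) and
#' \eqn{\varepsilon_{\theta\theta} = u/r}. The thickness model fixes the
#' effective depth \eqn{h(r)}: `"half_space_scaling"` (default) uses
#' \eqn{h = (3\pi/16)\,r}, the depth-recruitment scaling of a thick
#' substrate, under which the quadrature reproduces the closed-form
#' contractile energy; `"plane_stress_sheet"` uses a constant sheet
#' thickness.
#'
#' @param field A \linkS4class{RadialDisplacementField}.
#' @param substrate An \linkS4class{ElasticSubstrate}; its Poisson ratio must
#'   match the field's.
#' @param thicknessModel `"half_space_scaling"` or `"plane_stress_sheet"`.
#' @param sheetThickness Sheet thickness in m (plane_stress_sheet only;
#'   default 1e-6).
#' @param depthFactor Depth proportionality constant for half_space_scaling
#'   (default 3*pi/16).
#' @return Energy in joules (non-negative). Converges at second order in the
#'   grid spacing.
#' @export
strainEnergyQuadrature <- function(field, substrate,
                                   thicknessModel = c("half_space_scaling",
                                                      "plane_stress_sheet"),
                                   sheetThickness = 1e-6,
                                   depthFactor = .kDepth) {
  thicknessModel <- match.arg(thicknessModel)
  validObject(field); validObject(substrate)
  if (abs(field@poissonRatio - substrate@poissonRatio) > 1e-12)
    stop("Poisson ratio of field and substrate disagree")
  r <- field@radii
  u <- field@displacement
  s <- substrate@poissonRatio
  err <- pracma::gradient(u, r)     # second-order, handles non-uniform grids
  ett <- u / r
  w <- substrate@youngModulus / (2 * (1 - s^2)) *
    (err^2 + ett^2 + 2 * s * err * ett)
  h <- switch(thicknessModel,
              half_space_scaling = depthFactor * r,
              plane_stress_sheet = rep(sheetThickness, length(r)))
  pracma::trapz(r, 2 * pi * r * h * w)
}

#' Quadrature oracle for the contractile energy
#'
#' Independent numerical route to the contractile energy: the contraction is
#' treated as a family of self-similar states, one per pattern radius
#' \eqn{s}; each state's substrate field is obtained by
#' \code{\link{navierRadialSolution}} on the annulus
#' \eqn{[s, f\,s]} with edge displacement proportional to \eqn{s} and zero
#' far-field displacement, its energy by
#' \code{\link{strainEnergyQuadrature}} under half-space depth scaling, and
#' the contractile energy is the difference of the state energies at
#' \eqn{r_i} and \eqn{r_f}. With \code{extrapolate = TRUE} the outer cutoff
#' is pushed to the infinite-substrate limit by evaluating at cutoff factors
#' \{f, 2f, 4f\} and extrapolating quadratically in 1/f (the truncated
#' outer field contributes an O(1/f) energy deficit).
#'
#' @param substrate An \linkS4class{ElasticSubstrate}.
#' @param deformation A \linkS4class{PatternDeformation}.
#' @param outerFactor Outer cutoff radius as a multiple of the pattern
#'   radius (default 10).
#' @param nPoints Grid points per solve (default 2048).
#' @param extrapolate Extrapolate the cutoff to infinity (default TRUE; use
#'   FALSE for the raw finite-annulus energy).
#' @return Energy in joules.
#' @examples
#' gel <- ElasticSubstrate(1e4, 0.5)
#' def <- PatternDeformation(1000, 900)
#' oracle <- contractileEnergyOracle(gel, def, outerFactor = 16, nPoints = 512)
#' closed <- contractileEnergy(gel, def)
#' abs(oracle - closed) / closed   # ~1e-4 or better
#' @export
contractileEnergyOracle <- function(substrate, deformation, outerFactor = 10,
                                    nPoints = 2048, extrapolate = TRUE) {
  validObject(substrate); validObject(deformation)
  stateEnergy <- function(s, f) {
    fld <- navierRadialSolution(substrate@poissonRatio, s, f * s,
                                innerDisplacement = s,
                                outerDisplacement = 0, nPoints = nPoints)
    strainEnergyQuadrature(fld, substrate, "half_space_scaling")
  }
  energyAt <- function(f)
    stateEnergy(initialRadius(deformation), f) -
      stateEnergy(finalRadius(deformation), f)
  if (!extrapolate) return(energyAt(outerFactor))
  fs <- outerFactor * c(1, 2, 4)
  q <- vapply(fs, energyAt, numeric(1))
  x <- 1 / fs
  # quadratic fit in 1/f; intercept = infinite-substrate limit
  X <- cbind(1, x, x^2)
  unname(drop(solve(t(X) %*% X, t(X) %*% q))[1])
}
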
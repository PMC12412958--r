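#' @import methods
NULL

#' Elastic substrate
#'
#' Linear-elastic description of the gel a cell deforms: Young's modulus
#' \eqn{E} (Pa) and Poisson ratio \eqn{\sigma}. The contractility assay uses
#' polyacrylamide gels around 10 kPa, treated as incompressible
#' (\eqn{\sigma = 0.5}).
#'
#' @slot youngModulus Young's modulus in Pa (> 0).
#' @slot poissonRatio Poisson ratio, in [0, 0.5].
#' @export
setClass("ElasticSubstrate",
  representation(youngModulus = "numeric", poissonRatio = "numeric"),
  prototype(youngModulus = 1e4, poissonRatio = 0.5))

setValidity("ElasticSubstrate", function(object) {
  msg <- NULL
  if (length(object@youngModulus) != 1 || !is.finite(object@youngModulus) ||
      object@youngModulus <= 0)
    msg <- c(msg, "youngModulus must be a single positive finite value (Pa)")
  if (length(object@poissonRatio) != 1 || !is.finite(object@poissonRatio) ||
      object@poissonRatio < 0 || object@poissonRatio > 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5]")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ElasticSubstrate
#'
#' @param youngModulus Young's modulus in Pa (default 1e4, i.e. 10 kPa).
#' @param poissonRatio Poisson ratio (default 0.5, incompressible).
#' @return An \linkS4class{ElasticSubstrate}.
#' @examples
#' gel <- ElasticSubstrate(youngModulus = 1e4, poissonRatio = 0.5)
#' @export
ElasticSubstrate <- function(youngModulus = 1e4, poissonRatio = 0.5) {
  new("ElasticSubstrate", youngModulus = as.numeric(youngModulus),
      poissonRatio = as.numeric(poissonRatio))
}

#' Micropattern deformation
#'
#' Initial and final areas of a circular micropattern contracted by an
#' adherent cell. Areas are stored in m^2; the constructor accepts um^2
#' (the reporting unit) or m^2. The equivalent radii
#' \eqn{r = \sqrt{A/\pi}} are derived on demand.
#'
#' @slot initialArea Initial pattern area in m^2.
#' @slot finalArea Final (deformed) pattern area in m^2.
#' @export
setClass("PatternDeformation",
  representation(initialArea = "numeric", finalArea = "numeric"))

setValidity("PatternDeformation", function(object) {
  msg <- NULL
  if (length(object@initialArea) != 1 || !is.finite(object@initialArea) ||
      object@initialArea <= 0)
    msg <- c(msg, "initialArea must be a single positive finite area (m^2)")
  if (length(object@finalArea) != 1 || !is.finite(object@finalArea) ||
      object@finalArea <= 0)
    msg <- c(msg, "finalArea must be a single positive finite area (m^2)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PatternDeformation
#'
#' @param initialArea,finalArea Pattern areas before and after deformation.
#' @param unit Unit of the supplied areas, `"um2"` (default) or `"m2"`.
#' @return A \linkS4class{PatternDeformation} (areas stored in m^2).
#' @examples
#' PatternDeformation(1000, 976.5)  # um^2
#' @export
PatternDeformation <- function(initialArea, finalArea, unit = c("um2", "m2")) {
  unit <- match.arg(unit)
  k <- if (unit == "um2") 1e-12 else 1
  new("PatternDeformation", initialArea = as.numeric(initialArea) * k,
      finalArea = as.numeric(finalArea) * k)
}

#' Radial displacement field
#'
#' A sampled axisymmetric radial displacement field u(r) of the substrate
#' surface, as produced by \code{\link{navierRadialSolution}}. Radii are
#' strictly increasing and positive; units are meters.
#'
#' @slot radii Radial sample positions (m), strictly increasing, > 0.
#' @slot displacement Radial displacement u(r) at each sample (m).
#' @slot poissonRatio Poisson ratio the field was solved under.
#' @export
setClass("RadialDisplacementField",
  representation(radii = "numeric", displacement = "numeric",
                 poissonRatio = "numeric"))

setValidity("RadialDisplacementField", function(object) {
  msg <- NULL
  if (length(object@radii) != length(object@displacement))
    msg <- c(msg, "radii and displacement must have equal length")
  if (length(object@radii) < 2 || any(!is.finite(object@radii)) ||
      any(object@radii <= 0) || any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be positive, finite and strictly increasing")
  if (length(object@poissonRatio) != 1 || object@poissonRatio < 0 ||
      object@poissonRatio > 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5]")
  if (is.null(msg)) TRUE else msg
})

#' Reference/deformed micropattern image pair
#'
#' Two grayscale images of the same fluorescent micropattern: the reference
#' (initial outline) and the deformed state, with the common pixel size.
#' Images are numeric matrices indexed [row, col], origin top-left,
#' pixel-center coordinate convention.
#'
#' @slot reference Reference image (numeric matrix).
#' @slot deformed Deformed image (numeric matrix, same dimensions).
#' @slot pixelSize Pixel size in um/px (> 0).
#' @export
setClass("PatternImagePair",
  representation(reference = "matrix", deformed = "matrix",
                 pixelSize = "numeric"))

setValidity("PatternImagePair", function(object) {
  msg <- NULL
  if (!identical(dim(object@reference), dim(object@deformed)))
    msg <- c(msg, "reference and deformed images must have identical shape")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive value (um/px)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PatternImagePair
#'
#' @param reference,deformed Grayscale images (numeric matrices, same shape).
#' @param pixelSize Pixel size in um/px.
#' @return A \linkS4class{PatternImagePair}.
#' @export
PatternImagePair <- function(reference, deformed, pixelSize) {
  new("PatternImagePair", reference = reference, deformed = deformed,
      pixelSize = as.numeric(pixelSize))
}

#' Segmented micropattern
#'
#' Result of \code{\link{segmentPattern}}: a single filled connected
#' component with its physical area and centroid.
#'
#' @slot mask Logical matrix, the segmented pattern (holes filled, one
#'   connected component).
#' @slot area Pattern area in um^2 (foreground pixel count x pixelSize^2).
#' @slot centroid Centroid as (row, col) in pixel coordinates
#'   (pixel-center convention).
#' @slot pixelSize Pixel size in um/px.
#' @export
setClass("SegmentedPattern",
  representation(mask = "matrix", area = "numeric", centroid = "numeric",
                 pixelSize = "numeric"))

setValidity("SegmentedPattern", function(object) {
  msg <- NULL
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@area) != 1 || object@area <= 0)
    msg <- c(msg, "area must be positive")
  expected <- sum(object@mask) * object@pixelSize^2
  if (abs(object@area - expected) > 1e-9 * max(object@area, expected))
    msg <- c(msg, "area inconsistent with mask pixel count and pixelSize")
  if (length(object@centroid) != 2) msg <- c(msg, "centroid must be (row, col)")
  if (is.null(msg)) TRUE else msg
})

#' Force-distance curve
#'
#' One approach-retract cycle of a single-cell force-spectroscopy
#' measurement. Heights are piezo positions in um, forces in nN; the sign
#' convention is positive = compressive (cantilever pushed up), negative =
#' adhesive. The retract segment must be present; within each segment the
#' height is strictly monotone.
#'
#' @slot height Piezo position samples (um).
#' @slot force Force samples (nN), same length as height.
#' @slot segment Character per sample, "approach" or "retract".
#' @slot metadata List: retractVelocity (um/s), setpoint (nN), zLength (um),
#'   plus processing state (baselineCorrected flag, baselineNoise in nN).
#' @export
setClass("ForceDistanceCurve",
  representation(height = "numeric", force = "numeric", segment = "character",
                 metadata = "list"))

setValidity("ForceDistanceCurve", function(object) {
  msg <- NULL
  n <- length(object@height)
  if (length(object@force) != n || length(object@segment) != n)
    msg <- c(msg, "height, force and segment must have equal length")
  if (!all(object@segment %in% c("approach", "retract")))
    msg <- c(msg, "segment labels must be 'approach' or 'retract'")
  if (!any(object@segment == "retract"))
    msg <- c(msg, "a retract segment must be present")
  for (seg in unique(object@segment)) {
    h <- object@height[object@segment == seg]
    if (length(h) > 1 && !(all(diff(h) > 0) || all(diff(h) < 0)))
      msg <- c(msg, sprintf("height must be strictly monotone within the %s segment", seg))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ForceDistanceCurve
#'
#' @param height Piezo positions (um).
#' @param force Forces (nN).
#' @param segment Segment labels per sample ("approach"/"retract"); a single
#'   value is recycled.
#' @param retractVelocity Retract velocity in um/s (default 0.8).
#' @param setpoint Approach setpoint in nN (default 8).
#' @param zLength Retract length in um (default 50).
#' @return A \linkS4class{ForceDistanceCurve}.
#' @export
ForceDistanceCurve <- function(height, force, segment = "retract",
                               retractVelocity = 0.8, setpoint = 8,
                               zLength = 50) {
  segment <- rep_len(as.character(segment), length(height))
  new("ForceDistanceCurve", height = as.numeric(height),
      force = as.numeric(force), segment = segment,
      metadata = list(retractVelocity = retractVelocity, setpoint = setpoint,
                      zLength = zLength, baselineCorrected = FALSE,
                      baselineNoise = NA_real_))
}

#' Adhesion metrics of a force-distance curve
#'
#' Summary of one retract curve: the work of detachment, the peak adhesive
#' force, the distance over which the cell stays attached, and the number of
#' discrete unbinding steps.
#'
#' @slot adhesionEnergy Work of detachment in pJ.
#' @slot adhesionForce Peak adhesive force magnitude in uN.
#' @slot ruptureLength Distance from contact to the last above-noise
#'   unbinding signal, um.
#' @slot nSteps Number of detected unbinding steps.
#' @slot baselineNoise Standard deviation of the corrected baseline (nN).
#' @export
setClass("AdhesionMetrics",
  representation(adhesionEnergy = "numeric", adhesionForce = "numeric",
                 ruptureLength = "numeric", nSteps = "integer",
                 baselineNoise = "numeric"))

setValidity("AdhesionMetrics", function(object) {
  v <- c(object@adhesionEnergy, object@adhesionForce, object@ruptureLength,
         object@baselineNoise)
  if (any(v < 0, na.rm = TRUE)) "all metrics must be non-negative" else TRUE
})

#' Segmented particle set
#'
#' Focal adhesions (or any particles) segmented from a fluorescence image:
#' one row per particle with its area, centroid and bounding box, plus the
#' bookkeeping aggregates count, mean area and total area
#' (meanArea * count == totalArea by construction).
#'
#' @slot particles data.frame with columns area_um2, centroid_row,
#'   centroid_col, bbox_rmin, bbox_rmax, bbox_cmin, bbox_cmax.
#' @slot count Number of particles.
#' @slot meanArea Mean particle area (um^2); NA when count is 0.
#' @slot totalArea Total particle area (um^2).
#' @slot pixelSize Pixel size (um/px).
#' @export
setClass("ParticleSet",
  representation(particles = "data.frame", count = "integer",
                 meanArea = "numeric", totalArea = "numeric",
                 pixelSize = "numeric"))

setValidity("ParticleSet", function(object) {
  msg <- NULL
  if (object@count != nrow(object@particles))
    msg <- c(msg, "count must equal the number of particle rows")
  if (object@count > 0) {
    if (abs(object@meanArea * object@count - object@totalArea) >
        1e-9 * max(object@totalArea, 1e-12))
      msg <- c(msg, "meanArea * count must equal totalArea")
  }
  if (is.null(msg)) TRUE else msg
})

#' Cell shape metrics
#'
#' Spreading area, second-moment-ellipse aspect ratio and isoperimetric
#' circularity (4*pi*A/P^2) of a cell mask.
#'
#' @slot spreadingArea Area in um^2.
#' @slot aspectRatio Major/minor axis ratio of the fitted ellipse (>= 1).
#' @slot circularity 4*pi*A/P^2; 1 for a perfect disk (discretization can
#'   push it slightly above 1).
#' @export
setClass("ShapeMetrics",
  representation(spreadingArea = "numeric", aspectRatio = "numeric",
                 circularity = "numeric"))

#' Filament set
#'
#' Skeleton branches of line-like structures (actin filaments) with their
#' physical lengths.
#'
#' @slot segments List of polyline paths, each an n x 2 matrix of (row, col)
#'   pixel coordinates.
#' @slot lengths Path lengths in um.
#' @slot meanLength Arithmetic mean of lengths (NA when empty).
#' @slot pixelSize Pixel size (um/px).
#' @export
setClass("FilamentSet",
  representation(segments = "list", lengths = "numeric",
                 meanLength = "numeric", pixelSize = "numeric"))

setValidity("FilamentSet", function(object) {
  msg <- NULL
  if (length(object@segments) != length(object@lengths))
    msg <- c(msg, "segments and lengths must have equal length")
  if (any(object@lengths < 0)) msg <- c(msg, "lengths must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Migration track
#'
#' Time-stamped positions of one migrating cell. Times are minutes with a
#' uniform frame interval; positions are um, either 1D (n x 1, the position
#' along the channel axis) or 2D (n x 2).
#'
#' @slot trackId Identifier.
#' @slot times Times in minutes, strictly increasing, uniform interval.
#' @slot positions n x 1 or n x 2 matrix of positions in um.
#' @export
setClass("Track",
  representation(trackId = "character", times = "numeric",
                 positions = "matrix"))

setValidity("Track", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (n < 3) msg <- c(msg, "a track needs at least 3 samples")
  if (nrow(object@positions) != n)
    msg <- c(msg, "positions must have one row per time point")
  if (!ncol(object@positions) %in% c(1, 2))
    msg <- c(msg, "positions must be 1D or 2D")
  if (n >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-6 * mean(dt))
      msg <- c(msg, "frame interval must be uniform (within 1e-6 relative)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a Track
#'
#' @param trackId Identifier (coerced to character).
#' @param times Times in minutes (strictly increasing, uniform interval).
#' @param positions Numeric vector (1D) or n x 1 / n x 2 matrix of positions
#'   in um.
#' @return A \linkS4class{Track}.
#' @examples
#' Track("t1", times = seq(0, 50, by = 5), positions = seq(0, 10, 1))
#' @export
Track <- function(trackId, times, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1)
  new("Track", trackId = as.character(trackId), times = as.numeric(times),
      positions = positions)
}

#' Generator specification
#'
#' Common knobs of the synthetic-data generators: the seed (which fixes all
#' randomness -- identical specs give bit-identical output), the pixel size
#' for image generators, and the intensity noise level as a fraction of the
#' dynamic range.
#'
#' @slot seed Integer seed.
#' @slot pixelSize um/px for image generators.
#' @slot noiseSigma Gaussian intensity noise, fraction of dynamic range.
#' @export
setClass("GeneratorSpec",
  representation(seed = "integer", pixelSize = "numeric",
                 noiseSigma = "numeric"))

setValidity("GeneratorSpec", function(object) {
  msg <- NULL
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneratorSpec
#'
#' @param seed Integer seed fixing all randomness of a generator call.
#' @param pixelSize Pixel size in um/px for image generators (default 0.2).
#' @param noiseSigma Gaussian intensity noise as a fraction of the dynamic
#'   range (default 0.05).
#' @return A \linkS4class{GeneratorSpec}.
#' @export
GeneratorSpec <- function(seed = 1L, pixelSize = 0.2, noiseSigma = 0.05) {
  new("GeneratorSpec", seed = as.integer(seed),
      pixelSize = as.numeric(pixelSize), noiseSigma = as.numeric(noiseSigma))
}
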
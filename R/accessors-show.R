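#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
setMethod("youngModulus", "ElasticSubstrate", function(object)
  object@youngModulus)

#' @rdname accessors
setMethod("poissonRatio", "ElasticSubstrate", function(object)
  object@poissonRatio)

#' @rdname accessors
setMethod("poissonRatio", "RadialDisplacementField", function(object)
  object@poissonRatio)

.areaUnit <- function(x, unit) {
  unit <- match.arg(unit, c("m2", "um2"))
  if (unit == "um2") x * 1e12 else x
}

#' @rdname accessors
setMethod("initialArea", "PatternDeformation", function(object, unit = "m2")
  .areaUnit(object@initialArea, unit))

#' @rdname accessors
setMethod("finalArea", "PatternDeformation", function(object, unit = "m2")
  .areaUnit(object@finalArea, unit))

#' @rdname accessors
setMethod("initialRadius", "PatternDeformation", function(object)
  sqrt(object@initialArea / pi))

#' @rdname accessors
setMethod("finalRadius", "PatternDeformation", function(object)
  sqrt(object@finalArea / pi))

#' @rdname accessors
setMethod("radii", "RadialDisplacementField", function(object) object@radii)

#' @rdname accessors
setMethod("displacement", "RadialDisplacementField", function(object)
  object@displacement)

#' @rdname accessors
setMethod("pixelSize", "PatternImagePair", function(object) object@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "SegmentedPattern", function(object) object@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "ParticleSet", function(object) object@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "FilamentSet", function(object) object@pixelSize)

#' @rdname accessors
setMethod("particleCount", "ParticleSet", function(object) object@count)

#' @rdname accessors
setMethod("meanArea", "ParticleSet", function(object) object@meanArea)

#' @rdname accessors
setMethod("totalArea", "ParticleSet", function(object) object@totalArea)

# ---- show methods ----

setMethod("show", "ElasticSubstrate", function(object) {
  cat(sprintf("ElasticSubstrate: E = %.4g kPa, sigma = %.3g\n",
              object@youngModulus / 1e3, object@poissonRatio))
})

setMethod("show", "PatternDeformation", function(object) {
  cat(sprintf(
    "PatternDeformation: A_i = %.4g um^2 (r_i = %.3g um), A_f = %.4g um^2 (r_f = %.3g um)\n",
    object@initialArea * 1e12, initialRadius(object) * 1e6,
    object@finalArea * 1e12, finalRadius(object) * 1e6))
})

setMethod("show", "RadialDisplacementField", function(object) {
  cat(sprintf(
    "RadialDisplacementField: %d samples, r in [%.3g, %.3g] m, sigma = %.3g\n",
    length(object@radii), min(object@radii), max(object@radii),
    object@poissonRatio))
})

setMethod("show", "PatternImagePair", function(object) {
  cat(sprintf("PatternImagePair: %d x %d px at %.3g um/px\n",
              nrow(object@reference), ncol(object@reference),
              object@pixelSize))
})

setMethod("show", "SegmentedPattern", function(object) {
  cat(sprintf(
    "SegmentedPattern: area = %.4g um^2, centroid = (%.1f, %.1f) px\n",
    object@area, object@centroid[1], object@centroid[2]))
})

setMethod("show", "ForceDistanceCurve", function(object) {
  nr <- sum(object@segment == "retract")
  na <- sum(object@segment == "approach")
  cat(sprintf(
    "ForceDistanceCurve: %d retract / %d approach samples, z-length %.3g um%s\n",
    nr, na, object@metadata$zLength,
    if (isTRUE(object@metadata$baselineCorrected))
      sprintf(", baseline-corrected (noise %.3g nN)",
              object@metadata$baselineNoise) else ""))
})

setMethod("show", "AdhesionMetrics", function(object) {
  cat(sprintf(
    "AdhesionMetrics: energy %.4g pJ, force %.4g uN, rupture %.4g um, %d steps\n",
    object@adhesionEnergy, object@adhesionForce, object@ruptureLength,
    object@nSteps))
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf(
    "ParticleSet: %d particles, mean %.4g um^2, total %.4g um^2\n",
    object@count, object@meanArea, object@totalArea))
})

setMethod("show", "ShapeMetrics", function(object) {
  cat(sprintf(
    "ShapeMetrics: area %.4g um^2, aspect ratio %.3g, circularity %.3g\n",
    object@spreadingArea, object@aspectRatio, object@circularity))
})

setMethod("show", "FilamentSet", function(object) {
  cat(sprintf("FilamentSet: %d filaments, mean length %.4g um\n",
              length(object@lengths), object@meanLength))
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track %s: %d frames, %d min, %dD\n", object@trackId,
              length(object@times),
              round(max(object@times) - min(object@times)),
              ncol(object@positions)))
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: seed %d, %.3g um/px, noise %.3g\n",
              object@seed, object@pixelSize, object@noiseSigma))
})

#' Coerce AdhesionMetrics to a one-row data.frame
#'
#' @param x An \linkS4class{AdhesionMetrics}.
#' @param row.names,optional,... Ignored (base signature).
#' @return data.frame with columns adhesion_energy_pJ, adhesion_force_uN,
#'   rupture_length_um, n_steps, baseline_noise_nN.
#' @export
as.data.frame.AdhesionMetrics <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(adhesion_energy_pJ = x@adhesionEnergy,
             adhesion_force_uN = x@adhesionForce,
             rupture_length_um = x@ruptureLength,
             n_steps = x@nSteps,
             baseline_noise_nN = x@baselineNoise)
}
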
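#' @include AllClasses.R
NULL

#' @rdname contractileEnergy
#' @export
setGeneric("contractileEnergy", function(substrate, deformation, ...)
  standardGeneric("contractileEnergy"))

#' @rdname pacsEnergy
#' @export
setGeneric("pacsEnergy", function(pair, substrate, ...)
  standardGeneric("pacsEnergy"))

#' @rdname baselineCorrect
#' @export
setGeneric("baselineCorrect", function(curve, ...)
  standardGeneric("baselineCorrect"))

#' @rdname contactPoint
#' @export
setGeneric("contactPoint", function(curve, ...)
  standardGeneric("contactPoint"))

#' @rdname adhesionForce
#' @export
setGeneric("adhesionForce", function(curve, ...)
  standardGeneric("adhesionForce"))

#' @rdname adhesionEnergy
#' @export
setGeneric("adhesionEnergy", function(curve, ...)
  standardGeneric("adhesionEnergy"))

#' @rdname ruptureLength
#' @export
setGeneric("ruptureLength", function(curve, ...)
  standardGeneric("ruptureLength"))

#' @rdname detectSteps
#' @export
setGeneric("detectSteps", function(curve, ...)
  standardGeneric("detectSteps"))

#' @rdname adhesionMetrics
#' @export
setGeneric("adhesionMetrics", function(curve, ...)
  standardGeneric("adhesionMetrics"))

#' @rdname trackMetrics
#' @export
setGeneric("pathLength", function(track) standardGeneric("pathLength"))

#' @rdname trackMetrics
#' @export
setGeneric("netDisplacement", function(track) standardGeneric("netDisplacement"))

#' @rdname trackMetrics
#' @export
setGeneric("meanSpeed", function(track) standardGeneric("meanSpeed"))

#' @rdname persistence
#' @export
setGeneric("persistence", function(track, ...) standardGeneric("persistence"))

# ---- accessors ----

#' Accessors for cellmech classes
#'
#' Slot accessors: Young's modulus (Pa) and Poisson ratio of a substrate;
#' areas (m^2 or um^2) and derived radii (m) of a pattern deformation; radii
#' and displacement of a radial field; pixel size of image-derived objects.
#'
#' @param object A cellmech S4 object.
#' @param unit For area accessors, `"m2"` (default) or `"um2"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("youngModulus", function(object) standardGeneric("youngModulus"))

#' @rdname accessors
#' @export
setGeneric("poissonRatio", function(object) standardGeneric("poissonRatio"))

#' @rdname accessors
#' @export
setGeneric("initialArea", function(object, unit = "m2")
  standardGeneric("initialArea"))

#' @rdname accessors
#' @export
setGeneric("finalArea", function(object, unit = "m2")
  standardGeneric("finalArea"))

#' @rdname accessors
#' @export
setGeneric("initialRadius", function(object) standardGeneric("initialRadius"))

#' @rdname accessors
#' @export
setGeneric("finalRadius", function(object) standardGeneric("finalRadius"))

#' @rdname accessors
#' @export
setGeneric("radii", function(object) standardGeneric("radii"))

#' @rdname accessors
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("particleCount", function(object) standardGeneric("particleCount"))

#' @rdname accessors
#' @export
setGeneric("meanArea", function(object) standardGeneric("meanArea"))

#' @rdname accessors
#' @export
setGeneric("totalArea", function(object) standardGeneric("totalArea"))
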
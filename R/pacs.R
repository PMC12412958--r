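#' @include AllClasses.R AllGenerics.R imaging-utils.R
NULL

#' Segment a fluorescent micropattern
#'
#' Global threshold (Otsu by default, or a fixed fraction of the intensity
#' range), optional Gaussian pre-smoothing, selection of the largest
#' 8-connected component, and hole filling. The physical area is the
#' foreground pixel count times \code{pixelSize^2}.
#'
#' @param image Grayscale image (numeric matrix, [row, col]).
#' @param pixelSize Pixel size in um/px.
#' @param method Threshold method, `"otsu"` (default) or `"fixed_fraction"`.
#' @param fraction Fraction of the intensity range for
#'   `method = "fixed_fraction"` (default 0.5).
#' @param smoothSigma Gaussian pre-smoothing sigma in px (default 1; 0
#'   disables).
#' @param threshold Optional explicit intensity threshold, overriding
#'   \code{method} (used e.g. to threshold an image pair jointly).
#' @return A \linkS4class{SegmentedPattern}.
#' @examples
#' spec <- GeneratorSpec(seed = 7)
#' gel <- ElasticSubstrate(1e4, 0.5)
#' gp <- genPatternPair(gel, initialArea = 1000, trueEnergy = 3, spec = spec)
#' segmentPattern(gp$pair@reference, pixelSize(gp$pair))
#' @export
segmentPattern <- function(image, pixelSize,
                           method = c("otsu", "fixed_fraction"),
                           fraction = 0.5, smoothSigma = 1,
                           threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (diff(range(image)) <= 0)
    stop("cannot segment a constant image")
  sm <- .smooth(image, smoothSigma)
  th <- if (is.null(threshold))
    .threshold(sm, method = method, fraction = fraction) else threshold
  mask <- sm > th
  if (!any(mask)) stop("empty foreground after thresholding")
  lab <- .label8(mask)
  st <- .labelStats(lab)
  keep <- st$label[which.max(st$npix)]
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) > 0
  idx <- which(mask)
  r <- ((idx - 1) %% nrow(mask)) + 1
  cl <- ((idx - 1) %/% nrow(mask)) + 1
  new("SegmentedPattern", mask = mask, area = sum(mask) * pixelSize^2,
      centroid = c(mean(r), mean(cl)), pixelSize = pixelSize)
}

#' Contractile energy of a micropattern image pair
#'
#' The pattern-based contractility screening measurement for one cell:
#' segments the reference and deformed images with
#' \code{\link{segmentPattern}}, then maps the measured areas to energy
#' through \code{\link{contractileEnergy}} (the same code path as the
#' closed-form model; no separate formula). Identical images give exactly
#' zero.
#'
#' Because the energy depends on the small difference of two large areas,
#' the pair is thresholded jointly by default: one threshold computed from
#' the pooled intensities of both (smoothed) images, so any threshold bias
#' shifts both areas equally and cancels in the difference. Set
#' \code{jointThreshold = FALSE} for fully independent per-image
#' segmentation.
#'
#' @param pair A \linkS4class{PatternImagePair}.
#' @param substrate An \linkS4class{ElasticSubstrate}.
#' @param method,fraction,smoothSigma Passed to \code{\link{segmentPattern}}.
#' @param jointThreshold Compute one threshold from both images (default
#'   TRUE).
#' @param allowExpansion Passed to \code{\link{contractileEnergy}}.
#' @return List with \code{energy_pJ}, \code{area_initial_um2},
#'   \code{area_final_um2} and \code{expansion} (logical flag).
#' @export
setMethod("pacsEnergy",
  signature(pair = "PatternImagePair", substrate = "ElasticSubstrate"),
  function(pair, substrate, method = "otsu", fraction = 0.5,
           smoothSigma = 1, jointThreshold = TRUE, allowExpansion = TRUE) {
    validObject(pair)
    th <- NULL
    if (jointThreshold) {
      pooled <- rbind(.smooth(pair@reference, smoothSigma),
                      .smooth(pair@deformed, smoothSigma))
      th <- .threshold(pooled, method = method, fraction = fraction)
    }
    ref <- segmentPattern(pair@reference, pair@pixelSize, method = method,
                          fraction = fraction, smoothSigma = smoothSigma,
                          threshold = th)
    def <- segmentPattern(pair@deformed, pair@pixelSize, method = method,
                          fraction = fraction, smoothSigma = smoothSigma,
                          threshold = th)
    defm <- PatternDeformation(ref@area, def@area, unit = "um2")
    u <- contractileEnergy(substrate, defm, allowExpansion = allowExpansion)
    list(energy_pJ = as.numeric(u) * 1e12,
         area_initial_um2 = ref@area,
         area_final_um2 = def@area,
         expansion = attr(u, "expansion"))
  })

#' Batch PaCS analysis from a manifest
#'
#' Runs \code{\link{pacsEnergy}} over a manifest of image pairs. Failures
#' (unreadable files, segmentation errors) are recorded per cell with a
#' reason code in the \code{status} column, never silently dropped.
#'
#' @param manifest data.frame (or CSV path) with columns \code{cell_id},
#'   \code{reference_path}, \code{deformed_path}, \code{pixel_size_um}.
#' @param substrate An \linkS4class{ElasticSubstrate}.
#' @param config Optional list of segmentation settings: \code{method},
#'   \code{fraction}, \code{smooth_sigma}, \code{allow_expansion}. See
#'   \code{\link{readPacsConfig}} for the file form.
#' @return data.frame with columns cell_id, area_initial_um2,
#'   area_final_um2, energy_pJ, status ("ok" or "error: ...").
#' @export
batchPacs <- function(manifest, substrate, config = list()) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("cell_id", "reference_path", "deformed_path", "pixel_size_um")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  method <- config$method %||% "otsu"
  fraction <- config$fraction %||% 0.5
  smoothSigma <- config$smooth_sigma %||% 1
  allowExpansion <- config$allow_expansion %||% TRUE
  if (nrow(manifest) == 0)
    return(data.frame(cell_id = character(0), area_initial_um2 = numeric(0),
                      area_final_um2 = numeric(0), energy_pJ = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    out <- data.frame(cell_id = rec$cell_id, area_initial_um2 = NA_real_,
                      area_final_um2 = NA_real_, energy_pJ = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      pair <- PatternImagePair(readGrayTIFF(rec$reference_path),
                               readGrayTIFF(rec$deformed_path),
                               rec$pixel_size_um)
      pacsEnergy(pair, substrate, method = method, fraction = fraction,
                 smoothSigma = smoothSigma, allowExpansion = allowExpansion)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- paste0("error: ", conditionMessage(res))
    } else {
      out$area_initial_um2 <- res$area_initial_um2
      out$area_final_um2 <- res$area_final_um2
      out$energy_pJ <- res$energy_pJ
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a PaCS configuration file
#'
#' YAML (or JSON, which YAML parses) configuration for the contractility
#' pipeline. Recognized keys: \code{young_modulus_kpa} (default 10),
#' \code{poisson_ratio} (default 0.5), \code{allow_expansion} (default
#' TRUE), \code{oracle_outer_radius_factor} (default 10),
#' \code{oracle_n_points} (default 2048), plus the segmentation keys of
#' \code{\link{batchPacs}}.
#'
#' @param path Path to the config file, or NULL for defaults.
#' @return List with a \code{substrate} (\linkS4class{ElasticSubstrate}) and
#'   the remaining settings.
#' @export
readPacsConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  full <- list(
    young_modulus_kpa = cfg$young_modulus_kpa %||% 10,
    poisson_ratio = cfg$poisson_ratio %||% 0.5,
    allow_expansion = cfg$allow_expansion %||% TRUE,
    oracle_outer_radius_factor = cfg$oracle_outer_radius_factor %||% 10,
    oracle_n_points = cfg$oracle_n_points %||% 2048,
    method = cfg$method %||% "otsu",
    fraction = cfg$fraction %||% 0.5,
    smooth_sigma = cfg$smooth_sigma %||% 1)
  full$substrate <- ElasticSubstrate(full$young_modulus_kpa * 1e3,
                                     full$poisson_ratio)
  full
}

`%||%` <- function(a, b) if (is.null(a)) b else a
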
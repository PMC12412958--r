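#' @include AllClasses.R AllGenerics.R imaging-utils.R
NULL

#' Quantify particles (focal adhesions) in a fluorescence image
#'
#' Threshold-and-count quantification: global threshold, 8-connected
#' components, and a minimum-area filter. Per-particle areas are pixel
#' counts times \code{pixelSize^2}; the aggregates satisfy
#' \code{meanArea * count == totalArea} exactly.
#'
#' A constant image yields an empty set with a warning (count 0), not an
#' error, so blank fields of view flow through batch analyses.
#'
#' @param image Grayscale image (numeric matrix).
#' @param pixelSize Pixel size in um/px.
#' @param thresholdMethod `"otsu"` (default) or `"fixed_fraction"`.
#' @param fraction Fraction of the intensity range for fixed_fraction.
#' @param minArea Minimum particle area in um^2 (default 0.1, well below
#'   the smallest reported mean focal-adhesion sizes, ~0.6 um^2).
#' @param smoothSigma Gaussian pre-smoothing in px (default 0).
#' @return A \linkS4class{ParticleSet}.
#' @export
quantifyParticles <- function(image, pixelSize,
                              thresholdMethod = c("otsu", "fixed_fraction"),
                              fraction = 0.5, minArea = 0.1,
                              smoothSigma = 0) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (minArea < 0) stop("minArea must be >= 0")
  empty <- function() new("ParticleSet",
    particles = data.frame(area_um2 = numeric(0), centroid_row = numeric(0),
                           centroid_col = numeric(0), bbox_rmin = integer(0),
                           bbox_rmax = integer(0), bbox_cmin = integer(0),
                           bbox_cmax = integer(0)),
    count = 0L, meanArea = NA_real_, totalArea = 0, pixelSize = pixelSize)
  if (diff(range(image)) <= 0) {
    warning("constant image: no particles")
    return(empty())
  }
  sm <- .smooth(image, smoothSigma)
  th <- .threshold(sm, method = thresholdMethod, fraction = fraction)
  mask <- sm > th
  if (!any(mask)) {
    warning("empty foreground: no particles")
    return(empty())
  }
  st <- .labelStats(.label8(mask))
  st$area_um2 <- st$npix * pixelSize^2
  st <- st[st$area_um2 >= minArea, , drop = FALSE]
  if (nrow(st) == 0) return(empty())
  particles <- data.frame(area_um2 = st$area_um2,
                          centroid_row = st$centroid_row,
                          centroid_col = st$centroid_col,
                          bbox_rmin = st$bbox_rmin, bbox_rmax = st$bbox_rmax,
                          bbox_cmin = st$bbox_cmin, bbox_cmax = st$bbox_cmax)
  new("ParticleSet", particles = particles, count = nrow(particles),
      meanArea = sum(particles$area_um2) / nrow(particles),
      totalArea = sum(particles$area_um2), pixelSize = pixelSize)
}

#' Cell shape metrics from a binary mask
#'
#' Spreading area (pixel count), aspect ratio (major/minor axis of the
#' second-central-moment ellipse fit) and circularity
#' \eqn{4\pi A / P^2}, with the perimeter measured on the 8-connected
#' boundary chain using the corner-corrected chain-length estimator
#' (weights 0.980 / 1.406 / -0.091 for axis steps, diagonal steps and
#' direction changes), which is unbiased to well under 1\% for smooth
#' shapes. Plain sqrt(2) diagonal weighting is available for comparison
#' but overestimates smooth perimeters by ~5\%.
#'
#' @param mask Logical (or 0/1 numeric) matrix with >= 16 foreground
#'   pixels.
#' @param pixelSize Pixel size in um/px.
#' @param perimeterWeights `"calibrated"` (default) or `"sqrt2"`.
#' @return A \linkS4class{ShapeMetrics}.
#' @export
cellShapeMetrics <- function(mask, pixelSize,
                             perimeterWeights = c("calibrated", "sqrt2")) {
  perimeterWeights <- match.arg(perimeterWeights)
  mask <- mask > 0
  npx <- sum(mask)
  if (npx < 16) stop("mask must have at least 16 foreground pixels")
  idx <- which(mask)
  r <- ((idx - 1) %% nrow(mask)) + 1
  cl <- ((idx - 1) %/% nrow(mask)) + 1
  # second central moments -> ellipse axes
  mrr <- stats::var(r) * (npx - 1) / npx
  mcc <- stats::var(cl) * (npx - 1) / npx
  mrc <- stats::cov(r, cl) * (npx - 1) / npx
  tr <- mrr + mcc
  det_ <- mrr * mcc - mrc^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, .Machine$double.eps)
  aspect <- sqrt(l1 / l2)
  # boundary-following contour of the largest component
  contour <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))
  per_px <- sum(vapply(contour, function(cc)
    .chainLength(cc, closed = TRUE, weights = perimeterWeights), numeric(1)))
  area <- npx * pixelSize^2
  perim <- per_px * pixelSize
  new("ShapeMetrics", spreadingArea = area, aspectRatio = aspect,
      circularity = 4 * pi * area / perim^2)
}

#' Measure filament lengths in a fluorescence image
#'
#' Quantifies line-like structures (actin filaments): Gaussian ridge
#' smoothing, global threshold, Zhang-Suen skeletonization, decomposition
#' of the skeleton into branch paths by removing junction pixels (>= 3
#' skeleton neighbors), and per-branch chain lengths with the calibrated
#' step weights. Branches shorter than \code{minLength} are discarded as
#' skeletonization debris.
#'
#' A blank (constant) image returns an empty set with a warning;
#' \code{meanLength} is NA in that case.
#'
#' @param image Grayscale image (numeric matrix).
#' @param pixelSize Pixel size in um/px.
#' @param smoothSigma Ridge-smoothing sigma in px (default 1).
#' @param thresholdMethod `"otsu"` (default) or `"fixed_fraction"`.
#' @param fraction Fraction for fixed_fraction.
#' @param minLength Minimum branch length in um (default 1).
#' @return A \linkS4class{FilamentSet}.
#' @export
measureFilaments <- function(image, pixelSize, smoothSigma = 1,
                             thresholdMethod = c("otsu", "fixed_fraction"),
                             fraction = 0.5, minLength = 1) {
  thresholdMethod <- match.arg(thresholdMethod)
  empty <- function() new("FilamentSet", segments = list(),
                          lengths = numeric(0), meanLength = NA_real_,
                          pixelSize = pixelSize)
  if (diff(range(image)) <= 0) {
    warning("constant image: no filaments")
    return(empty())
  }
  sm <- .smooth(image, smoothSigma)
  th <- .threshold(sm, method = thresholdMethod, fraction = fraction)
  mask <- sm > th
  if (!any(mask)) {
    warning("no ridges detected")
    return(empty())
  }
  skel <- .skeletonize(mask)
  if (!any(skel)) {
    warning("no ridges detected")
    return(empty())
  }
  tc <- .transitionCount(skel)
  branches <- skel & tc <= 2          # junction pixels removed
  lab <- .label8(branches)
  nlab <- max(lab)
  segments <- list()
  lengths <- numeric(0)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    coords <- cbind(((idx - 1) %% nrow(lab)) + 1,
                    ((idx - 1) %/% nrow(lab)) + 1)
    path <- .orderPath(coords)
    len <- .chainLength(path, closed = FALSE) * pixelSize
    if (len >= minLength) {
      segments[[length(segments) + 1]] <- path
      lengths <- c(lengths, len)
    }
  }
  if (length(lengths) == 0) {
    warning("no filaments above minLength")
    return(empty())
  }
  new("FilamentSet", segments = segments, lengths = lengths,
      meanLength = mean(lengths), pixelSize = pixelSize)
}

#' Batch morphometry from a manifest
#'
#' Per-cell focal-adhesion, shape and filament quantification. The
#' manifest names a focal-adhesion image per cell and, optionally, a cell
#' mask and an actin image; absent inputs leave their columns NA. The
#' optional column \code{fa_area_per_cell_area} (total FA area normalized
#' to the spreading area) is filled when both inputs are present.
#'
#' @param manifest data.frame (or CSV path) with columns \code{cell_id},
#'   \code{fa_image_path}, \code{pixel_size_um} and optionally
#'   \code{cell_mask_path}, \code{actin_image_path}.
#' @param minArea Minimum particle area in um^2 (default 0.1).
#' @return data.frame with cell_id, fa_count, fa_mean_area_um2,
#'   fa_total_area_um2, spreading_area_um2, aspect_ratio, circularity,
#'   actin_mean_length_um, fa_area_per_cell_area, status.
#' @export
batchMorphometry <- function(manifest, minArea = 0.1) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("cell_id", "fa_image_path", "pixel_size_um")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(manifest) == 0)
    return(data.frame(cell_id = character(0), fa_count = integer(0),
                      fa_mean_area_um2 = numeric(0),
                      fa_total_area_um2 = numeric(0),
                      spreading_area_um2 = numeric(0),
                      aspect_ratio = numeric(0), circularity = numeric(0),
                      actin_mean_length_um = numeric(0),
                      fa_area_per_cell_area = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    out <- data.frame(cell_id = rec$cell_id, fa_count = NA_integer_,
                      fa_mean_area_um2 = NA_real_,
                      fa_total_area_um2 = NA_real_,
                      spreading_area_um2 = NA_real_, aspect_ratio = NA_real_,
                      circularity = NA_real_, actin_mean_length_um = NA_real_,
                      fa_area_per_cell_area = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      ps <- quantifyParticles(readGrayTIFF(rec$fa_image_path),
                              rec$pixel_size_um, minArea = minArea)
      out$fa_count <- ps@count
      out$fa_mean_area_um2 <- ps@meanArea
      out$fa_total_area_um2 <- ps@totalArea
      if (!is.null(rec$cell_mask_path) && !is.na(rec$cell_mask_path) &&
          nzchar(rec$cell_mask_path)) {
        shp <- cellShapeMetrics(readGrayTIFF(rec$cell_mask_path) > 0.5,
                                rec$pixel_size_um)
        out$spreading_area_um2 <- shp@spreadingArea
        out$aspect_ratio <- shp@aspectRatio
        out$circularity <- shp@circularity
        out$fa_area_per_cell_area <- ps@totalArea / shp@spreadingArea
      }
      if (!is.null(rec$actin_image_path) && !is.na(rec$actin_image_path) &&
          nzchar(rec$actin_image_path)) {
        fs <- measureFilaments(readGrayTIFF(rec$actin_image_path),
                               rec$pixel_size_um)
        out$actin_mean_length_um <- fs@meanLength
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- paste0("error: ", conditionMessage(res))
      out
    } else res
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
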
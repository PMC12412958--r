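#' @include AllClasses.R AllGenerics.R
NULL

# Retract segment of a curve, oriented so height increases (tip moving away
# from the surface).
.retract <- function(curve) {
  idx <- which(curve@segment == "retract")
  h <- curve@height[idx]
  f <- curve@force[idx]
  if (length(h) > 1 && h[1] > h[length(h)]) {
    h <- rev(h); f <- rev(f)
  }
  list(height = h, force = f)
}

.requireCorrected <- function(curve) {
  if (!isTRUE(curve@metadata$baselineCorrected))
    stop("curve must be baseline-corrected first (see baselineCorrect())")
}

.oddWindow <- function(n, len) max(1L, min(2L * (as.integer(n) %/% 2L) + 1L,
                                           if (len %% 2L == 0L) len - 1L else len))

#' Baseline-correct a force-distance curve
#'
#' Fits a first-degree (offset + slope) trend to the final
#' \code{tailFraction} of the retract segment -- the part farthest from the
#' surface, where the cell is fully detached -- and subtracts that trend
#' from the whole retract (the approach, when present, is corrected with
#' the same line). The standard deviation of the corrected tail is stored
#' as the baseline noise, which all subsequent thresholds are expressed in.
#'
#' @param curve A \linkS4class{ForceDistanceCurve}.
#' @param tailFraction Fraction of the retract used for the fit, in
#'   (0, 0.5] (default 0.2: the final 10 um of a 50 um retract).
#' @return The corrected \linkS4class{ForceDistanceCurve}, with metadata
#'   \code{baselineCorrected = TRUE} and \code{baselineNoise} (nN).
#' @export
setMethod("baselineCorrect", "ForceDistanceCurve",
  function(curve, tailFraction = 0.2) {
    if (!(tailFraction > 0 && tailFraction <= 0.5))
      stop("tailFraction must lie in (0, 0.5]")
    ret <- .retract(curve)
    n <- length(ret$height)
    if (n < 10) stop("retract segment has fewer than 10 samples")
    ntail <- max(2L, floor(n * tailFraction))
    tail_idx <- (n - ntail + 1):n
    fit <- stats::lm.fit(cbind(1, ret$height[tail_idx]),
                         ret$force[tail_idx])
    trend <- function(h) fit$coefficients[1] + fit$coefficients[2] * h
    force <- curve@force - trend(curve@height)
    noise <- stats::sd(ret$force[tail_idx] - trend(ret$height[tail_idx]))
    md <- curve@metadata
    md$baselineCorrected <- TRUE
    md$baselineNoise <- noise
    initialize(curve, force = force, metadata = md)
  })

#' Contact point of a retract curve
#'
#' The retract height at which the force last crosses zero coming from the
#' compressive (positive) side: the origin for all tip-surface distances
#' (rupture length, adhesion energy). The force is median-filtered first so
#' isolated noise excursions cannot masquerade as compression; compressive
#' samples are identified as filtered force above \code{noiseK} times the
#' baseline noise, and the crossing is located by linear interpolation
#' after the last such sample. A curve that is never compressive falls
#' back to the first retract sample, with a warning.
#'
#' @param curve A baseline-corrected \linkS4class{ForceDistanceCurve}.
#' @param noiseK Compression detection threshold in baseline-noise units
#'   (default 3).
#' @param smoothN Running-median window in samples (odd; default 5; 1
#'   disables).
#' @return Contact height in um.
#' @export
setMethod("contactPoint", "ForceDistanceCurve",
  function(curve, noiseK = 3, smoothN = 5) {
  .requireCorrected(curve)
  ret <- .retract(curve)
  h <- ret$height
  w <- .oddWindow(smoothN, length(ret$force))
  f <- if (w > 1) stats::runmed(ret$force, w) else ret$force
  thr <- noiseK * max(curve@metadata$baselineNoise, 1e-9)
  # contact precedes the deepest adhesion; restricting the search there
  # keeps noise excursions in the force-free tail from masquerading as
  # late compression
  im <- which.min(f)
  if (im < 2) im <- length(f)
  comp <- which(f[1:im] > thr)
  if (length(comp) == 0 && f[im] < -thr)
    comp <- which(f[1:im] > 0 & seq_len(im) < im)
  if (length(comp) == 0) {
    warning("curve is never compressive; contact set to first retract sample")
    return(h[1])
  }
  i0 <- max(comp)
  below <- which(f[i0:length(f)] <= 0)
  if (length(below) == 0) {
    warning("force never crosses zero after compression; contact set to last compressive sample")
    return(h[i0])
  }
  j <- i0 + below[1] - 1   # first sample at or below zero
  if (j == 1) return(h[1])
  # linear interpolation between (j-1, j)
  f1 <- f[j - 1]; f2 <- f[j]
  if (f1 == f2) return(h[j])
  h[j - 1] + (h[j] - h[j - 1]) * f1 / (f1 - f2)
})

#' Adhesion force of a retract curve
#'
#' Magnitude of the most adhesive (most negative) retract force relative to
#' the corrected baseline. A short running-median filter suppresses the
#' upward bias that single-sample noise excursions would otherwise add to
#' the extremum.
#'
#' @param curve A baseline-corrected \linkS4class{ForceDistanceCurve}.
#' @param smoothN Running-median window in samples (odd; default 11; 1
#'   disables). The window is short against the well width, so the peak is
#'   not flattened, while the noise-induced upward bias of the extremum is
#'   suppressed.
#' @return Adhesion force in uN (non-negative).
#' @export
setMethod("adhesionForce", "ForceDistanceCurve", function(curve, smoothN = 11) {
  .requireCorrected(curve)
  ret <- .retract(curve)
  f <- ret$force
  w <- .oddWindow(smoothN, length(f))
  if (w > 1) f <- stats::runmed(f, w)
  max(0, -min(f)) / 1000
})

#' Adhesion energy (work of detachment) of a retract curve
#'
#' Trapezoidal integral of the adhesive force magnitude
#' \eqn{\max(0, -F)} over the tip-surface distance, from the contact point
#' to the end of the adhesive region (the last sample whose smoothed
#' absolute force exceeds \code{noiseK} times the baseline noise).
#'
#' @param curve A baseline-corrected \linkS4class{ForceDistanceCurve}.
#' @param noiseK Threshold defining the end of the adhesive region (default
#'   3).
#' @param smoothN Running-median window for the region bound (default 5).
#' @return Adhesion energy in pJ (non-negative; 0 for a flat curve).
#' @export
setMethod("adhesionEnergy", "ForceDistanceCurve",
  function(curve, noiseK = 3, smoothN = 5) {
    .requireCorrected(curve)
    ret <- .retract(curve)
    hc <- contactPoint(curve, noiseK = noiseK)
    d <- ret$height - hc
    keep <- d >= 0
    d <- d[keep]; f <- ret$force[keep]
    if (length(d) < 2) return(0)
    w <- .oddWindow(smoothN, length(f))
    sm <- if (w > 1) stats::runmed(f, w) else f
    thr <- noiseK * max(curve@metadata$baselineNoise, 1e-9)
    above <- which(abs(sm) > thr)
    if (length(above) == 0) return(0)
    iend <- max(above)
    if (iend < 2) return(0)
    # nN * um = fJ; report pJ
    pracma::trapz(d[1:iend], pmax(0, -f[1:iend])) / 1000
  })

#' Rupture length of a retract curve
#'
#' Distance from the contact point to the last retract sample whose
#' (median-filtered) absolute force exceeds \code{noiseK} times the
#' baseline noise -- the point where the last tether lets go. Zero when no
#' adhesive signal is present. Monotone non-decreasing as the noise
#' tolerance is relaxed, and never larger than the retract length.
#'
#' @param curve A baseline-corrected \linkS4class{ForceDistanceCurve}.
#' @param noiseK Detection threshold in baseline-noise units (default 3).
#' @param smoothN Running-median window in samples (odd; default 5). The
#'   filter keeps isolated noise excursions in the force-free tail from
#'   masquerading as the final rupture.
#' @return Rupture length in um.
#' @export
setMethod("ruptureLength", "ForceDistanceCurve",
  function(curve, noiseK = 3, smoothN = 5) {
    .requireCorrected(curve)
    ret <- .retract(curve)
    hc <- contactPoint(curve, noiseK = noiseK)
    d <- ret$height - hc
    keep <- d >= 0
    d <- d[keep]; f <- ret$force[keep]
    if (length(d) == 0) return(0)
    w <- .oddWindow(smoothN, length(f))
    sm <- if (w > 1) stats::runmed(f, w) else f
    thr <- noiseK * max(curve@metadata$baselineNoise, 1e-9)
    above <- which(abs(sm) > thr)
    if (length(above) == 0) return(0)
    min(d[max(above)], curve@metadata$zLength)
  })

#' Detect discrete unbinding steps in a retract curve
#'
#' Locates upward force jumps (toward zero, i.e. releases of load) in the
#' retract exceeding \code{minJump} within a short sample window: the
#' signature of discrete bond or tether ruptures. Contiguous detections are
#' merged into one event at the position of the steepest jump.
#'
#' @param curve A baseline-corrected \linkS4class{ForceDistanceCurve}.
#' @param minJump Minimum force jump in nN (default 5x the baseline noise).
#' @param window Jump evaluation window in samples (default 5).
#' @param noiseK Threshold used for the default \code{minJump} and for the
#'   contact point (default 3).
#' @return data.frame with one row per step: \code{distance_um} (from the
#'   contact point) and \code{jump_nN}, sorted by distance.
#' @export
setMethod("detectSteps", "ForceDistanceCurve",
  function(curve, minJump = NULL, window = 5, noiseK = 3) {
    .requireCorrected(curve)
    noise <- max(curve@metadata$baselineNoise, 1e-9)
    if (is.null(minJump)) minJump <- 5 * noise
    ret <- .retract(curve)
    hc <- contactPoint(curve, noiseK = noiseK)
    d <- ret$height - hc
    f <- ret$force
    # median window ~2x the jump window: noise in the windowed difference
    # stays well below any resolvable step while edges survive
    wm <- .oddWindow(2 * window - 1, length(f))
    sm <- if (wm > 1) stats::runmed(f, wm) else f
    n <- length(sm)
    window <- max(1L, as.integer(window))
    if (n <= window)
      return(data.frame(distance_um = numeric(0), jump_nN = numeric(0)))
    dw <- sm[(window + 1):n] - sm[1:(n - window)]
    cand <- which(dw > minJump & d[1:(n - window)] >= 0)
    if (length(cand) == 0)
      return(data.frame(distance_um = numeric(0), jump_nN = numeric(0)))
    # merge candidates closer than one window into single events
    grp <- cumsum(c(1, diff(cand) > window))
    steps <- do.call(rbind, lapply(split(cand, grp), function(ix) {
      peak <- ix[which.max(dw[ix])]
      data.frame(distance_um = d[peak] + (d[min(peak + window, n)] - d[peak]) / 2,
                 jump_nN = max(dw[ix]))
    }))
    steps <- steps[order(steps$distance_um), , drop = FALSE]
    rownames(steps) <- NULL
    steps
  })

#' All adhesion metrics of one curve
#'
#' Convenience wrapper: baseline-corrects the curve if needed, then computes
#' adhesion energy, adhesion force, rupture length and the unbinding-step
#' count with shared settings.
#'
#' @param curve A \linkS4class{ForceDistanceCurve}.
#' @param noiseK Noise threshold in baseline-noise units (default 3).
#' @param minJump Step threshold in nN (default 5x baseline noise).
#' @param tailFraction Baseline tail fraction (default 0.2).
#' @return An \linkS4class{AdhesionMetrics}.
#' @export
setMethod("adhesionMetrics", "ForceDistanceCurve",
  function(curve, noiseK = 3, minJump = NULL, tailFraction = 0.2) {
    if (!isTRUE(curve@metadata$baselineCorrected))
      curve <- baselineCorrect(curve, tailFraction = tailFraction)
    steps <- detectSteps(curve, minJump = minJump, noiseK = noiseK)
    new("AdhesionMetrics",
        adhesionEnergy = adhesionEnergy(curve, noiseK = noiseK),
        adhesionForce = adhesionForce(curve),
        ruptureLength = ruptureLength(curve, noiseK = noiseK),
        nSteps = nrow(steps),
        baselineNoise = curve@metadata$baselineNoise)
  })

#' Read a force-distance curve from a TSV file
#'
#' Tab-separated text with a header line and columns \code{height_um},
#' \code{force_nN}, \code{segment} ("approach"/"retract"; approach
#' optional). Mirrors a plain vendor text export.
#'
#' @param path Path to the TSV file.
#' @param retractVelocity,setpoint,zLength Metadata defaults (0.8 um/s,
#'   8 nN, 50 um); zLength defaults to the retract height span when NULL.
#' @return A \linkS4class{ForceDistanceCurve}.
#' @export
readForceCurve <- function(path, retractVelocity = 0.8, setpoint = 8,
                           zLength = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("height_um", "force_nN", "segment")
  if (!all(need %in% names(tab)))
    stop("curve file must have columns: ", paste(need, collapse = ", "))
  if (is.null(zLength)) {
    h <- tab$height_um[tab$segment == "retract"]
    zLength <- diff(range(h))
  }
  ForceDistanceCurve(tab$height_um, tab$force_nN, tab$segment,
                     retractVelocity = retractVelocity, setpoint = setpoint,
                     zLength = zLength)
}

#' Write a force-distance curve to a TSV file
#'
#' @param curve A \linkS4class{ForceDistanceCurve}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeForceCurve <- function(curve, path) {
  utils::write.table(
    data.frame(height_um = curve@height, force_nN = curve@force,
               segment = curve@segment),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Batch adhesion metrics over a set of curve files
#'
#' @param paths Character vector of curve TSV paths, or a directory (all
#'   \code{*.tsv} inside are used).
#' @param noiseK Noise threshold (default 3).
#' @return data.frame with curve_id (file base name), adhesion_energy_pJ,
#'   adhesion_force_uN, rupture_length_um, n_steps, status.
#' @export
batchScfs <- function(paths, noiseK = 3) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0)
    return(data.frame(curve_id = character(0),
                      adhesion_energy_pJ = numeric(0),
                      adhesion_force_uN = numeric(0),
                      rupture_length_um = numeric(0), n_steps = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  rows <- lapply(paths, function(p) {
    out <- data.frame(curve_id = sub("\\.tsv$", "", basename(p)),
                      adhesion_energy_pJ = NA_real_,
                      adhesion_force_uN = NA_real_,
                      rupture_length_um = NA_real_, n_steps = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch(adhesionMetrics(readForceCurve(p), noiseK = noiseK),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- paste0("error: ", conditionMessage(res))
    } else {
      out$adhesion_energy_pJ <- res@adhesionEnergy
      out$adhesion_force_uN <- res@adhesionForce
      out$rupture_length_um <- res@ruptureLength
      out$n_steps <- res@nSteps
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
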
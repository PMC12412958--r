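#' @include AllClasses.R AllGenerics.R imaging-utils.R contractility.R
NULL

# Antialiased disk: pixel value = approximate coverage (linear edge ramp one
# pixel wide), exact in the large-radius limit.
.diskCoverage <- function(n, centerRow, centerCol, radiusPx) {
  r <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((r - centerRow)^2 + (cl - centerCol)^2)
  matrix(pmin(1, pmax(0, radiusPx - d + 0.5)), n, n)
}

#' Synthetic micropattern image pair with known contractile energy
#'
#' Emulates one cell of the contractility screen: the final pattern area is
#' obtained from the requested ground-truth energy through
#' \code{\link{invertEnergyToFinalArea}}, and the reference/deformed
#' micropattern is rendered as an antialiased bright disk over background
#' with additive Gaussian intensity noise. The disk center is jittered
#' uniformly within one pixel (as real patterns land anywhere on the
#' sensor lattice), so pixel-counting discretization error is not locked
#' to the lattice and averages out over a cohort of seeds. Identical specs
#' give bit-identical images.
#'
#' @param substrate An \linkS4class{ElasticSubstrate}.
#' @param initialArea Initial pattern area in um^2 (default 1000).
#' @param trueEnergy Ground-truth contractile energy in pJ.
#' @param spec A \linkS4class{GeneratorSpec} (seed, pixel size um/px,
#'   noise fraction).
#' @param imageSize Image side in px (default: fitted to the pattern).
#' @param background,foreground Background/foreground intensity levels
#'   (defaults 0.1 / 0.9).
#' @return List with \code{pair} (a \linkS4class{PatternImagePair}) and
#'   \code{truth} (list: area_initial_um2, area_final_um2, energy_pJ).
#' @examples
#' gel <- ElasticSubstrate(1e4, 0.5)
#' gp <- genPatternPair(gel, 1000, trueEnergy = 4.907, spec = GeneratorSpec(1))
#' gp$truth$energy_pJ
#' @export
genPatternPair <- function(substrate, initialArea = 1000, trueEnergy,
                           spec = GeneratorSpec(), imageSize = NULL,
                           background = 0.1, foreground = 0.9) {
  ai_m2 <- initialArea * 1e-12
  af_m2 <- invertEnergyToFinalArea(substrate, ai_m2, trueEnergy * 1e-12)
  af_um2 <- af_m2 * 1e12
  ps <- spec@pixelSize
  rI <- sqrt(initialArea / pi) / ps
  rF <- sqrt(af_um2 / pi) / ps
  if (is.null(imageSize)) imageSize <- 2 * ceiling(1.4 * rI) + 32
  amp <- foreground - background
  withr::with_seed(spec@seed, {
    ctr <- (imageSize + 1) / 2 + stats::runif(2, -0.5, 0.5)
    ref <- background + amp * .diskCoverage(imageSize, ctr[1], ctr[2], rI) +
      stats::rnorm(imageSize^2, 0, spec@noiseSigma * amp)
    def <- background + amp * .diskCoverage(imageSize, ctr[1], ctr[2], rF) +
      stats::rnorm(imageSize^2, 0, spec@noiseSigma * amp)
  })
  list(pair = PatternImagePair(ref, def, ps),
       truth = list(area_initial_um2 = initialArea,
                    area_final_um2 = af_um2, energy_pJ = trueEnergy))
}

#' Synthetic force-distance retract curve with known adhesion metrics
#'
#' Constructs a retract whose noise-free analytic form has exactly the
#' requested work of detachment, peak adhesive force and rupture position:
#' a smooth adhesive well (half-sine rise to the peak, cosine relaxation to
#' a plateau) followed by a staircase of discrete unbinding steps whose
#' last step sits at \code{trueRupture}; the plateau level is solved from
#' the energy constraint. Linear baseline drift and Gaussian force noise
#' are added on top.
#'
#' With all three targets zero the curve is a flat noisy baseline.
#'
#' @param trueEnergy Work of detachment in pJ.
#' @param trueForce Peak adhesive force in uN.
#' @param trueRupture Distance from contact to the final rupture, um.
#' @param nRandomSteps Number of seeded intermediate unbinding steps
#'   (default 3; the final rupture adds one more).
#' @param spec A \linkS4class{GeneratorSpec} (only the seed is used).
#' @param zLength Retract length in um (default 50).
#' @param dz Sample spacing in um (default 0.01).
#' @param noiseNN Gaussian force noise sd in nN (default 2, the visible
#'   noise scale of typical FluidFM retractions).
#' @param contactHeight Piezo height of the contact point, um (default
#'   0.3; the region below is the compressive ramp from the 8 nN setpoint,
#'   whose slope is steep as for a stiff probe-cell contact).
#' @param riseLength,decayEnd Well geometry in um from contact: distance to
#'   the force peak (default 2) and end of the smooth relaxation (default
#'   8).
#' @param driftOffset,driftSlope Baseline drift in nN and nN/um (defaults
#'   3 and 0.05).
#' @return List with \code{curve} (a \linkS4class{ForceDistanceCurve}) and
#'   \code{truth} (energy_pJ, force_uN, rupture_um, n_steps, contact_um,
#'   step_positions_um, step_jumps_nN, and the noise-free force
#'   \code{force0_nN}).
#' @export
genForceCurve <- function(trueEnergy = 3.36, trueForce = 0.279,
                          trueRupture = 31, nRandomSteps = 3,
                          spec = GeneratorSpec(), zLength = 50, dz = 0.01,
                          noiseNN = 2, contactHeight = 0.3, riseLength = 2,
                          decayEnd = 8, driftOffset = 3, driftSlope = 0.05) {
  h <- seq(0, zLength, by = dz)
  d <- h - contactHeight
  n <- length(h)
  zeroTargets <- trueEnergy <= 0 && trueForce <= 0 && trueRupture <= 0
  truth <- list(energy_pJ = trueEnergy, force_uN = trueForce,
                rupture_um = trueRupture, contact_um = contactHeight)
  if (zeroTargets) {
    f0 <- numeric(n)
    truth$n_steps <- 0L
    truth$step_positions_um <- numeric(0)
    truth$step_jumps_nN <- numeric(0)
  } else {
    P <- trueForce * 1000          # uN -> nN
    Ework <- trueEnergy * 1000     # pJ -> nN um
    a <- riseLength; b <- decayEnd
    if (!(0 < a && a < b && b < trueRupture))
      stop("need 0 < riseLength < decayEnd < trueRupture")
    if (trueRupture > zLength - contactHeight)
      stop("trueRupture exceeds the available retract range")
    k <- nRandomSteps + 1L
    withr::with_seed(spec@seed, {
      margin <- 0.05 * (trueRupture - b)
      pos <- if (k > 1)
        sort(stats::runif(k - 1, b + margin, trueRupture - margin))
      else numeric(0)
      pos <- c(pos, trueRupture)
      w <- stats::runif(k, 0.5, 1.5)
      w <- w / sum(w)
      noise <- stats::rnorm(n, 0, noiseNN)
    })
    lvl <- 1 - cumsum(w)           # level fractions after each step
    lvl[k] <- 0
    # plateau area per unit L: sum of (level before step j) * segment length
    segStart <- c(b, pos[-k])
    S <- sum(c(1, lvl[-k]) * (pos - segStart))
    L <- (Ework - P * b / 2) / ((b - a) / 2 + S)
    if (!is.finite(L) || L <= 0 || L >= P)
      stop(sprintf(
        "inconsistent (energy, force, rupture) triple: no admissible well (plateau %.3g nN vs peak %.3g nN)",
        L, P))
    f0 <- numeric(n)
    pre <- d < 0
    f0[pre] <- 8 * (-d[pre]) / contactHeight   # compressive ramp (setpoint 8 nN)
    rise <- d >= 0 & d <= a
    f0[rise] <- -P * sin(pi * d[rise] / (2 * a))^2
    dec <- d > a & d <= b
    f0[dec] <- -L - (P - L) * cos(pi * (d[dec] - a) / (2 * (b - a)))^2
    plateau <- d > b & d <= trueRupture
    lv <- c(L, L * lvl[-k])        # level on segment j (before step j+1)
    seg <- findInterval(d[plateau], segStart, left.open = TRUE)
    f0[plateau] <- -lv[pmax(seg, 1)]
    truth$n_steps <- k
    truth$step_positions_um <- pos
    truth$step_jumps_nN <- c(L, L * lvl[-k]) - c(L * lvl)
  }
  if (zeroTargets)
    withr::with_seed(spec@seed, noise <- stats::rnorm(n, 0, noiseNN))
  force <- f0 + noise + driftOffset + driftSlope * h
  truth$force0_nN <- f0
  curve <- ForceDistanceCurve(h, force, "retract", zLength = zLength)
  list(curve = curve, truth = truth)
}

#' Synthetic focal-adhesion image with known particle ground truth
#'
#' Places non-overlapping ellipses with log-normally distributed areas
#' (given mean and coefficient of variation), uniform orientation and
#' aspect ratio, over a noisy background. The ground truth records, per
#' ellipse, both the requested analytic area and the exactly painted pixel
#' area (painted pixel count x pixelSize^2), so the bookkeeping identity
#' sum(painted areas) == mask pixel count x pixelSize^2 holds exactly.
#'
#' @param nAdhesions Number of ellipses (0 gives pure background).
#' @param meanArea Mean ellipse area in um^2 (default 0.977).
#' @param areaCV Coefficient of variation of the areas (default 0.4).
#' @param spec A \linkS4class{GeneratorSpec}; pixelSize should resolve the
#'   particles (0.1 um/px is typical for a 63x objective).
#' @param imageSize Image side in px (default 512).
#' @param aspectRange Ellipse aspect-ratio range (default c(1.5, 3)).
#' @param background,foreground Intensity levels (0.15 / 0.9).
#' @param matchMean Rescale the sampled areas so their mean equals
#'   \code{meanArea} exactly (default TRUE).
#' @param minGapPx Minimum bounding-box gap between ellipses in px
#'   (default 3).
#' @param maxTries Placement retries per ellipse before a packing error
#'   (default 200).
#' @return List with \code{image}, \code{mask} and \code{truth} (count,
#'   areas_requested_um2, areas_painted_um2, centers).
#' @export
genFaImage <- function(nAdhesions, meanArea = 0.977, areaCV = 0.4,
                       spec = GeneratorSpec(pixelSize = 0.1),
                       imageSize = 512, aspectRange = c(1.5, 3),
                       background = 0.15, foreground = 0.9,
                       matchMean = TRUE, minGapPx = 3, maxTries = 200) {
  ps <- spec@pixelSize
  amp <- foreground - background
  withr::with_seed(spec@seed, {
    if (nAdhesions > 0) {
      sdl <- sqrt(log(1 + areaCV^2))
      areas <- stats::rlnorm(nAdhesions, log(meanArea) - sdl^2 / 2, sdl)
      areas <- pmax(areas, 0.2 * meanArea)
      if (matchMean) areas <- areas * meanArea / mean(areas)
      if (sum(areas) / (imageSize^2 * ps^2) > 0.3)
        stop("packing infeasible: total ellipse area exceeds 30% of the frame")
      aspects <- stats::runif(nAdhesions, aspectRange[1], aspectRange[2])
      phis <- stats::runif(nAdhesions, 0, pi)
      mask <- matrix(FALSE, imageSize, imageSize)
      excl <- matrix(FALSE, imageSize, imageSize)
      painted <- numeric(nAdhesions)
      centers <- matrix(NA_real_, nAdhesions, 2)
      for (i in seq_len(nAdhesions)) {
        area_px <- areas[i] / ps^2
        bax <- sqrt(area_px / (pi * aspects[i]))   # semi-minor
        aax <- aspects[i] * bax                    # semi-major
        ok <- FALSE
        for (try in seq_len(maxTries)) {
          ext <- ceiling(aax) + 1
          cr <- stats::runif(1, 1 + ext, imageSize - ext)
          cc <- stats::runif(1, 1 + ext, imageSize - ext)
          rr <- floor(cr - ext):ceiling(cr + ext)
          ccl <- floor(cc - ext):ceiling(cc + ext)
          sub <- expand.grid(r = rr, c = ccl)
          dr <- sub$r - cr; dc <- sub$c - cc
          u <- dc * cos(phis[i]) + dr * sin(phis[i])
          v <- -dc * sin(phis[i]) + dr * cos(phis[i])
          inside <- (u / aax)^2 + (v / bax)^2 <= 1
          if (!any(inside)) next
          pr <- sub$r[inside]; pc <- sub$c[inside]
          g <- minGapPx
          er <- max(1, min(pr) - g):min(imageSize, max(pr) + g)
          ec <- max(1, min(pc) - g):min(imageSize, max(pc) + g)
          if (any(excl[er, ec])) next
          mask[cbind(pr, pc)] <- TRUE
          excl[er, ec] <- TRUE
          painted[i] <- length(pr) * ps^2
          centers[i, ] <- c(cr, cc)
          ok <- TRUE
          break
        }
        if (!ok) stop("packing failure: could not place ellipse ", i)
      }
    } else {
      mask <- matrix(FALSE, imageSize, imageSize)
      areas <- painted <- numeric(0)
      centers <- matrix(numeric(0), 0, 2)
    }
    img <- background + amp * mask +
      stats::rnorm(imageSize^2, 0, spec@noiseSigma * amp)
  })
  list(image = img, mask = mask,
       truth = list(count = as.integer(nAdhesions),
                    areas_requested_um2 = areas,
                    areas_painted_um2 = painted, centers = centers))
}

# Distance from point grid to a segment (p1, p2), all in pixel coords.
.segDist <- function(pr, pc, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- ((pr - p1[1]) * vx + (pc - p1[2]) * vy) / max(len2, 1e-12)
  t <- pmin(1, pmax(0, t))
  sqrt((pr - (p1[1] + t * vx))^2 + (pc - (p1[2] + t * vy))^2)
}

# Minimum distance between two segments (sampled; adequate for placement).
.segSegDist <- function(a1, a2, b1, b2, nSamp = 25) {
  t <- seq(0, 1, length.out = nSamp)
  pa <- cbind(a1[1] + t * (a2[1] - a1[1]), a1[2] + t * (a2[2] - a1[2]))
  min(.segDist(pa[, 1], pa[, 2], b1, b2))
}

#' Synthetic actin-filament image with known segment lengths
#'
#' Renders straight, non-intersecting, antialiased line segments of
#' near-normal lengths over a noisy background. Ground truth records the
#' exact endpoint-to-endpoint lengths.
#'
#' @param nFilaments Number of segments (0 gives pure background).
#' @param meanLength Mean segment length in um (default 19.1).
#' @param lengthCV Coefficient of variation of the lengths (default 0.25).
#' @param spec A \linkS4class{GeneratorSpec}.
#' @param imageSize Image side in px (default 768).
#' @param widthUm Filament stroke width in um (default 0.5).
#' @param matchMean Rescale sampled lengths so their mean equals
#'   \code{meanLength} exactly (default TRUE).
#' @param minGapPx Minimum distance between segments in px (default 4).
#' @param maxTries Placement retries per segment (default 300).
#' @param background,foreground Intensity levels (0.1 / 0.9).
#' @return List with \code{image} and \code{truth} (lengths_um,
#'   mean_length_um, endpoints).
#' @export
genFilamentImage <- function(nFilaments, meanLength = 19.1, lengthCV = 0.25,
                             spec = GeneratorSpec(), imageSize = 768,
                             widthUm = 0.5, matchMean = TRUE, minGapPx = 4,
                             maxTries = 300, background = 0.1,
                             foreground = 0.9) {
  ps <- spec@pixelSize
  amp <- foreground - background
  halfw <- widthUm / ps / 2
  withr::with_seed(spec@seed, {
    img <- matrix(background, imageSize, imageSize)
    endpoints <- vector("list", nFilaments)
    lengths <- numeric(0)
    if (nFilaments > 0) {
      lens <- stats::rnorm(nFilaments, meanLength, lengthCV * meanLength)
      lens <- pmax(lens, 0.3 * meanLength)
      if (matchMean) lens <- lens * meanLength / mean(lens)
      placed <- list()
      for (i in seq_len(nFilaments)) {
        lpx <- lens[i] / ps
        ok <- FALSE
        for (try in seq_len(maxTries)) {
          ang <- stats::runif(1, 0, pi)
          margin <- halfw + 3
          cr <- stats::runif(1, margin + lpx / 2, imageSize - margin - lpx / 2)
          cc <- stats::runif(1, margin + lpx / 2, imageSize - margin - lpx / 2)
          p1 <- c(cr - lpx / 2 * sin(ang), cc - lpx / 2 * cos(ang))
          p2 <- c(cr + lpx / 2 * sin(ang), cc + lpx / 2 * cos(ang))
          if (min(p1, p2) < margin || max(p1, p2) > imageSize - margin) next
          clear <- TRUE
          for (q in placed) {
            if (.segSegDist(p1, p2, q[[1]], q[[2]]) < 2 * halfw + minGapPx) {
              clear <- FALSE; break
            }
          }
          if (!clear) next
          # paint over the segment's bounding box with a soft edge
          rr <- max(1, floor(min(p1[1], p2[1]) - halfw - 2)):
            min(imageSize, ceiling(max(p1[1], p2[1]) + halfw + 2))
          ccl <- max(1, floor(min(p1[2], p2[2]) - halfw - 2)):
            min(imageSize, ceiling(max(p1[2], p2[2]) + halfw + 2))
          sub <- expand.grid(r = rr, c = ccl)
          dd <- .segDist(sub$r, sub$c, p1, p2)
          val <- pmin(1, pmax(0, halfw + 0.5 - dd))
          sel <- val > 0
          idx <- cbind(sub$r[sel], sub$c[sel])
          img[idx] <- pmax(img[idx], background + amp * val[sel])
          placed[[length(placed) + 1]] <- list(p1, p2)
          endpoints[[i]] <- rbind(p1, p2)
          lengths <- c(lengths, sqrt(sum((p2 - p1)^2)) * ps)
          ok <- TRUE
          break
        }
        if (!ok) stop("packing failure: could not place filament ", i)
      }
    }
    img <- img + stats::rnorm(imageSize^2, 0, spec@noiseSigma * amp)
  })
  list(image = img,
       truth = list(lengths_um = lengths,
                    mean_length_um = if (length(lengths)) mean(lengths) else NA_real_,
                    endpoints = endpoints))
}

# Cache for the telegraph calibration tables.
.cellmechCache <- new.env(parent = emptyenv())

#' Telegraph-process persistence calibration
#'
#' Mapping from the per-frame direction-flip probability q of a 1D
#' constant-step telegraph walk to the expected confinement ratio
#' (persistence) at a given track length. No closed form exists at finite
#' duration, so the mapping is computed once by seeded simulation (internal
#' fixed seed, independent of generator seeds) and memoized; it is
#' deterministic for a given number of steps.
#'
#' @param nSteps Number of steps per track.
#' @param qGrid Flip probabilities to tabulate. The default grid is dense
#'   at small q, where the confinement ratio falls steeply (a handful of
#'   expected flips per track already destroys most of the net
#'   displacement).
#' @param nRep Simulated tracks per grid point (default 4000).
#' @return data.frame with columns \code{q} and \code{mean_cr} (expected
#'   confinement ratio), non-increasing in q (enforced after simulation).
#' @export
telegraphCalibration <- function(nSteps,
                                 qGrid = c(0, 5e-4, 0.001, 0.002, 0.003,
                                           0.005, 0.0075, 0.01, 0.015,
                                           0.02, 0.03, 0.05, 0.075, 0.1,
                                           0.15, 0.2, 0.3, 0.4, 0.5, 0.65,
                                           0.8, 0.98),
                                 nRep = 4000) {
  key <- sprintf("telegraph_%d_%d_%d", nSteps, length(qGrid), nRep)
  if (!is.null(.cellmechCache[[key]])) return(.cellmechCache[[key]])
  mean_cr <- withr::with_seed(190346731L, vapply(qGrid, function(q) {
    flips <- matrix(stats::rbinom(nRep * (nSteps - 1), 1, q), nRep)
    dirs <- cbind(1, 1 - 2 * flips)
    dirs <- t(apply(dirs, 1, cumprod))
    mean(abs(rowSums(dirs)) / nSteps)
  }, numeric(1)))
  # enforce monotonicity against simulation jitter
  mean_cr <- rev(cummax(rev(mean_cr)))
  tab <- data.frame(q = qGrid, mean_cr = mean_cr)
  .cellmechCache[[key]] <- tab
  tab
}

#' Synthetic 1D channel migration tracks
#'
#' Telegraph-process walks along the channel axis: constant step magnitude
#' \code{meanSpeed * frameInterval}, direction flipping with a per-frame
#' probability calibrated (via \code{\link{telegraphCalibration}}) so the
#' expected confinement ratio at the given duration equals
#' \code{persistenceTarget}. A target of 1 produces zero flips and
#' persistence exactly 1.
#'
#' @param nTracks Number of tracks.
#' @param meanSpeed Speed in um/min (every track's mean speed is exactly
#'   this, since steps have constant magnitude).
#' @param persistenceTarget Expected confinement ratio, in [0, 1].
#' @param frameInterval Frame interval in minutes (default 5).
#' @param duration Track duration in minutes (default 600, i.e. ten hours).
#' @param spec A \linkS4class{GeneratorSpec} (only the seed is used).
#' @return List with \code{tracks} (list of \linkS4class{Track}) and
#'   \code{truth} (q, per-track realized persistence, targets).
#' @export
genTracks <- function(nTracks, meanSpeed, persistenceTarget,
                      frameInterval = 5, duration = 600,
                      spec = GeneratorSpec()) {
  if (persistenceTarget < 0 || persistenceTarget > 1)
    stop("persistenceTarget must lie in [0, 1]")
  nSteps <- round(duration / frameInterval)
  if (nSteps < 2) stop("duration must cover at least 2 frames")
  stepLen <- meanSpeed * frameInterval
  if (persistenceTarget == 1) {
    q <- 0
  } else {
    cal <- telegraphCalibration(nSteps)
    if (persistenceTarget < min(cal$mean_cr) - 1e-9)
      stop(sprintf(
        "infeasible persistenceTarget %.3g: minimum achievable at this duration is %.3g",
        persistenceTarget, min(cal$mean_cr)))
    cr <- rev(cal$mean_cr); qq <- rev(cal$q)
    keep <- !duplicated(cr)
    cr <- cr[keep]; qq <- qq[keep]
    q <- if (length(cr) >= 4) {
      # monotone cubic inverse of the calibration curve
      f <- stats::splinefun(cr, qq, method = "hyman")
      min(max(f(min(max(persistenceTarget, min(cr)), max(cr))), 0), 1)
    } else {
      stats::approx(cr, qq, xout = persistenceTarget, rule = 2)$y
    }
  }
  times <- seq(0, by = frameInterval, length.out = nSteps + 1)
  withr::with_seed(spec@seed, {
    tracks <- lapply(seq_len(nTracks), function(i) {
      d0 <- sample(c(-1, 1), 1)
      flips <- stats::rbinom(nSteps - 1, 1, q)
      dirs <- d0 * cumprod(c(1, 1 - 2 * flips))
      pos <- cumsum(c(0, dirs * stepLen))
      Track(sprintf("sim_%03d", i), times, matrix(pos, ncol = 1))
    })
  })
  realized <- vapply(tracks, function(tr)
    suppressWarnings(persistence(tr)), numeric(1))
  list(tracks = tracks,
       truth = list(q = q, mean_speed_um_min = meanSpeed,
                    persistence_target = persistenceTarget,
                    realized_persistence = realized))
}

#' Deterministic straight track with exact mean speed
#'
#' @param speed Speed in um/min.
#' @param frameInterval Frame interval in minutes (default 5).
#' @param duration Duration in minutes (default 600).
#' @param trackId Identifier.
#' @return A \linkS4class{Track} whose \code{meanSpeed} equals \code{speed}
#'   exactly and whose persistence is exactly 1.
#' @export
straightTrack <- function(speed, frameInterval = 5, duration = 600,
                          trackId = "straight") {
  times <- seq(0, duration, by = frameInterval)
  Track(trackId, times, matrix((times - times[1]) * speed, ncol = 1))
}

#' Deterministic two-leg track with exact persistence
#'
#' Moves \code{forward} um in one direction, then \code{back} um in the
#' opposite direction, in equal per-leg steps: the confinement ratio is
#' exactly (forward - back) / (forward + back).
#'
#' @param forward,back Leg lengths in um.
#' @param frameInterval Frame interval in minutes (default 5).
#' @param nForward,nBack Frames per leg (defaults 10 and 5).
#' @param trackId Identifier.
#' @return A \linkS4class{Track}.
#' @examples
#' persistence(twoLegTrack(87, 13))  # 0.74
#' @export
twoLegTrack <- function(forward, back, frameInterval = 5, nForward = 10,
                        nBack = 5, trackId = "twoleg") {
  pos <- c(seq(0, forward, length.out = nForward + 1),
           forward - seq_len(nBack) * back / nBack)
  times <- seq(0, by = frameInterval, length.out = length(pos))
  Track(trackId, times, matrix(pos, ncol = 1))
}

#' Render a channel movie from tracks
#'
#' Draws each track's position per frame as a Gaussian nucleus spot along a
#' horizontal channel, over a noisy background, for testing
#' \code{\link{trackNuclei}}. All tracks must share the same time base.
#' 1D tracks run along the image x axis at mid-height. Positions are
#' shifted by a common offset so everything is in frame; the ground truth
#' returned is in movie coordinates.
#'
#' @param tracks List of \linkS4class{Track} objects (possibly empty).
#' @param spec A \linkS4class{GeneratorSpec}.
#' @param spotSigmaUm Nucleus spot sigma in um (default 3).
#' @param frameHeightPx Frame height in px (default 64).
#' @param nFramesBlank Number of frames when \code{tracks} is empty
#'   (default 10).
#' @param laneSpacingUm Vertical spacing between 1D tracks' channel lanes
#'   in um (default 25; keeps nuclei separable).
#' @return List with \code{frames} (list of matrices), \code{truth}
#'   (tracks in movie coordinates) and \code{offset_um}.
#' @export
genChannelMovie <- function(tracks, spec = GeneratorSpec(),
                            spotSigmaUm = 3, frameHeightPx = 64,
                            nFramesBlank = 10, laneSpacingUm = 25) {
  ps <- spec@pixelSize
  if (length(tracks) == 0) {
    frames <- withr::with_seed(spec@seed, lapply(seq_len(nFramesBlank),
      function(k) matrix(stats::rnorm(frameHeightPx^2, 0.1,
                                      spec@noiseSigma), frameHeightPx)))
    return(list(frames = frames, truth = list(), offset_um = 0))
  }
  times <- tracks[[1]]@times
  for (tr in tracks) if (!isTRUE(all.equal(tr@times, times)))
    stop("all tracks must share the same time base")
  nT <- length(tracks)
  is1d <- vapply(tracks, function(tr) ncol(tr@positions) == 1, logical(1))
  xs <- lapply(tracks, function(tr) tr@positions[, 1])
  allx <- unlist(xs)
  marginUm <- 4 * spotSigmaUm
  offset <- marginUm - min(allx)
  widthPx <- ceiling((diff(range(allx)) + 2 * marginUm) / ps)
  heightPx <- if (all(is1d) && nT > 1)
    ceiling(nT * laneSpacingUm / ps) else frameHeightPx
  laneY <- function(i) {
    if (all(is1d) && nT > 1) (i - 0.5) * laneSpacingUm
    else heightPx * ps / 2
  }
  sig <- spotSigmaUm / ps
  rows <- matrix(seq_len(heightPx), heightPx, widthPx)
  cols <- matrix(seq_len(widthPx), heightPx, widthPx, byrow = TRUE)
  truth <- lapply(seq_len(nT), function(i) {
    tr <- tracks[[i]]
    if (is1d[i])
      Track(tr@trackId, tr@times,
            cbind(tr@positions[, 1] + offset, laneY(i)))
    else
      Track(tr@trackId, tr@times,
            cbind(tr@positions[, 1] + offset, tr@positions[, 2]))
  })
  frames <- withr::with_seed(spec@seed, lapply(seq_along(times), function(k) {
    fr <- matrix(0.1, heightPx, widthPx)
    for (i in seq_len(nT)) {
      p <- truth[[i]]@positions[k, ]
      cx <- p[1] / ps; cy <- p[2] / ps
      fr <- fr + 0.8 * exp(-((cols - cx)^2 + (rows - cy)^2) / (2 * sig^2))
    }
    fr + stats::rnorm(heightPx * widthPx, 0, spec@noiseSigma)
  }))
  list(frames = frames, truth = truth, offset_um = offset)
}
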
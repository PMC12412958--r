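#' @include AllClasses.R AllGenerics.R imaging-utils.R
NULL

.stepLengths <- function(track) {
  d <- diff(track@positions)
  sqrt(rowSums(d^2))
}

#' Per-track path metrics
#'
#' \code{pathLength}: total traveled distance (sum of step lengths, um).
#' \code{netDisplacement}: straight-line distance between first and last
#' position (um). \code{meanSpeed}: path length divided by elapsed time
#' (um/min). All three are invariant to reversing the time axis.
#'
#' @param track A \linkS4class{Track}.
#' @return A single numeric value.
#' @name trackMetrics
NULL

#' @rdname trackMetrics
setMethod("pathLength", "Track", function(track) sum(.stepLengths(track)))

#' @rdname trackMetrics
setMethod("netDisplacement", "Track", function(track) {
  p <- track@positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
})

#' @rdname trackMetrics
setMethod("meanSpeed", "Track", function(track) {
  pathLength(track) / (max(track@times) - min(track@times))
})

#' Directional persistence of a track
#'
#' The primary definition is the confinement ratio: net displacement over
#' path length, bounded in [0, 1] by the triangle inequality, exactly 1
#' for monotone motion and exactly 0 for a track that returns to its
#' origin. This matches the described semantics of a persistence that lies
#' between 0 (constantly changing direction) and 1 (no changes in
#' direction). The alternative `"mean_cosine"` method -- the mean cosine of
#' the turning angles between consecutive steps, rescaled from [-1, 1] to
#' [0, 1] -- is provided for sensitivity checks.
#'
#' A track with zero path length has undefined persistence: NA with a
#' warning.
#'
#' @param track A \linkS4class{Track}.
#' @param method `"confinement"` (default) or `"mean_cosine"`.
#' @return Persistence in [0, 1] (NA when undefined).
#' @examples
#' tr <- twoLegTrack(forward = 87, back = 13)
#' persistence(tr)  # (87 - 13) / (87 + 13) = 0.74
#' @export
setMethod("persistence", "Track",
  function(track, method = c("confinement", "mean_cosine")) {
    method <- match.arg(method)
    steps <- .stepLengths(track)
    if (method == "confinement") {
      pl <- sum(steps)
      if (pl == 0) {
        warning("zero path length: persistence undefined")
        return(NA_real_)
      }
      return(netDisplacement(track) / pl)
    }
    d <- diff(track@positions)
    keep <- steps > 0
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < 2) {
      warning("not enough moving steps for turning angles")
      return(NA_real_)
    }
    v1 <- d[-nrow(d), , drop = FALSE]
    v2 <- d[-1, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    (mean(cosang) + 1) / 2
  })

#' Per-track statistics table
#'
#' @param tracks A list of \linkS4class{Track} objects.
#' @param persistenceMethod Passed to \code{\link{persistence}}.
#' @return data.frame with track_id, mean_speed_um_min, persistence,
#'   path_length_um, net_displacement_um, n_frames.
#' @export
trackStats <- function(tracks, persistenceMethod = "confinement") {
  rows <- lapply(tracks, function(tr) {
    data.frame(track_id = tr@trackId,
               mean_speed_um_min = meanSpeed(tr),
               persistence = suppressWarnings(
                 persistence(tr, method = persistenceMethod)),
               path_length_um = pathLength(tr),
               net_displacement_um = netDisplacement(tr),
               n_frames = length(tr@times), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Speed-persistence correlation across tracks
#'
#' Pearson correlation between per-track mean speed and persistence.
#' Faster cells migrating more persistently show up as r > 0. With zero
#' variance in either variable the correlation is undefined: NA with a
#' warning.
#'
#' @param tracks A list of \linkS4class{Track} objects (>= 3 with defined
#'   statistics).
#' @return Correlation coefficient in [-1, 1] (NA when undefined), with
#'   attribute \code{n} (number of tracks used).
#' @export
speedPersistenceCorrelation <- function(tracks) {
  st <- trackStats(tracks)
  st <- st[is.finite(st$mean_speed_um_min) & is.finite(st$persistence), ]
  if (nrow(st) < 3) stop("need at least 3 tracks with defined statistics")
  if (stats::sd(st$mean_speed_um_min) == 0 || stats::sd(st$persistence) == 0) {
    warning("zero variance: correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(st$mean_speed_um_min, st$persistence)
  }
  attr(r, "n") <- nrow(st)
  r
}

#' Track nuclei in a time-lapse movie
#'
#' Simplified nucleus tracker for channel movies: per-frame Otsu threshold
#' and 8-connected components give nucleus centroids; detections are linked
#' frame-to-frame by greedy nearest-neighbour assignment (closest pairs
#' first) gated at \code{maxStep}; unmatched detections start new tracks;
#' tracks with gaps are terminated, not gap-closed; tracks shorter than 3
#' frames are discarded. Frames with no detections simply terminate all
#' open tracks.
#'
#' Positions are reported in um as (x, y) = (col, row) * pixelSize, using
#' the pixel-center convention.
#'
#' @param movie List of grayscale frames (numeric matrices) or a 3D array
#'   [row, col, frame]; >= 3 frames.
#' @param pixelSize Pixel size in um/px.
#' @param frameInterval Frame interval in minutes (default 5).
#' @param maxStep Maximum linkable displacement per frame in um.
#' @param minNucleusArea Minimum detection area in um^2 (default 2).
#' @return List of \linkS4class{Track} objects (2D positions).
#' @export
trackNuclei <- function(movie, pixelSize, frameInterval = 5, maxStep,
                        minNucleusArea = 2) {
  if (is.array(movie) && length(dim(movie)) == 3)
    movie <- lapply(seq_len(dim(movie)[3]), function(k) movie[, , k])
  if (length(movie) < 3) stop("need at least 3 frames")
  if (maxStep <= 0) stop("maxStep must be positive")
  detect <- function(frame) {
    if (diff(range(frame)) <= 0)
      return(matrix(numeric(0), ncol = 2))
    th <- .threshold(frame, method = "otsu")
    mask <- frame > th
    # nuclei are sparse bright spots; a threshold that keeps a large part
    # of the frame means there is nothing but background texture
    if (!any(mask) || mean(mask) > 0.3) return(matrix(numeric(0), ncol = 2))
    st <- .labelStats(.label8(mask))
    st <- st[st$npix * pixelSize^2 >= minNucleusArea, , drop = FALSE]
    cbind(st$centroid_col * pixelSize, st$centroid_row * pixelSize)
  }
  open <- list()    # each: list(points = matrix, frames = integer)
  done <- list()
  for (k in seq_along(movie)) {
    det <- detect(movie[[k]])
    nOpen <- length(open)
    nDet <- nrow(det)
    assignedTrack <- rep(FALSE, nOpen)
    assignedDet <- rep(FALSE, nDet)
    if (nOpen > 0 && nDet > 0) {
      last <- do.call(rbind, lapply(open, function(tr)
        tr$points[nrow(tr$points), ]))
      dmat <- outer(seq_len(nOpen), seq_len(nDet), Vectorize(function(i, j)
        sqrt(sum((last[i, ] - det[j, ])^2))))
      ord <- order(dmat)
      for (o in ord) {
        if (dmat[o] > maxStep) break
        i <- ((o - 1) %% nOpen) + 1
        j <- ((o - 1) %/% nOpen) + 1
        if (assignedTrack[i] || assignedDet[j]) next
        open[[i]]$points <- rbind(open[[i]]$points, det[j, ])
        open[[i]]$frames <- c(open[[i]]$frames, k)
        assignedTrack[i] <- TRUE
        assignedDet[j] <- TRUE
      }
    }
    # unmatched open tracks terminate (no gap closing)
    if (any(!assignedTrack)) {
      done <- c(done, open[!assignedTrack])
      open <- open[assignedTrack]
    }
    # unmatched detections start new tracks
    for (j in which(!assignedDet)) {
      open[[length(open) + 1]] <- list(points = det[j, , drop = FALSE],
                                       frames = k)
    }
    if (nDet == 0 && length(open) > 0) {
      done <- c(done, open)
      open <- list()
    }
  }
  done <- c(done, open)
  done <- Filter(function(tr) length(tr$frames) >= 3, done)
  lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    Track(sprintf("track_%03d", i),
          times = (tr$frames - 1) * frameInterval,
          positions = tr$points)
  })
}

#' Read tracks from a CSV table
#'
#' Long-format track table with columns \code{track_id}, \code{frame},
#' \code{time_min}, \code{x_um} and optionally \code{y_um}. Tracks with
#' fewer than 3 samples are dropped.
#'
#' @param path CSV path or data.frame in the same layout.
#' @return List of \linkS4class{Track} objects.
#' @export
readTracks <- function(path) {
  tab <- if (is.character(path))
    utils::read.csv(path, stringsAsFactors = FALSE) else path
  need <- c("track_id", "frame", "time_min", "x_um")
  if (!all(need %in% names(tab)))
    stop("track table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(tab$track_id)) {
    sub <- tab[tab$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    if (nrow(sub) < 3) next
    pos <- if ("y_um" %in% names(sub)) cbind(sub$x_um, sub$y_um)
           else matrix(sub$x_um, ncol = 1)
    out[[length(out) + 1]] <- Track(id, sub$time_min, pos)
  }
  out
}

#' Write tracks to a CSV table
#'
#' @param tracks List of \linkS4class{Track} objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeTracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(track_id = tr@trackId,
                     frame = seq_along(tr@times),
                     time_min = tr@times,
                     x_um = tr@positions[, 1])
    if (ncol(tr@positions) == 2) df$y_um <- tr@positions[, 2]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
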
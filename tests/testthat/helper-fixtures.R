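# Shared fixture builders. Everything is generated in code; no binary data.

# Antialiased disk image (linear one-pixel edge ramp).
diskImage <- function(n, radiusPx, centerRow = (n + 1) / 2,
                      centerCol = (n + 1) / 2, bg = 0.1, fg = 0.9) {
  r <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((r - centerRow)^2 + (cl - centerCol)^2)
  matrix(bg + (fg - bg) * pmin(1, pmax(0, radiusPx - d + 0.5)), n, n)
}

# Antialiased straight line segment image; p1, p2 in (row, col) pixel coords.
lineImage <- function(n, p1, p2, halfWidthPx = 1.25, bg = 0.1, fg = 0.9) {
  sub <- expand.grid(r = seq_len(n), c = seq_len(n))
  dd <- cellmech:::.segDist(sub$r, sub$c, p1, p2)
  matrix(bg + (fg - bg) * pmin(1, pmax(0, halfWidthPx + 0.5 - dd)), n, n)
}

# Piecewise-linear retract curve through (distance, force) nodes, with a
# compressive ramp before the contact point. Heights in um, forces in nN.
piecewiseCurve <- function(nodes, contact = 0.5, setpoint = 8, zLength = 50,
                           dz = 0.01) {
  h <- seq(0, zLength, by = dz)
  d <- h - contact
  f <- numeric(length(h))
  f[d < 0] <- setpoint * (-d[d < 0]) / contact
  pos <- d >= 0
  f[pos] <- approx(nodes[, 1], nodes[, 2], xout = d[pos], rule = 2)$y
  ForceDistanceCurve(h, f, "retract", zLength = zLength)
}

# Exact permutation p value of the two-sided pooled-t statistic for small
# samples, by full enumeration of group assignments.
permutationP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  tObs <- abs(twoSampleT(a, b)$t)
  tAll <- apply(idx, 2, function(i) {
    abs(twoSampleT(pooled[i], pooled[-i])$t)
  })
  mean(tAll >= tObs - 1e-12)
}
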
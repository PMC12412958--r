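---
title: "cellmech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellmech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

cellmech quantifies four cell-mechanical assays — micropattern-based
contractility screening, single-cell force spectroscopy, focal-adhesion /
cell-shape morphometry, and confined 1D migration — together with seeded
synthetic-data generators that emulate each assay's raw data with known
ground truth. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic benchmarks do and do not
demonstrate about real data.

## 1. Contractile energy of a cell on a micropattern

A cell adherent to a circular fibronectin micropattern on a soft
polyacrylamide gel contracts the pattern from area $A_i$ to $A_f$. The
substrate is a linear-elastic solid with Young's modulus $E$ (10 kPa by
default) and Poisson ratio $\sigma$ (0.5, incompressible). The energy the
cell stores in the substrate is

$$U \;=\; g(\sigma)\, E\, \frac{3\sqrt{\pi}}{32}\,
  \left(A_i^{3/2} - A_f^{3/2}\right),
\qquad
g(\sigma) \;=\; \frac{\left(2(1-\sigma)+\sigma\right)^2 - \sigma^2}
                      {(1-\sigma)(1+\sigma)} \;=\; \frac{4}{1+\sigma}.$$

### Why this grouping of the prefactor

The two sub-expressions $(1-\sigma)(1+\sigma)$ and
$(2(1-\sigma)+\sigma)^2-\sigma^2 = 4(1-\sigma)$ can a priori be grouped as
$g$ or $1/g$; the elastostatics decides. The substrate displacement obeys
the equilibrium (Navier) equation
$(1-2\sigma)\Delta\vec u + \vec\nabla(\vec\nabla\cdot\vec u) = 0$, which
for a purely radial field $u(r)$ reduces (independently of $\sigma$) to
$u'' + u'/r - u/r^2 = 0$ with the analytic solution family
$u(r) = Ar + B/r$. Outside the pattern the admissible decaying branch is
$u = B/r$, a *pure shear* field ($\varepsilon_{rr} = -\varepsilon_{\theta\theta}$),
whose energy density is proportional to the shear modulus
$G = E/\bigl(2(1+\sigma)\bigr)$. Any energy built from such a field must
therefore carry $1/(1+\sigma)$ — which selects $g = 4/(1+\sigma)$. The
reciprocal grouping, $\propto E\,(1+\sigma)$, cannot arise as the energy of
any positive-definite isotropic plane-elastic field and is rejected.

### The quadrature oracle

`contractileEnergyOracle()` recomputes the energy by an independent route:

1. `navierRadialSolution()` solves the equilibrium equation numerically on
   the annulus $[s, f\!\cdot\! s]$ (pattern radius $s$, outer cutoff factor
   $f$) with prescribed boundary displacements;
2. `strainEnergyQuadrature()` integrates the plane-stress energy density
   $w = \frac{E}{2(1-\sigma^2)}\left(\varepsilon_{rr}^2 +
   \varepsilon_{\theta\theta}^2 + 2\sigma\varepsilon_{rr}
   \varepsilon_{\theta\theta}\right)$ over the annulus with an effective
   depth $h(r)$;
3. the contraction is treated as a family of self-similar states indexed by
   the pattern radius (edge displacement proportional to $s$), whose
   quadrature energy scales as $E\,s^3/(1+\sigma)$; the contractile energy
   is the difference of the state energies at $r_i$ and $r_f$, which
   reproduces the $A^{3/2}$-difference structure of the closed form.

Two thickness models are implemented. `half_space_scaling`
($h(r) = \kappa r$ with $\kappa = 3\pi/16$) encodes that a surface
deformation of lateral scale $r$ recruits substrate to a depth
proportional to $r$; this is the model the closed form matches, and
$\kappa$ is the single geometric constant shared between the two routes
(the oracle independently validates the $\sigma$-dependence and the
$A^{3/2}$ structure, not $\kappa$ itself). `plane_stress_sheet` (constant
thickness) is provided for comparison and does *not* reproduce the closed
form — a thin bonded sheet stores energy with a different radial weighting.

```{r oracle}
gel <- ElasticSubstrate(youngModulus = 1e4, poissonRatio = 0.5)
def <- PatternDeformation(1000, 900)   # um^2
closed <- contractileEnergy(gel, def)
oracle <- contractileEnergyOracle(gel, def, outerFactor = 16, nPoints = 512)
c(closed_pJ = as.numeric(closed) * 1e12, rel_err = abs(oracle - closed) / closed)
```

Numerical choices: on the default log-spaced grid the three-point scheme
uses the exact discrete operator $u_{i-1} - 2\cosh(h)u_i + u_{i+1}$, whose
characteristic roots $e^{\pm h}$ are exactly the sampled analytic family,
so the solver is exact to rounding; the uniform grid uses standard
second-order central differences. The truncated outer field contributes an
$O(1/f)$ energy deficit (about 2% at the default cutoff factor 10), so the
oracle evaluates at $\{f, 2f, 4f\}$ and extrapolates quadratically in
$1/f$; with that extrapolation the two routes agree to better than
$10^{-4}$ across $(\sigma, A_i, A_f)$.

Units are SI (m, Pa, J) inside the model; the imaging layer converts to
µm² and pJ at the boundary. A final area larger than the initial one
(segmentation jitter) yields a sign-flagged negative energy by default
rather than an error.

### From images to energy

`segmentPattern()` applies Gaussian pre-smoothing (σ = 1 px), a global
Otsu threshold (or a fixed fraction of the intensity range), keeps the
largest 8-connected component and fills holes; the area is the foreground
pixel count times the pixel area. `pacsEnergy()` segments the
reference/deformed pair and feeds the measured areas to
`contractileEnergy()` — the identical code path, no second formula.

Because the energy depends on the *small difference* of two large areas,
the pair is thresholded jointly by default (one Otsu threshold from the
pooled intensities of both smoothed images): any threshold bias then
shifts both areas equally and cancels in the difference. Independent
per-image thresholds remain available (`jointThreshold = FALSE`).

## 2. Single-cell force spectroscopy

A retract force–distance curve (piezo height in µm, force in nN;
positive = compressive) is reduced to four metrics:

* **baseline**: a first-degree trend fitted to the final 20% of the
  retract (guaranteed off-surface on a 50 µm retract) and subtracted; the
  residual standard deviation defines the baseline noise that all
  thresholds are expressed in;
* **contact point**: the height of the last zero crossing from the
  compressive side, located by interpolation; the search is restricted to
  before the global force minimum, since physical contact always precedes
  the deepest adhesion;
* **adhesion energy**: trapezoidal integral of $\max(0, -F)$ over
  tip–surface distance from contact to the end of the adhesive region,
  reported in pJ (1 nN·µm = 1 fJ);
* **adhesion force**: magnitude of the most negative force (µN);
* **rupture length**: distance from contact to the last sample whose
  filtered absolute force exceeds $k\sigma$ ($k = 3$ by default);
* **steps**: upward force jumps above `minJump` (default 5× noise) within
  a short window — discrete unbinding events.

All detectors operate on running-median-filtered force (windows 5–11
samples, i.e. 0.05–0.11 µm at the default 10 nm sampling). At a realistic
2 nN noise level, a force-free 20 µm tail contains thousands of samples,
so isolated $>3\sigma$ excursions are near-certain; per-sample
thresholding would routinely misplace the rupture point, while short
medians suppress these excursions and displace step edges by at most two
samples. The integration variable is piezo height, not tip–sample
separation: with a 2 N/m lever and sub-µN forces the deflection correction
is sub-nm and neglected.

The curve generator (`genForceCurve()`) constructs a retract whose
noise-free form has *analytically exact* targets: a half-sine rise to the
peak force, a cosine relaxation to a plateau, and a staircase of seeded
unbinding steps ending exactly at the requested rupture distance; the
plateau level is solved in closed form from the energy constraint (an
inconsistent energy/force/rupture triple is rejected). Gaussian noise
(2 nN) and linear drift are added on top.

## 3. Morphometry

`quantifyParticles()` is the classic threshold-and-count quantification:
global threshold, 8-connected components, minimum-area filter
(0.1 µm² by default — far below the ~0.6–1.3 µm² mean focal-adhesion
sizes it is meant to protect). EBImage's labeling is 4-connected, so
diagonal-touching labels are merged with a union–find pass.

`cellShapeMetrics()` reports the spreading area, the aspect ratio of the
second-central-moment ellipse, and the circularity $4\pi A/P^2$. The
perimeter estimator matters: a plain 8-chain with $\sqrt2$ diagonal
weights overestimates a digital circle's perimeter by ~5.5% and biases
circularity to ~0.90 for a true disk. We therefore use the
corner-corrected chain-length estimator (weights 0.980 per axis step,
1.406 per diagonal step, −0.091 per direction change), which is accurate
to a few tenths of a percent for smooth boundaries and digitized straight
lines; the plain $\sqrt2$ weighting remains available for comparison.
Discretization can still push a disk's circularity marginally above 1
(values up to ~1.05 are within tolerance and are not clipped).

`measureFilaments()` (one of several defensible readings of a "mean
filament length" measurement, chosen because it is testable on synthetic
fixtures): Gaussian ridge smoothing, global threshold, Zhang–Suen
skeletonization, removal of junction pixels (crossing number ≥ 3 of the
8-neighborhood ring — raw neighbor counts misclassify staircase pixels),
and per-branch chain lengths with the calibrated weights. Skeleton ends
retract by roughly the stroke half-width, a −2 to −4% bias on 20 µm
filaments; steep-angle staircases can add a few percent. Both effects are
well inside the 10% recovery tolerance used in the benchmarks.

## 4. Confined migration

Tracks are time-stamped positions (µm, minutes; 5-min frames, ≥ 3
samples). `persistence()` is the **confinement ratio**: net displacement
over path length, exactly 1 for monotone motion and 0 for a track that
returns to its start — matching the described 0-to-1 semantics of a
directional persistence. The underlying tracking software's definition is
not specified in the original description, so the confinement ratio is the
primary reading and the mean turning-angle cosine (rescaled to [0, 1]) is
available behind `method = "mean_cosine"` for sensitivity checks.
`meanSpeed()` is path length over elapsed time. Channel tracks are 1D
(position along the channel axis); 10×10 µm or 5×5 µm channels are below
one cell diameter, so the transverse coordinate carries no information.

`trackNuclei()` is a deliberately simple, auditable tracker: per-frame
Otsu threshold and connected components give nucleus centroids (frames
where the threshold keeps > 30% of pixels are treated as empty — nuclei
are sparse spots); greedy nearest-neighbour linking, closest pairs first,
gated at `maxStep`; gaps terminate tracks (determinism over completeness);
tracks shorter than 3 frames are dropped. In channels, crossings are rare
and greedy linking is essentially exact; it is not a general-purpose 2D
tracker.

The track generator is a 1D telegraph process: constant step magnitude
`meanSpeed × frameInterval`, direction flipping with per-frame probability
$q$. There is no closed form for the expected confinement ratio of a
finite track, so the mapping $q \mapsto E[\mathrm{CR}]$ is computed once
by seeded simulation (internal fixed seed, 4000 tracks per grid point,
grid dense at small $q$ where a handful of expected flips already destroys
most of the net displacement), memoized, and inverted by monotone cubic
interpolation. A cohort of 200 tracks matches a persistence target of 0.74
to within ±0.05; single tracks scatter widely, as real cells do.

## 5. The synthetic generators — what they do and do not show

Every generator is a pure function of a `GeneratorSpec` (seed, pixel size,
noise fraction): identical specs give bit-identical output, and every
generator returns a machine-readable ground-truth record that the
round-trip benchmarks consume. Defaults are chosen to emulate the study
conditions: 10 kPa incompressible gel, 1000 µm² patterns, 50 µm retracts
at 8 nN setpoint with 2 nN force noise, 5-minute frames over ten hours,
5% intensity noise on images. Image pixel sizes: 0.1 µm/px for
focal-adhesion fields (63× high-NA imaging), 0.2 µm/px for patterns and
filament fields (the larger structures tolerate coarser sampling and keep
the benchmark images tractable). The pattern generator jitters the disk
center uniformly within one pixel — real patterns land anywhere on the
sensor lattice — which keeps pixel-counting discretization error zero-mean
across a cohort.

The generators emulate the *statistical structure* each analysis step
assumes: antialiased geometric primitives over Gaussian-noise backgrounds,
analytically controlled force wells, constant-step telegraph walks. They
do not emulate uneven illumination, out-of-focus light, organelle texture,
curved or crossing filaments, cell debris, or detector shot noise.
Passing the round trips therefore demonstrates that the estimators are
unbiased and correctly calibrated on data satisfying their assumptions —
not that segmentation thresholds transfer to arbitrary real micrographs.
Absolute particle counts on real images remain threshold-dependent; the
benchmarks are recovery benchmarks, by design.

Benchmark problem sizes: contractility cohorts of 38 (control-sized) and
22 (blebbistatin-sized) image pairs at 256² px; ten 512² focal-adhesion
fields of ~30–40 adhesions; one 768² filament field of 30 filaments;
5001-sample force curves; 200-track migration cohorts. These mirror the
study's group sizes where reported.

## 6. Statistics

`twoSampleT()` implements the independent two-sample, two-sided t test
from the closed form — pooled-variance by default, which is the default
behavior of the standard independent-samples t routine named in the
original methods; Welch by flag. Degenerate zero-variance/equal-mean input
returns p = 1 with a flag. `significanceLabel()` maps p to
n.s. / * / ** / *** at thresholds 0.05 / 0.01 / 0.001 with strict
inequalities (p = 0.05 is n.s.). The figure-caption convention that uses
0.005 for the third star is supported through the `thresholds` argument;
the methods-section convention is the default. No multiple-testing
correction is applied by default, matching the reported procedure;
`p.adjust` can be applied downstream. `groupSummary()` pools per-cell
values across repeats (the reported group n's correspond to pooled cells)
and compares every group against a named control.

## 7. Known limitations

* The contractility model assumes a circular pattern, purely radial
  deformation, and a substrate response captured by the half-space depth
  scaling; irregular deformations and finite gel thickness are out of
  scope (no finite-element modelling, no traction-force microscopy).
* The force-curve layer does not parse vendor binary formats, calibrate
  spring constants, or fit tether models; it consumes plain TSV exports.
* The filament measurement reports skeleton-branch lengths of
  well-separated straight structures; dense, curved or crossing networks
  will fragment at junctions.
* The tracker has no gap closing and no global assignment; it is built for
  sparse channel movies.
* Persistence as confinement ratio depends on track duration; comparisons
  are only meaningful at matched observation times (the generators use a
  common ten-hour duration for this reason).
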
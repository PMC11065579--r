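---
title: "Quantifying fibrous ECM architecture, spectra, and mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrous ECM architecture, spectra, and mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmquant)
```

ecmquant implements the quantification stack used when comparing fibrous
extracellular-matrix states — e.g. healthy versus irradiated mammary
tissue, or the decellularized-ECM hydrogels derived from them — across
electron micrographs, Raman spectra, AFM indentation, rheology, and
fluorescence-based cell assays.  This vignette documents the models, the
tunable parameters and their defaults, the synthetic data used for
validation, and the numerical choices a user should know about.

## Fiber-network architecture

### Segmentation

`segment_fibers()` expects bright fibers on a dark background (flip with
`invert = TRUE`) and applies, in order:

1. min–max intensity normalization, which makes every downstream
   descriptor invariant to affine intensity transforms of the input;
2. a 3×3 median filter (`median_window = 3`; larger odd windows go through
   a generic rank filter);
3. locally adaptive Otsu thresholding on `otsu_tile_px = 64` tiles with
   bilinear interpolation of tile thresholds.  A tile may only *lower* the
   threshold when its upper intensity tail reaches above the global Otsu
   level — otherwise local Otsu would happily split pure background noise
   in fiber-free tiles.  Images smaller than one tile fall back to global
   Otsu;
4. one morphological closing with a 3-px disc and removal of connected
   specks below `min_object_px = 16`;
5. a half-maximum refinement: only pixels above the midpoint between the
   local background and the local profile peak are kept.  The local peak
   is a running maximum over a `peak_radius_px = 15` disc, corrected by
   2.5 median-absolute-deviations of the background for the upward bias
   of a running maximum under noise.  This step is removal-only (the
   background cannot gain pixels) and matters because the *diameter*
   descriptor is defined on the full-width-at-half-maximum support of a
   fiber's cross-section; a plain Otsu cut sits below the half-maximum
   and systematically widens thick fibers by ~10 %.

A constant image yields an empty mask with a warning rather than an
error, so batch runs survive blank fields.

### Skeleton graph

`skeletonize_network()` thins the mask with the Zhang–Suen two-pass
algorithm (compiled code), then traces the skeleton into junction-pixel
clusters (8-connected components of pixels with ≥ 3 neighbours, after
merging clusters within `node_merge_px = 3`) and branch segments.  Three
bookkeeping choices proved important:

* **Spur handling is bookkeeping, not surgery.**  Terminal branches
  shorter than `spur_prune_px = 2` are dropped from the segment table but
  their pixels stay in the skeleton.  Erasing spur pixels and re-thinning
  looks tidier but cascades: each re-thinning reshapes junction cores and
  spawns new spurs, and in dense fields it can eat a crossing entirely.
* **Pass-through clusters are merged away.**  Thinning occasionally emits
  a two-pixel staircase along a perfectly ordinary fiber; the resulting
  "junction" has exactly two incident branches.  Such clusters are
  contracted so a straight fiber remains a single segment with one
  orientation and one length.
* **Optional graph pruning is off by default.**  A refinement stage that
  drops segments longer than 3× the median (with a Gabriel-graph variant
  behind `prune = "delaunay"`) is retained for compatibility with
  Delaunay-based network refiners, but on a skeleton-traced graph the
  long branches *are* the fibers: enabling it destroys junction incidence
  and halves the recovered intersection count, so the default is
  `prune = "none"`.

Per-segment diameter is `2·median(EDT) − 1` px sampled along the segment
(EDT = Euclidean distance transform of the mask; the −1 accounts for the
half-pixel overshoot on each side, and the median resists inflation where
a segment passes a junction zone).  Per-segment orientation is the
principal axis of the segment's pixel cloud, in `[0, 180)`.

### Counting intersections

Thinning does not map fiber crossings to junction pixels one-to-one: an X
of thick fibers splits into two Y-junctions joined by a short bridge, a
shallow crossing stretches into a band, and several fibers meeting in a
blob merge into one multi-arm cluster.  `estimate_intersections()`
therefore counts crossings by junction-complex arithmetic: clusters joined
by bridges shorter than 2.5× the local diameter (capped at 15 px) form a
complex; a lone cluster with $A$ arms counts $\binom{A/2}{2}$ crossings
(1 for an X, 3 for a compact three-fiber blob) and a lone three-arm
cluster counts ½ (one half of a stretched crossing); an extended
multi-cluster complex counts $(A-2)/2$, which scores a bridged Y–Y pair
once and a chain of crossings once per crossing.  `n_nodes` and the node
density descriptor report this estimate.

### Descriptors

`compute_descriptors()` returns one tidy row per image:
covered area ratio (mask fraction), porosity (its exact complement), the
length-weighted mean segment diameter, node density per mm², the mean
area of background components that do not touch the image border (in mm²,
matching the conventional reporting unit, and in µm², the natural scale
at these magnifications), and the orientation index
$100·\bar R$, where $\bar R$ is the length-weighted mean resultant of the
doubled segment orientations — 0 % for an isotropic network, 100 % for a
perfectly aligned one.  Excluding border-touching pores avoids biasing
the histogram with components whose true extent is unknown.

## Raman pipeline

The order is smooth → subtract background → normalize.

* `raman_smooth()` is the standard two-parameter Savitzky–Golay filter,
  order 5 over a 15-point window; "order 5" refers to the local
  polynomial, so polynomials up to degree 5 pass through at machine
  precision, including at the edges.
* `raman_subtract_background()` is the iterative modified polynomial fit:
  fit a degree-7 polynomial (orthogonal basis on a centred coordinate for
  conditioning), clip the working spectrum to the fit wherever it lies
  above it, repeat.  The per-round change of the fitted baseline decays
  roughly geometrically, so the stopping rule bounds the *projected total
  remaining change* (last change divided by one minus the estimated decay
  ratio) at `threshold = 1e-4` of the input intensity range.  Bounding
  the projected remainder rather than the last step is what makes the
  operation idempotent to within the same threshold — with a plain
  last-step rule, a second application can still drift by several times
  the threshold.  Non-convergence at `max_iter` returns the result with a
  warning flag rather than failing.
* `raman_normalize()` rescales to `[0, 1]`, attaining both endpoints
  exactly.
* `peak_ratios()` reads band intensities as the windowed maximum within
  ±10 1/cm of the amide I (1650), amide III (1265), and lipid (1300)
  positions — robust to small calibration shifts — and reports
  amide-I/lipid and amide-III/lipid ratios, flagging (not `Inf`-ing) a
  non-positive lipid band.
* `raman_pca()` is column-mean-centred PCA by SVD with no variance
  scaling (the spectra are already min–max normalized), loading signs
  fixed so each component's largest-magnitude loading is positive.

## Contact mechanics and rheology

`fit_hertz()` fits
$F(z) = b + \tfrac{4}{3}\,\frac{E}{1-\nu^2}\sqrt{R}\,\max(z - z_0, 0)^{3/2}$
by profiled least squares: for any contact point $z_0$ the model is linear
in $(b, a)$, so a 60-point grid over candidate contact points followed by
a 1-D golden-section refinement of $z_0$ gives a global, derivative-free
fit with the Hertzian amplitude constrained non-negative.  Joint
estimation of the contact point avoids the low-SNR bias of threshold-based
contact detection.  A curve with no force rise above baseline returns a
flagged failure, never an exception.  Defaults follow common spherical
probes: tip radius 5 µm, ν = 0.5; units (nm, nN, µm) are converted to SI
internally.

`stiffness_histogram()` pools fitted moduli into fixed-width bins and
detects modes as plateau-aware local maxima with a prominence of at least
20 % of the tallest bin (clusters straddling a bin edge count once).

`youngs_from_rheology()` averages the final 20 % of a time sweep (the
gelation plateau) and converts with $E = 2G(1+\nu)$; following the tissue
rheology workflow this pipeline mirrors, $G = G' + G''$, with the
conventional $|G^*| = \sqrt{G'^2 + G''^2}$ available via
`g_mode = "magnitude"`.  With ν = 0.5, E = 3G.

## Cell metrics

Morphology uses the standard definitions — elongation index =
major/minor axis of the second-moment equivalent ellipse (with the 1/12
pixel-integration correction), form factor = 4πA/P² — with the perimeter
from Vossepoel–Smeulders corner-corrected chain codes, which keeps a
rasterized disc within a few percent of form factor 1.  Objects touching
the border are flagged; sub-5-px objects are flagged degenerate with `NA`
ratios.  Colocalization is exact integer pixel arithmetic on binary
masks.  The invasion index divides invading by migrating cell counts and
refuses a zero denominator.  Marker positivity thresholds per-object mean
intensities, by Otsu over the means by default.  The analyte fold-change
filter keeps ratios at or *above* 1.5 (the cutoff is inclusive) and
excludes, with a flag, analytes whose control value cannot form a ratio.

## Synthetic data and what validation does (and does not) show

Every generator is a pure function of its spec (seeded; bit-identical on
repeat) and emits its ground truth alongside the data.

* **Fiber images**: straight strokes with Gaussian cross-sections
  (FWHM = the declared diameter, so "true diameter" is well defined),
  composited by maximum, plus i.i.d. Gaussian noise.  Directions follow
  an axial von Mises law (κ = 0 isotropic, κ = ∞ parallel).  The default
  field is 512×512 px at 0.1 µm/px (a 51 µm field) with 6-µm strokes —
  chosen once so that fields of 10–100 fibers span sparse to dense but
  remain in the regime where individual fibers are resolvable; the
  density-gradient experiment uses 20-µm strokes so that enclosed pores
  exist at every condition.
* **Spectra**: Gaussian peaks at 1265/1300/1650 1/cm over a smooth
  polynomial fluorescence hump, on a 600–2000 1/cm grid.  The grid
  deliberately includes the peak-free 1800–2000 region, as real
  fingerprint scans do: polynomial background estimation needs peak-free
  anchor stretches, and without one the broad amide-I band pulls the fit
  up by ~2 %.
* **Force curves**: exact Hertz law beyond the contact point, constant
  baseline before it.
* **Mask pairs**: exact positive-pixel and overlap counts by
  construction.

Validated at these conditions (the test suite and
`scripts/acceptance.R` recompute all of this): per-cell mean diameter
recovery within 15 % over a width × density × alignment grid; pooled
intersection counts within 20 % of brute-force crossing counts of the
truth geometry (single sparse cells expect ~1 crossing and are
integer-noise dominated, hence the pooled comparison); pooled isotropic
orientation index below 5 % and parallel fields above 90 %; noiseless
spectral peak recovery within 2 % and within 5 % under noise; Hertz
round-trips at 1e-6 relative and median errors ≈ 1 % under 5 % force
noise; exact rheology and cell-metric arithmetic; bit-identical replay of
every stage from its emitted config.

What this does **not** show: real SEM contrast (charging, depth of field,
secondary-electron texture), curved or branching fibers, true
tissue-spectrum complexity (overlapping bands, cosmic rays, detector
response), cantilever artefacts, or segmentation of real cell images
(masks are accepted as input; only a minimal Otsu labelling helper is
provided for fixtures).  Recovery rates quoted here bound the algorithmic
error of the pipeline, not the measurement error of any instrument.

## Known limitations

* Intersection counting degrades gracefully but measurably in heavily
  fused fields (coverage ≳ 40 %): arms of true crossings merge before
  reaching the junction and cannot be recovered by any skeleton method.
* Lengthwise-merged parallel fibers are reported at their merged width;
  at high alignment and density this inflates the mean diameter by up to
  ~10 %.
* The modified-polyfit background estimator retains an irreducible pull
  of 1–2 % under very broad peaks near a grid edge; widening the grid
  into peak-free regions is the effective remedy.
* Orientation statistics on a single sparse image carry finite-sample
  noise of order $100/\sqrt{n_\text{segments}}$ percent; compare groups
  on pooled segments or many fields.
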
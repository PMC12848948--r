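---
title: "Quantifying condensates and nucleoprotein filaments from images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensates and nucleoprotein filaments from images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpstools)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate. All quantitative statements about accuracy refer to properties
that the package's test suite itself computes on generated scenes.

## 1. The droplet-edge statistic for phase separation

Brightfield images of phase-separated samples show condensed droplets as
refractile disks with sharp rims when in focus. The degree of phase
separation in one field of view is measured as an *edge fractional area*:

1. Estimate the intensity gradient with the 5-tap Farid–Simoncelli
   separable derivative pair (a smoothing prefilter `p` along one axis, an
   antisymmetric derivative kernel `d` along the other), applied as
   correlation with reflection padding at the borders; the per-pixel
   statistic is the magnitude `sqrt(gx^2 + gy^2)`.
2. Compute the standard deviation σ of the gradient image.
3. Count pixels with magnitude strictly greater than `k_sd * σ`
   (default `k_sd = 10`) and divide by the field area.

Sharp rims of in-focus droplets exceed 10σ; defocused droplets (gradients
attenuated by blur) and the smooth component of optical speckle do not.
A sample is summarized by the mean and sample SD of the per-field
fractions (five fields by convention), then normalized by the mean of a
non-phase-separating reference imaged with the same optics, which removes
the fixed speckle contribution. The reported error is the sample SD
divided by the reference mean; the reference normalized against itself is
exactly 1, the "no droplets" line on every state diagram.

Open choices, and how they were resolved:

* **Magnitude vs signed derivative.** The threshold is applied to the
  gradient *magnitude*. Thresholding a signed component would halve the
  rim response and make the statistic orientation-dependent; `k_sd` is
  exposed so sensitivity can be explored.
* **Per-field vs pooled σ.** σ is computed per field of view. The
  filtered image being thresholded is a per-field object, and per-field σ
  makes fields exchangeable under the later mean/SD summary.
* **Degenerate input.** A constant field has σ = 0 and returns fraction
  0 rather than raising; a zero-mean *reference* is rejected with an
  error, because the normalization is then undefined (the reference must
  contain the shared optical background).
* **Working regime.** The statistic presumes sparse edges: because the
  threshold scales with σ of the whole gradient image, rim pixels
  occupying more than roughly 1 % of the field inflate σ enough that the
  statistic saturates and eventually reverses. The generator defaults
  (512 × 512 fields, droplet radii 2–3.5 px) keep the tested droplet-count
  range 0–50 inside the monotone regime; this saturation is a known
  limitation of the statistic itself, not of the implementation.

The generator renders in-focus droplets as a dark interior disk with a
bright ~2 px rim (the typical defocused-brightfield appearance),
defocused droplets as the same template blurred by `defocus_sigma_px`,
and the optical background as a *fixed* texture — a smooth Gaussian
random field plus a sparse set of sharp speckle points (dust/deposit
artifacts) — that is a deterministic function of `speckle_seed` alone.
The sharp points are what give a droplet-free reference its small nonzero
edge fraction; without them the reference would measure exactly zero and
the normalization would be meaningless. Sample and reference share the
texture by sharing `speckle_seed`, exactly as real sample/reference pairs
share their optics.

## 2. Condensate segmentation and partition coefficients

The partition coefficient of a client molecule is
`PC_i = mean(I[condensate i]) / mean(I[dilute phase])`; PC = 1 means no
preferential interaction. Means, not medians, are used throughout, and no
background subtraction is applied — consequently PC is invariant to
multiplicative gain but *not* to additive offsets, which users must keep
in mind when cameras add a baseline.

Segmentation offers two modes behind one interface:

* **threshold** (default): Otsu's method on the largest-scale smoothed
  image splits condensate from background pixels; the final cut is the
  midpoint of the two class means applied to the *smallest*-scale
  smoothed image. The two-stage scheme matters: thresholding the heavily
  smoothed image directly would dilate every mask by roughly the
  smoothing radius, while the midpoint cut places the boundary at the
  half-intensity contour. Connected components (8-connected by default)
  smaller than `min_area_px = 9` are discarded as noise specks.
* **trained**: a deliberately simple supervised pixel classifier — a
  feature-whitened nearest-centroid rule (per-class means, pooled
  regularized per-feature variances) over the same feature family an
  interactive pixel-classification tool uses: per-scale smoothed
  intensity, gradient magnitude, and scale-normalized
  Laplacian-of-Gaussian (default scales 1, 2, 4 px). It requires at
  least 20 annotated pixels per class. Full-covariance discriminants
  fitted to a few dozen annotated pixels proved unstable here (they
  misplace the boundary under photon noise and are singular on
  noise-free scenes); the diagonal rule is stable in both regimes. The
  trained mode is an interface stand-in, not a re-implementation of any
  external tool, and its masks are coarser than threshold masks near
  condensate edges.

The dilute phase is defined as all pixels outside every condensate after
dilating the mask by `exclusion_ring_px = 3` px, a conservative guard
against halo contamination; setting the ring to 0 reproduces the literal
"whole background" reading. The alternative reading — a local annulus per
droplet — was not adopted because a single global dilute phase matches
the singular "background intensity" concept and makes PCs comparable
across condensates in a field.

The condensate generator draws non-overlapping disks whose interior is
exactly `E × background`; a 1-px linear edge band blends interior into
background. Ground-truth interior masks exclude that band, which is what
makes noise-free ratio checks exact; the full-footprint mask (band
included) is also returned for segmentation-overlap checks, where the
band's pixel ownership is undefined by construction and is excluded from
the comparison. Poisson noise scenes at background 100 counts give
per-condensate PC scatter of a few percent; the test suite checks that
ground-truth-mask estimates recover E within Monte-Carlo error, and that
segmentation-based estimates land within a few percent below E (boundary
pixels of the segmented footprint dilute the interior mean — documented
bias, visible in the README example).

## 3. Desk-scale single-molecule localization

Blinking movies are modeled with memoryless kinetics: each binding site
is ON in each frame independently with probability `p_on`. Explicit
imager binding/unbinding kinetics are deliberately out of scope — the
fitter only needs statistically realistic frames, and no kinetic
parameters would constrain such a model here. An ON event draws a Poisson photon
count; each photon's landing position is drawn from the emitter's
Gaussian PSF and binned into camera pixels. This is exactly a multinomial
over pixel-integrated Gaussian weights, so the frame sum equals the drawn
photon count up to truncation at the field border — photon conservation
is an identity, not an approximation. Baseline and Gaussian read noise
are added last.

Fitting uses a pixel-integrated (erf-based) 2-D Gaussian plus constant
background over a 9 × 9 px window, minimized by Levenberg–Marquardt with
residuals scaled by the square root of the model — the Gaussian
approximation of the Poisson likelihood. The weighting matters: unweighted
least squares is ~40 % less efficient at the photon counts tested
(N = 1000), enough to violate the σ/√N precision budget. Candidates are
3 × 3 local maxima above `bg + k_detect` robust noise SDs (median/MAD);
any two candidates within one fitting window are both dropped rather than
risking biased double fits — acceptable because all scenes of interest
here are low-density. Non-converged fits are dropped and counted in a QC
report, never raised as errors. The localization precision estimate is
the simple Thompson-style `σ_PSF/√N`, ignoring background and pixelation
corrections; adequate at desk scale and clearly labeled as an estimate.

Rendering is a 2-D histogram at `sr_pixel_nm` (default 10 nm), optionally
blurred per localization with its precision; kernels are renormalized
after truncation (including at image borders) so rendering conserves
mass exactly.

## 4. Filament tracing and puncta spacing

The filament pipeline formalizes analyses that are often done by eye:

1. **Density mask** — render the localization table (10 nm pixels),
   smooth with a 30 nm Gaussian, threshold at `min_density = 0.012`
   smoothed counts per pixel, then morphologically close (3 px box), fill
   holes smaller than 25 px, and drop components below 30 px. The
   threshold default sits near 10 % of the theoretical ridge density for
   the default scene parameters (1 localization per 10 nm, 15 nm
   localization σ): low enough that Poisson dips along a filament rarely
   break the mask, high enough to keep the footprint narrow. Hole filling
   is *size-limited* on purpose: the interior of a closed circular
   filament is a large hole that must survive.
2. **Skeleton** — Zhang–Suen thinning (implemented in the package; no
   installed dependency provides binary thinning), followed by a
   skeleton-graph construction in which diagonal adjacencies triangulated
   by an orthogonal neighbor are dropped — without this standard
   simplification, staircase chains read as junction clusters. Spur
   branches shorter than `prune_spur_nm = 100` nm are removed
   iteratively.
3. **Traces** — the skeleton graph (nodes: endpoints and junctions,
   edges: pixel chains) is decomposed longest-path-first: repeatedly take
   the longest unused chain and greedily extend both ends through
   junctions by the longest available continuation. The decomposition is
   deterministic given the mask. Cycles become closed traces (first point
   equals last).
4. **Contour length** — the raw pixel chain is smoothed by a 7-point
   moving average (wrapping for cycles) before summing Euclidean segment
   lengths; this removes both digitization staircase and
   localization-jitter wiggle, which otherwise inflate circle lengths by
   ~5 %. Open ends are then extended along the end tangent to the
   midpoint between the skeleton end and the mask boundary: thinning
   retracts an open end by about the mask half-width while density
   smoothing extends the mask a little less far beyond the true end, so
   the true end lies between the two; the midpoint splits the residual
   bias. The test suite verifies ≤ 5 % length error for circles (2πR) and
   lines, and ≤ 10 % additivity for k-unit tethers, at the default scene
   conditions (unit 2.1 µm).
5. **Clusters** — a connected mask component is a cluster if it holds at
   least two traces or any skeleton junction (degree ≥ 3). A lone circle
   is a cycle without junctions and is *not* a cluster.
6. **Puncta spacing** — second-channel localizations are grouped into
   puncta by single-linkage clustering cut at 75 nm (≈ 3× the default
   punctum σ), centroids are projected to the nearest trace vertex, and
   spacings are differences of sorted arc positions. Puncta farther than
   `assign_radius_nm = 150` nm from the trace are reported as unassigned,
   not errors. For a k-unit tether the generator places exactly k − 1
   junction puncta, so spacings exist for k ≥ 3; for k = 2 the recovery
   check is the lone punctum's arc position (one unit length from the
   end), which is the same geometric statement.

The filament generator draws arc-length-uniform localizations with
isotropic Gaussian jitter along lines, circles, or wormlike curves
(heading decorrelation length 30 µm), places filaments with a minimum
separation of 500 nm (fields of well-separated single complexes — the
regime in which per-filament statistics are meaningful), and models
bundles as m copies fanned about the curve midpoint so that bundle
members genuinely cross. Unit lengths can vary per filament
(`unit_length_sd_nm`), giving the single-filament population preset
(mean 2.1 µm, SD 0.4 µm) used in the parameter-recovery tests.

## 5. AFM stack processing

Height frames are leveled by subtracting a least-squares first-order
plane fitted to *all* pixels (per-scanline median leveling is available
behind `line_level`, off by default), then projected with the per-pixel
median across frames. Leveling is idempotent to numerical tolerance
(10⁻⁹ of the height range), the median is permutation-invariant in frame
order and uses the midpoint convention for even counts, and — for odd,
noise-free stacks — the projection is exactly unchanged by fewer than
half the frames being corrupted, which is why the generator refuses
`outlier_frames ≥ n_frames / 2`. Sparse tall features bias the all-pixel
plane fit by an amount bounded by their height × area fraction × fit
leverage; the tests quantify this against a masked-background oracle fit.
Only the two explicitly specified steps are implemented; scanner-specific
correction chains are out of scope.

## 6. What the generators do and do not emulate

The generators reproduce the *statistical structure* each analysis relies
on: sharp vs blurred edges over a fixed optical background; exact
enrichment ratios with Gaussian or Poisson noise; arc-length-uniform
localizations with Gaussian precision; per-frame Bernoulli blinking with
Poisson photons; tilted, noisy height frames with outliers. They do not
emulate realistic optics (no full PSF model, no aberrations), stage
drift, multi-emitter overlap at high density, condensate polydispersity
beyond disk shapes, filament persistence-length physics, or AFM tip
convolution. Passing tests therefore demonstrate correctness of the
*computations* under controlled conditions, not robustness to every
artifact of real microscopes; on real data the usual caveats (drift
correction, uneven illumination, antibody labeling efficiency) apply
upstream of this package.

## 7. Numerical and interface conventions

* Images are numeric matrices; rows index y, columns x; continuous
  coordinates are 0-based with pixel centers at integers; physical units
  are nm via `pixel_size_nm`, lengths reported in µm where conventional.
* Every stochastic generator derives all randomness from one `seed`
  argument through an arithmetic seed-splitting scheme; identical
  `(spec, seed)` give bit-identical output, and the global RNG state of
  the caller is never touched.
* Image sets travel as multi-page TIFF with a JSON sidecar carrying the
  intensity scale and pixel size (baseline TIFF stores [0, 1]).
  Localization tables round-trip through CSV (Parquet optionally, via
  arrow); an HDF5 dialect is not provided in this build. AFM stacks
  round-trip through plain-matrix text.
* Problem sizes used by the test suite — 512² brightfield fields, 400²
  condensate fields with 50 condensates per Monte-Carlo batch, 200-repeat
  fitter calibrations, 30-filament populations — were chosen as the
  smallest sizes at which the Monte-Carlo checks have useful power.
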
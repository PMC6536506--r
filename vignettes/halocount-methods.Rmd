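---
title: "Counting low-abundance proteins by single-molecule spots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting low-abundance proteins by single-molecule spots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

At fewer than ~10 copies per cell, a protein's fluorescence is barely above
cellular autofluorescence, and bulk-intensity quantification is dominated by
background and labelling artefacts. Direct counting sidesteps this: if every
labelled molecule in a chemically fixed cell appears as one immobile
diffraction-limited spot, the per-cell copy number is simply the number of
spots. `halocount` implements that measurement and its two companion
analyses — the photobleaching check that spots really are single
fluorophores, and the geometric simulation of how crowding makes the count
an underestimate.

The pipeline assumes:

* rod-shaped cells well modelled as spherocylinders (cylinder of radius
  *r* capped by two hemispheres), lying flat in the focal plane;
* at most one dye per protein molecule (a self-labelling tag binding a
  single organic fluorophore), so spots map 1:1 to molecules up to
  resolution effects;
* fixed cells: no molecular motion during the exposure;
* a z-stack of 4–5 planes spaced 200 nm covering the ~1 um cell depth, with
  most autofluorescence in the first plane.

## Cell segmentation and the newborn filter

Cells are found in the autofluorescence channel. The image is smoothed
(Gaussian, `smooth_sigma` = 1 px), the Sobel gradient magnitude is computed,
and pixels above a robust global threshold — median + `grad_k` (default 6)
MAD-based SDs of the gradient image — form the edge map, which is dilated
(disc radius `morph_radius` = 2 px), hole-filled, eroded back and labelled.
Regions below `min_area` (50 px) or touching the image border are removed.

Two departures from the classic gradient-threshold recipe are deliberate.
First, the threshold is robust rather than a histogram split (e.g. Otsu):
on a blank noise field the gradient histogram is unimodal and a histogram
split labels large spurious foreground, whereas the robust rule adapts to
the noise floor and returns zero regions — the behaviour a counting pipeline
must have on empty fields. Second, smoothing before the gradient roughly
doubles the edge signal-to-noise ratio, making single-field detection
reliable at modest contrast.

A consequence worth knowing: the thresholded edge band straddles the true
cell boundary, so segmented masks carry a halo of roughly 1.5 px per side
and measured lengths overestimate pole-to-pole truth by ~0.4–0.6 um at
0.16 um/px. We keep the generous mask deliberately — spot-to-cell assignment
is by mask membership, and molecules sit all the way to the membrane — and
accept the bias in the length estimate, which is shared by any
edge-detection segmentation of this type. The newborn filter
(`filter_newborn()`, strict length < 3.5 um) therefore acts on measured, not
true, length; in simulations some true newborn cells measure above the
cutoff and are dropped, which thins the sample without biasing counts
(cell length and copy number are independent in the generator).

Manual curation of mis-segmented cells is replaced by a reproducible
exclusion list keyed on `cell_id`; every excluded cell appears in the run
report with its reason. Coordinates throughout are 1-based (row, col) pixel
indices — the R convention — with pixel centers at integer positions;
`crop_around()` returns the offset such that `full = crop + offset` exactly.

For concentration measurements (`segment_by_intensity()`), the fluorescence
image itself is segmented: background is removed by subtracting a
morphological opening (disc radius 15 px, larger than a cell width), the
difference is smoothed, and the threshold is fitted to the "non-cell"
intensity distribution — median + 5 MAD-SDs of the lower 80% of pixels.
Each component is then trimmed of its lowest-intensity 20% of pixels
(`low_fraction`, configurable), which helps split touching cells;
`mean_intensity_per_area()` is the per-cell concentration proxy.

## Spot counting

The z-stack is collapsed by maximum projection *excluding the first plane*,
which carries most of the autofluorescence. Around each cell centroid a
30 x 35 px crop is taken (median-padded at borders so the band-pass sees no
edge step). The crop is band-pass filtered in the Crocker–Grier style:
convolution with a normalized Gaussian (sigma = sqrt(2) x `noise_size`,
the convention of the standard particle-pretracking kernels) minus a boxcar
average of half-width `feature_size` (default 7 px), negatives clipped.
A spot is a pixel that is maximal within its 6 x 6 px window and exceeds
the local threshold. The even window has no center pixel: neighbourhood
offsets run −3..+2 in each direction, and plateaus are broken
topmost-then-leftmost, so peak calling is deterministic. Peaks are assigned
to the cell whose *mask* contains them — not the crop — which resolves
overlapping crops of neighbouring cells.

### The local threshold

The threshold statistic is the one genuinely open design choice. Computing
median + k·MAD on the *band-passed* crop is self-defeating: after zero
clipping the majority of pixels are 0 and the MAD collapses, and even
pre-clipping, k = 3 sits near the expected maximum of ~10^3 correlated
noise pixels, admitting occasional false maxima on blank fields. The
default therefore takes the noise scale from the *raw* crop:
threshold = `threshold_k` x 1.4826 x MAD(raw crop), applied to the
zero-baseline band-passed image (`threshold_source = "raw"`). This anchors
specificity to the camera noise floor — blank-field band-pass maxima sit
~4x below it — at the cost of a higher sensitivity floor: a spot must rise
roughly 20 raw-noise SDs above background at its peak to survive the
band-pass attenuation of an undersampled PSF (sigma ≈ 0.53 px at
0.16 um/px). With organic dyes at 1–2 s exposures, real spots exceed this
floor by an order of magnitude. `threshold_source = "bandpass"` restores
the band-passed-crop statistic for users who want it.

### Resolution geometry

Because the 6 x 6 window suppresses the dimmer of two peaks whenever their
pixel offsets both lie in −3..+2, two spots can only both survive if their
*Chebyshev* pixel distance is at least 4 px (0.64 um) — the caller's hard
resolution floor, anisotropic in the image axes. This is why the synthetic
generator's "well-separated" mode (`min_separation_2d`,
`separation_metric = "chebyshev"`) constrains the Chebyshev distance of the
projected molecule positions *in the image frame* (the constraint is not
rotation-invariant, so it is evaluated after applying the cell's
orientation). Constrained placement starts from a uniform draw and applies
pairwise repulsion with re-projection into the cell body; the result is a
spread-out, non-uniform configuration — which is precisely what
"well-separated" means. When a drawn copy number cannot be packed at the
requested separation (for Poisson(5) in a 2.4–3.0 um cell this happens for
the upper Poisson tail, roughly N ≥ 8), the field generator redraws that
cell's count; the recorded ground truth is always what was actually placed,
so recovery comparisons remain unbiased even though the realized counts are
Poisson conditioned on geometric feasibility.

## Photobleaching-step analysis

`extract_trace()` reports, per frame, the mean intensity in a circular
aperture (radius 3 px) minus the *median* of a 5–8 px annulus — the median
resists contamination by neighbouring spots. `count_steps()` locates change
points by binary segmentation under a piecewise-constant least-squares
model and selects the model order with the penalized criterion
`n log(RSS/n) + penalty * k * log(n)` (penalty = 3). Steps are then kept
only if downward with height at least `min_step`; by default `min_step` is
3x the frame-to-frame noise SD (`mad(diff(x))/sqrt(2)`), low enough not to
reject genuine steps at step SNR 5 while the order penalty already
suppresses spurious change points on flat traces. The analysis is invariant
under constant offsets, reports all-downward steps only, and is exercised
at 0/1/2-fluorophore truth in the test suite (the two-step case emulating a
tandem double tag). No blinking or other photophysics is modelled.

## The undercounting simulation

Molecules are placed uniformly in the spherocylinder by a volume-weighted
choice between the cylinder and the two caps (cap probability
(4r/3)/(L + 4r/3)); the rejection sampler in a bounding box is kept in the
tests as the independent oracle, along with a 64-bin equal-volume
chi-square uniformity check. Projection to 2D drops the optical-axis
coordinate. Clustering at the diffraction limit `eps` (default 0.25 um)
uses minimum cluster size 1, under which density clustering reduces exactly
to connected components of the eps-proximity graph; the implementation is a
union-find over pairwise Euclidean distances, cross-checked in the tests
against single-linkage hierarchical clustering cut at eps and against a
literal brute-force union-find.

`simulate_undercount()` sweeps a Poisson-mean grid (default 0.5–15 by 0.5),
default 10,000 cells per grid point, with newborn-like geometry (lognormal
total length, median 2.5 um, truncated to [1.5, 3.5) um, radius 0.5 um —
typical dimensions for newborn *E. coli*; the radius and length
distribution are configurable because real strains differ).
`bias_threshold()` interpolates the λ at which relative undercounting of
the mean crosses `max_relative_bias` (default 5%, a conventional
"negligible bias" level exposed as a parameter). With these defaults the
threshold lands in the low single digits: a simple pair-collision estimate
— merge probability per molecule pair ≈ pi·eps²/A ≈ 0.09 for a newborn
footprint A ≈ 2.3 um², hence relative bias ≈ λ·p/2 — predicts λ* ≈ 1, and
the Monte-Carlo curve computed by the acceptance script agrees. Averages
are therefore near-faithful only for copy numbers of a few per cell; by ten
per cell, more than a quarter of molecules merge. The simulation models a
hard resolution radius only: no PSF-shape-dependent resolvability and no
localization noise on positions.

## The synthetic generator: what it does and does not emulate

`render_zstack()` draws each molecule as a *pixel-integrated* 2D Gaussian
(exact pixel sums via the normal CDF, so a noiseless in-focus molecule
integrates to `photons_per_molecule` to better than 1%), with width
sigma(dz) = `psf_sigma` x (1 + `defocus_scale`·|dz|) growing linearly with
defocus; planes sit at (p−1) x 200 nm and a cell resting on the coverslip
spans z in [0, 2r]. Noise is Poisson shot noise on background + signal
followed by Gaussian read noise. Defaults: 0.16 um/px (100x objective with
16 um camera pixels), psf_sigma 0.084 um (0.21 λ/NA at λ = 580 nm,
NA = 1.45, consistent with a ~250 nm two-point limit), background 100
counts, read noise 2 counts, 5000 photons/molecule/plane — a bright organic
dye at ~1 s exposures. Plane 1 additionally carries a uniform in-cell haze
(default 40 counts) so the skip-first-plane rule is exercised;
`render_autofluorescence()` elevates cell footprints by 100 counts for the
segmentation channel.

Not emulated: EMCCD excess-noise factor and gain calibration, 3D PSF
structure beyond the linear Gaussian defocus, autofluorescence texture
within cells, cell-to-cell brightness variability, uneven illumination,
focus drift, and cell growth or division. Passing tests on this generator
therefore demonstrate the correctness of the *algorithms* under a realistic
but idealized image model — not robustness to every real-microscope
artefact; the exclusion-list mechanism exists because real data still needs
a human veto.

## Statistics

`ks_two_sample()` computes D = max |ECDF difference| with the asymptotic
two-sided p-value (samples in the intended use are hundreds of cells;
p ≥ 0.05 reads "similar at the 5% level"). Counts are pooled across
replicates when distributions are compared. `aggregate_replicates()` bins
counts 0..`max_count` (tail pooled), averages per-bin proportions across
replicates, and reports spread as the SD across replicates by default with
an SEM option — figure legends in this field use both conventions, so both
are explicit. `dose_response()` summarizes per-condition mean intensity per
cell area, preserving condition order.

## Reproducibility, problem sizes, degenerate inputs

Every sampler takes an explicit seed and is bit-reproducible; pipeline runs
embed the configuration and its hash in the report, and reruns with the same
config and seed produce byte-identical CSVs. Configuration is YAML with
unknown keys rejected before any stage runs. Image I/O is 16-bit multi-page
TIFF with bit-exact round trips for integer data.

The shipped verification uses sizes chosen to give stable statistics at
interactive runtimes: 200 newborn cells across 10 fields for end-to-end
recovery; 10,000 cells per λ for the three-point detection-ratio
comparison and 2,000 per point for the 20-point bias curve; 500 traces for
bleach classification; 10^5 draws for sampler geometry; 1,000 random point
sets for the clustering oracle.

Degenerate inputs are defined, not accidental: empty fields segment to zero
regions; a constant image yields zero band-pass response, zero peaks and
zero intensity-segmentation regions; a single-pixel region has
length = width = one pixel; eps = 0 clustering returns every point as its
own cluster; an empty region table yields an empty counts table; a
zero-fluorophore trace reports zero steps.
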
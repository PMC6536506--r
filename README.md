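# halocount

Counting very low-abundance proteins (fewer than ~10 copies per cell) in
individual bacteria by single-molecule spot counting. When a cytoplasmic
protein carries a self-labelling tag bound to a bright organic dye, chemical
fixation stops its diffusion and every labelled molecule appears as one
diffraction-limited spot under conventional epifluorescence illumination.
Counting those spots per cell gives the absolute copy-number distribution —
no laser-based setup, no calibration against bulk fluorescence.

`halocount` implements the complete quantitative pipeline for fixed
rod-shaped bacteria (such as *E. coli*), for microscopists and quantitative
biologists who want reproducible, scriptable counting:

* **Cell segmentation** from the autofluorescence channel
  (smoothed-gradient edge evidence, dilate/fill/erode, region properties:
  area, perimeter, length, width) with a **newborn filter** (length < 3.5 um)
  so counts are not inflated by pre-division cells, and a reproducible
  exclusion-list mechanism in place of manual curation.
* **Spot counting**: maximum projection of the z-stack *excluding the first
  plane* (which carries most of the autofluorescence), a 30 x 35 px crop
  around each cell centroid, a Crocker–Grier-style spatial band-pass, and
  6 x 6 px local-maximum peak calling above a robust local threshold, with
  mask-based spot-to-cell assignment.
* **Photobleaching-step analysis** to verify single-fluorophore detection:
  background-subtracted spot traces and change-point counting by binary
  segmentation with a BIC-style penalty (a single dye bleaches in one step;
  a tandem double tag in two).
* **Undercounting simulation**: molecules placed uniformly in a
  spherocylinder, Poisson(λ) copies per cell, 2D projection, and clustering
  at the diffraction limit (eps ≈ 0.25 um, minimum cluster size 1 — exactly
  the eps-connected components), yielding detection-ratio curves versus λ and
  the largest λ with acceptable counting bias.
* **Statistics**: two-sample Kolmogorov–Smirnov comparison of count
  distributions, replicate aggregation with error bars, and dose–response
  summaries of mean fluorescence per cell area.
* **Synthetic microscopy generator**: spherocylindrical cells, Poisson copy
  numbers, pixel-integrated Gaussian PSFs with linear defocus across 4–5
  planes spaced 200 nm, shot + read noise, autofluorescence images and bleach
  traces — every stage of the pipeline is verifiable against known ground
  truth without microscope data.

## The counting model in brief

Per cell, the number of molecules N ~ Poisson(λ). A diffraction-limited
counter reports the number of *resolvable clusters* C ≤ N: two molecules
closer than the diffraction limit (~250 nm) in the 2D projection merge into
one spot. The detection ratio E[C]/E[N] is 1 at λ → 0 and decreases with
crowding; `bias_threshold()` reports the largest λ whose relative bias
1 − E[C]/E[N] stays within a tolerance (default 5%). For newborn-sized cells
this threshold sits in the low single digits, so direct counting is accurate
precisely in the low-abundance regime the method targets.

## Worked example

```r
library(halocount)

# a synthetic field with known ground truth: 12 newborn cells,
# Poisson(5) molecules each, well-separated high-SNR spots
f <- simulate_counting_field(12, 5, field_size = c(45, 45),
       length_distribution = list("uniform", min = 2.4, max = 3.0),
       min_separation_2d = 0.75, separation_metric = "chebyshev",
       rng_seed = 7)

run <- run_pipeline(f$autofluo, f$stack, field_id = "demo")
run
#> <halocount_run> demo: 12 segmented -> 9 newborn cells, 34 spots (mean 3.78/cell)
head(run$counts, 5)
#> # A tibble: 5 × 4
#>   field_id cell_id length_um n_spots
#>   <chr>      <int>     <dbl>   <int>
#> 1 demo           1      3.21       5
#> 2 demo           2      3.18       5
#> 3 demo           4      3.35       5
#> 4 demo           5      3.21       3
#> 5 demo           7      3.30       5
```

Twelve cells are segmented; nine pass the newborn length filter (measured
lengths include the segmentation halo, so some true newborns measure above
3.5 um and are dropped — enumerated in `run$report$dropped`). Per-cell
`n_spots` is the molecule count.

How badly would diffraction merge spots at higher expression?

```r
res <- simulate_undercount(undercount_config(lambda_grid = c(2, 5, 10),
         n_cells_per_lambda = 5000, rng_seed = 7))
res[, 1:4]
#>   lambda mean_true mean_detected detection_ratio
#> 1      2    2.0068        1.8312       0.9125
#> 2      5    4.9898        3.9904       0.7997
#> 3     10    9.9472        6.3550       0.6389
autoplot(res)
```

At λ = 2 about 9% of molecules merge; at λ = 10 more than a third do. Two
conditions are compared with the KS rule used for replicate validation:

```r
ks_two_sample(sample_poisson_counts(5, 200, rng_seed = 9),
              sample_poisson_counts(5, 200, rng_seed = 10))
#> # A tibble: 1 × 5
#>   statistic p_value   n_a   n_b similar
#> 1     0.095   0.327   200   200 TRUE
```

`D = 0.095` with `p = 0.33`: the two replicates are similar at the 5% level.

A command-line front end covering simulation, segmentation, counting,
bleach-step analysis, the undercounting simulation and KS comparison lives
at `inst/cli/halocount` (see `halocount config` for all defaults as YAML).

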
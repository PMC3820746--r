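---
title: "Quantifying cellularization fidelity from furrow-canal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cellularization fidelity from furrow-canal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(furrowquant)
```

## The assay

During *Drosophila* cellularization, plasma-membrane furrows ingress between
the ~6000 cortical nuclei of the syncytial blastoderm and partition the
embryo surface into a monolayer of mononucleate cells. In surface-view
confocal images taken at the depth of the furrow canals (the F-actin- and
Myosin-rich furrow tips), the canals form a bright, near-hexagonal network
whose tiles each enclose one nucleus. When an individual furrow fails or
regresses, the two flanking nuclei end up sharing one cell, and only a weak
residual link of furrow material marks where the boundary used to be.

`furrowquant` turns such images into fidelity metrics:

* the **mononucleate-cells-to-nuclei ratio** counted in fixed-area quadrats
  (1 in an intact embryo, below 1 when furrows fail),
* the **percentage of embryos displaying multinucleation** in a cohort,
* **furrow-canal intensity** (e.g. F-actin) per canal segment,
* and, for genetics, **embryo genotyping from RNA-FISH stacks** by counting
  nascent-transcription spots per nucleus.

## The six-step segmentation

The core of the package is a morphological procedure that extracts two masks
from one furrow-marker image:

1. **Coarse Gaussian smoothing** (`sigma_coarse_px`, default 4 px) retains
   only the coarse ridge structure.
2. **Mid threshold** on the smoothed image gives the preliminary
   *strong-network* mask: intact furrow canals only.
3. **Topology-preserving thinning** (Guo–Hall, implemented in compiled code)
   reduces it to a 1-px-wide skeleton. Thinning preserves the Euler number,
   is idempotent, and never leaves a 2×2 foreground block.
4. **Fine smoothing** (`sigma_fine_px`, default 1.5 px) plus a **low
   threshold** captures the weak residual links of failed furrows; closing
   (`close_radius_px`) joins broken links, thinning reduces them, and
   pruning removes spurs shorter than `min_link_length_px` and components
   disconnected from the main network (the two cleanup readings are
   independently switchable — both are defensible readings of "remaining
   disconnected links were removed", and the default applies both).
5. The thinned strong network plus the weak-link mask is **dilated and
   inverted**, holes are filled: the foreground is the candidate
   *nucleus-compartment* interiors.
6. A **high threshold** on the coarse-smoothed image flags saturated ridge
   blobs; compartment pixels under them are removed, and compartments
   touching the image border are discarded (partial cells cannot be scored).

Cells are the regions enclosed by the strong network alone; nucleus
compartments are the regions enclosed by strong plus weak links. Each
compartment is assigned to the cell it overlaps most, giving per-cell
nucleus counts; a cell with two or more compartments is multinucleate.

### Threshold selection

The original workflow selected the three thresholds manually per image. Here
they are resolved by a pluggable strategy, and every resolved value is
logged in the segmentation provenance. The default (`"otsu"`) is two-stage:

* stage 1 separates **background from all ridge signal** on the
  coarse-smoothed histogram — this is the step-4 *low* threshold, whose job
  is precisely to keep weak links (scaled by `low_threshold`, default 0.9,
  slightly inclusive so weak-link flanks are not clipped);
* stage 2, restricted to above-background pixels, separates **weak links
  from intact ridges** — the step-2 *mid* threshold. A single global Otsu
  would land between background and the weak links and leak failed furrows
  into the strong network.
* the step-6 *high* threshold is a multiple of the mid threshold
  (`high_threshold`, default 2.5) — only near-saturated blobs exceed it.

`"quantile"` and `"fixed"` strategies are available for manual control and
must satisfy low < mid < high.

Connectivity follows the standard duality: 8-connectivity for skeletons,
4-connectivity for compartments, so diagonal skeleton pixels cannot leak.
Images are indexed `[x, y]`, 1-based, with physical units derived from
`pixel_size_um`.

A guard aborts with a "no network found" error when the above-background
mask covers more than `max_network_fraction` (default 40%) of the image — a
structureless image thresholds near half coverage, a genuine ridge network
near a quarter — or when no compartment of plausible cell size
(`min_cell_area_px2`) survives.

## Quadrat counting and its bias

The ratio is counted in `quadrants_per_embryo` square windows of
`quadrant_area_um2` (defaults: two windows of 2835 µm²) at fixed fractional
positions; a window's ratio is (cells assayed with exactly one compartment) /
(compartments of assayed cells), and the embryo value is the window mean.
Two inclusion rules are provided:

* `"full"` (default): a cell is assayed only if it lies entirely inside the
  window. This prevents double counting, but because multinucleate cells
  are larger they are less likely to fit, which biases the ratio upward
  when failures are present.
* `"centroid"`: a cell is assayed if its centroid falls in the window — the
  standard size-unbiased quadrat rule, recommended for recovery studies and
  used by the package's own ratio-recovery validation.

Compartments that overlap no cell are excluded from the denominator and
reported (`n_unassigned`); whether the manual protocol counted such nuclei
is not stated anywhere we could verify, so the choice is logged rather than
guessed.

## The synthetic-embryo generator

No real images ship with the package, so validation rests on a generator
that emulates exactly the structure the procedure assumes:

* a **Voronoi tessellation of a jittered hexagonal lattice** (jitter ≤ 25%
  of the spacing) — surface views of the blastoderm are near-hexagonal;
* ridges of width `ridge_width_px` at unit amplitude; a planted fraction
  (`failure_fraction`) of interior edges carries only
  `weak_link_contrast` × that amplitude (default 0.3), the residual link the
  weak-link mask exists to catch;
* Gaussian blur (`blur_sigma_px`) and additive Gaussian read noise
  (`noise_sd`, default 0.09, i.e. ridge SNR ≈ 10), with optional Poisson
  shot noise. The default pixel size is 0.104 µm, the confocal sampling the
  assay was designed around.

Ground truth records nucleus centres, the failed-edge set, and the
cell-of-nucleus map obtained by merging tiles across failed edges; the
planted ratio is computed over interior tiles only, mirroring the border
exclusion of step 6. Boundary tiles are flagged and excluded. All
randomness flows from the config seed, and identical configs give
bit-identical images.

What the generator does **not** emulate: optics-accurate point-spread
functions, 3-D furrow geometry, intensity inhomogeneity across the field,
autofluorescence, or furrow ingression dynamics. Passing the recovery
suites therefore shows the algorithmic chain is correct under the stated
image model, not that thresholds transfer to any particular microscope.

## FISH genotyping

Embryos from a het × het cross are genotyped by RNA-FISH against nascent
transcripts: an active locus appears as a diffraction-limited nuclear spot,
so nuclei show 0, 1 or 2 sites for null, heterozygous and wild-type embryos.
The pipeline takes the maximum-intensity projection of a ~4 µm stack,
segments nuclei from the nucleus channel (Otsu, hole filling, optional
watershed split), detects spots as local maxima of the scale-normalised
Laplacian-of-Gaussian response at a fixed physical scale
(`spot_scale_um` = 0.3 µm), and assigns each spot to the nucleus under it.
The embryo's genotype follows the **maximum** spot count over nuclei
(0 → null, 1 → het, ≥2 → wt, capped at 2 only at assignment; raw counts are
kept for QC), with an insufficiency flag below 150 nuclei. The spot-response
threshold defaults to median + 10 × MAD of the response, floored at 5% of
the peak so a flat background cannot drag it to zero.

Two sites closer than the detection scale merge into one maximum; the
behaviour is pinned by a test (3 px apart resolves, 1 px does not) rather
than claimed to match manual counting of overlapping sister-chromatid
signals. Because per-site visibility draws are taken before position draws,
renders with the same seed are coupled across `p_detect`, and lowering
`p_detect` can only move calls toward fewer alleles.

The FISH renderer places ≥150 nuclei on a jittered grid at the ~6 µm
spacing of the cortical nuclear layer, with a 2 µm nucleus radius, a stack
of 3 slices spanning 4 µm, and a rendering pixel of 0.4 µm. The coarser
pixel (vs. 0.104 µm for furrow images) reflects that genotyping depends on
per-nucleus spot counts, not on resolving spot substructure; spots remain
diffraction-limited (~1 px) at this sampling, which is what the detector is
specified against. The observed genotype distribution is compared with the
Mendelian 25/50/25 expectation by a chi-square goodness-of-fit test, with
binomial standard errors on each percentage.

## Statistics layer

Per-embryo values are compared with a two-sided two-sample *t* test
(pooled variance by default — Welch available — matching how per-embryo
points are usually compared) or a two-way ANOVA with interaction for fully
crossed designs such as genotype × temperature; the embryo is always the
unit of analysis. No multiple-testing correction is applied, and the output
says so (`p_adjust = "none"`). Multinucleation frequencies are reported as
percent ± binomial s.e.m.; furrow-canal intensities as mean ± s.d. over
canals.

## Validation suites and problem sizes

The test suite validates every stage against independent oracles: planted
merges against a hand-written union-find; thinning against closed-form
fixtures and Euler-number preservation; Gaussian smoothing against direct
kernel convolution; detection against planted spot lists; the *t* statistic
against the hand-computed value for {1,2,3} vs {4,5,6} (t = −3.674, df = 4).
The end-to-end suites run at desk scale, chosen so each check exercises the
full pipeline with comfortable statistical margins:

* wild-type ratio: one 1152 × 592 px embryo with 100 nuclei and two
  2835 µm² quadrats — the ratio must be exactly 1;
* assignment recovery: 20 noiseless 512 × 512 px embryos with 49 nuclei at
  0% and 10% failed edges (100% and ≥95% of interior nuclei matched);
* ratio recovery: 8 seeds × failure fractions {0, 0.02, 0.05, 0.1} on
  640 × 640 px embryos, centroid inclusion, tracking truth within ±0.03;
* Mendelian genotyping: 200 cohorts × 148 embryos × 150 nuclei rendered and
  called through the full image pipeline, recovering 25/50/25 within
  Monte-Carlo error;
* ANOVA calibration: 1000 null replicates of a 2 × 2 design, interaction
  type-I error 0.05 ± 0.02.

## Numerical choices and edge cases

* Thinning scans pixels in a fixed order; with the two Guo–Hall
  subiterations this makes results deterministic and orientation choices
  explicit. A final property — no 2×2 block — is asserted, not assumed.
* Otsu on a constant image is an explicit error (degenerate histogram), and
  the two-stage refinement falls back to the single-stage value when the
  above-background population is too small or too uniform to split.
* Compartments and cells below `min_cell_area_px2` (default 100 px²) are
  dropped as thinning-artifact slivers before labelling; labels are always
  consecutive `1..L`.
* A spot plateau (two equal maxima from merged sites) is counted once, by
  lexicographic tie-break.
* Window placement is deterministic (fixed fractional positions along the
  long axis); windows that do not fit raise an error rather than silently
  shrinking.

## Known limitations

* Threshold transfer to real micrographs will generally need the
  `"quantile"`/`"fixed"` strategies or per-dataset inspection of the logged
  thresholds; the Otsu defaults are conventions validated on the image
  model, not fits to published intensity statistics (none are available).
* The nucleus-compartment route infers nuclei from the furrow channel; the
  optional nucleus-channel route (blob segmentation + centroid containment)
  is preferable when a Hoechst-like channel exists.
* No 3-D measurements: furrow length, z-profiles and time series are out of
  scope; stacks are only ever max-projected.
* The FISH detector does not attempt sub-diffraction localisation or
  transcription-kinetics modelling.
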
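---
title: "Quantifying zebrafish vascular networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zebrafish vascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebravasc)
```

This vignette is the package's account of its science: what each stage of
the pipeline computes, which parameters matter and why they default to
the values they do, what the synthetic phantoms do and do not emulate,
and where the genuinely open design choices were and how they were
settled.

## The measurement problem

Endothelial reporter transgenics render the whole vasculature of a
zebrafish embryo fluorescent. A confocal z-stack of the head or trunk is
collapsed to a 2D maximum-intensity projection, and the biological
questions — is the network shorter, less branched, dilated? — become
image-measurement questions. The difficulties are (i) heterogeneous
reporter expression and low signal-to-noise in parts of the field,
(ii) the subjectivity of manual tracing, and (iii) comparability across
embryos imaged at different depths. The pipeline addresses (i) with local
contrast enhancement and curvilinear-structure filtering, (ii) by fixing
every step in code with recorded parameters, and (iii) by converting to
physical units and normalising network length by imaged depth.

## Stage by stage

### Projection and calibration

Stacks are (z, y, x) arrays with XY pixel size (µm/px) and z-step (µm).
The projection takes the per-pixel maximum over z and carries
`z_depth = n_slices x z_step` forward. Calibration precedence is
explicit configuration > embedded TIFF resolution tags > package defaults
(1/1.2 µm/px and 5 µm z-step, the acquisition settings the pipeline was
designed around); any fallback to a default is logged as a warning,
because a wrong scale silently corrupts every micron-space metric.
Projections supplied without stack provenance carry `z_depth = 0` and the
pipeline refuses to compute depth-normalised metrics until a depth is
given — a deliberate guard against meaningless normalisation.

The XY calibration is stated in two directions by the acquisition
conventions (0.83 µm/px and 1.2 px/µm, reciprocals rounded differently).
The package uses 1.2 px/µm as the conversion constant, since that is the
form in which the conversion is applied; both are configurable.

### Normalisation, CLAHE, Otsu

8-bit normalisation is a linear min–max stretch (half-to-even rounding;
constant images map to zero). It is invariant to positive affine
rescaling of the input, so acquisition gain does not affect downstream
thresholds.

CLAHE equalises histograms tile-by-tile with a clip limit bounding slope
(noise amplification), interpolating bilinearly between tile mappings.
Defaults: clip limit 2.0, 4 x 4 tiles. Images not divisible by the tile
grid are mirror-padded and cropped back, avoiding edge artefacts that
replicate-padding or truncation would introduce. The ordering is fixed:
normalise, then CLAHE, then Otsu and tubularity filtering both operate on
the enhanced image. (Whether the initial Otsu mask should see the
enhanced or the raw 8-bit image is not dictated by the pipeline's
numbered stage order alone; the package defaults to the enhanced image,
consistent with that order, and the alternative is one flag away.)

Otsu thresholding maximises the between-class variance over the 256-bin
histogram; foreground is strictly above the threshold. Ties take the
lowest maximising threshold, making the operation deterministic. A
constant image has no variance to split: the mask is empty and a warning
is raised.

### Tubularity filtering

Vessels are curvilinear: locally they look like ridges, with one strongly
negative Hessian eigenvalue across the vessel and one near zero along it.
All four filters are built on the scale-normalised Hessian
(σ² · second Gaussian derivatives), eigenvalues ordered by magnitude
(|λ_lo| ≤ |λ_hi|), responses taken as the per-pixel maximum over
σ ∈ {3, …, 8} px and rescaled to [0, 255]:

* **Meijering (default)**: modified eigenvalues λ′ = λ + λ_other/3; the
  response is the magnitude of the most negative modified eigenvalue.
  After the final rescale this is exactly the classical neuriteness
  normalised by the strongest ridge in the image.
* **Frangi**: blobness ratio λ_lo/λ_hi and structure norm
  S = √(λ_lo² + λ_hi²) combined as
  exp(−R_B²/2β²)(1 − exp(−S²/2c²)), β = 0.5, c = half the maximal S at
  that scale; bright ridges only (λ_hi < 0).
* **Sato**: λ_c = −λ_hi gated by exp(−λ_lo²/2(αλ_c)²) with α = 0.5 for
  λ_lo ≤ 0 and 2 otherwise.
* **Jerman**: the ratio form λ_c²(λ_ρ − λ_c)(3/(λ_c + λ_ρ))³ with the
  regularised λ_ρ (τ = 0.5), saturating at 1 across the ridge core —
  flat responses by design.

With γ = 2 scale normalisation the single-scale response of a bar of
width w peaks at σ ≈ w/2 (for a boxcar profile the maximum of
2a·g_σ(a) over σ is at σ = a), which is why the 3–8 px ladder covers
vessels roughly 5–16 px wide and why the scale-selection property is
asserted in the tests.

The segmentation threshold (default 10) applies to the [0, 255]-rescaled
response. The printed constant is only meaningful on a fixed scale;
rescaling to 8-bit makes it so.

### Mask refinement, labelling, curation

The thresholded response is intersected with the Otsu mask by default:
tubularity filters respond in a halo around vessels (the Gaussian
aperture), and the intensity-based Otsu mask trims that halo, while the
tubularity response suppresses Otsu's isolated background speckle. Union
and filter-only modes exist for unusual material. Clean-up follows the
standard dual convention: 8-connected foreground objects below 50 px are
removed, 4-connected background holes below 200 px are filled.

Components are labelled 1..n in raster order of their first pixel —
fully deterministic — and curation is scriptable rather than
interactive: a list of segment IDs (from config or a JSON sidecar) is
zeroed out, survivors are relabelled contiguously, and the removal list
is recorded in the outputs. Reproducibility demands that curation be an
artefact, not a session.

### Skeletonisation

Two thinning variants are provided. `zhang` is the classical Zhang–Suen
two-subiteration parallel thinning. `lee` (the default) deletes simple
points — pixels whose removal provably preserves local topology, decided
by a 256-entry lookup table computed by brute force over all 3 x 3
configurations — in four directional subcycles with sequential
re-checking, preserving endpoints. Zhang–Suen guarantees no 2 x 2 block
survives; the simple-point variant can leave isolated thick pixels at
junction cores (bounded in the tests at 0.5% of skeleton pixels). Both
produce skeletons strictly inside the mask.

### Branchpoints and de-clustering

A branchpoint is a skeleton pixel with at least 3 skeleton neighbours in
its 3 x 3 window (the *inclusive* rule; a strict ≥ 4 variant is a flag).
A degree-3 pixel is the canonical bifurcation, so the inclusive rule is
the default. An important consequence, often overlooked: on an ideal
plus-shaped crossing the rule flags a *cluster* of five pixels (the
centre and the four arm-first pixels, which each see four neighbours via
diagonals). Junction clusters are exactly why the pipeline de-clusters:
raw branchpoints are scanned in raster order and a point is retained only
if it lies at least 30 px (≈ the mean vessel segment length) from every
previously retained point. The greedy raster rule is the only
deterministic reading of "keep the first point within the threshold",
and the retained set provably satisfies the pairwise separation.

Segment decomposition removes the *raw* (not the de-clustered)
branchpoints and labels the remaining 8-connected pieces, so segments
never span a junction even when junctions are merged for counting —
de-clustering is a counting correction, not a topology edit.

### Diameters and their discretisation

Per-pixel diameter is twice the Euclidean distance transform of the mask
at the skeleton pixel — the maximum inscribed circle. This convention has
a known half-pixel-per-side bias on odd widths: the centre row of a
5-px band is 3 px from the nearest background pixel *centre*, so the
estimate is 6 px, while even widths are recovered exactly. Junctions add
a second, geometric effect: any nonzero PSF rounds the concave corners
where vessels meet, and inscribed circles near a junction are genuinely
larger than the branch width. Both effects are properties of the
estimator and the geometry, not of segmentation quality. Accordingly,
*diameter recovery* in the validation suite is assessed two ways: on
straight single-width bars the estimate must be within 1 px of the
specified width (it is, for widths 3–15), and on junction-bearing
networks the pipeline's mean diameter is compared against the same
estimator applied to the ground-truth mask, isolating segmentation error
from estimator discretisation.

The image-level mean diameter averages segment means by default (matching
the per-segment outlier filtering); pixel-weighted averaging is a flag.

### Network metrics

Network length is the skeleton pixel count — the stated convention. A
√2-weighted variant (`network_length_diag_px`, diagonal links counted at
√2) is reported as a clearly separate convenience column for users who
want geodesic lengths; it is not used in any default metric. Vessel
density is the mean over square tiles of the within-tile vessel fraction;
the tile area is 100 µm² read literally (10 µm x 10 µm → 12 x 12 px at
1.2 px/µm), partial edge tiles dropped, and the area is configurable
because the literal reading is unusually small. Branchpoint density uses
the de-clustered count over the analysed area in µm².

### Units, depth normalisation, MAD filtering

Lengths and diameters divide by the px/µm scale; densities use scale².
Normalised network length divides micron length by the *physical* depth
of the source stack (µm); dividing by slice count instead is a flag, and
physical depth is the default because it is invariant to re-slicing the
same volume. Doubling the depth exactly halves the normalised length.

Outlier filtering uses the raw MAD — median(|x − median(x)|) with *no*
1.4826 normal-consistency factor — because the asymmetric multipliers
(lower 1x, upper 3x) are stated in raw-MAD units; a consistency-factor
option exists but is off by default. Bounds are closed intervals and
ties at the bounds are retained (deterministic and conservative). With
MAD = 0 only values equal to the median survive. Filtering applies to
the per-segment diameter and length distributions within an image and
affects the per-segment summary statistics; the total network length is
not recomputed from the filtered set (the filter is a statement about
distributions, not about the skeleton). Worked example:
`[1, 2, 3, 4, 100]` has median 3 and MAD 1, bounds `[2, 6]`, retaining
`[2, 3, 4]`. On Gaussian data the asymmetric bounds retain
Φ(3·0.6745) − Φ(−0.6745) ≈ 0.73 of the mass.

### Regions of interest

ROIs are polygons (even–odd rule, pixel centres tested, boundary pixels
included), boxes (inclusive corners) or axis-aligned half-planes, in
0-based (y, x) pixel coordinates, serialisable as JSON. The refined mask
is intersected with the region and *re-analysed from the skeleton up*
within the region's bounding box; cropping a whole-image skeleton instead
(a flag-worthy alternative, not currently taken) would create artificial
branch stubs at region boundaries. A full-image ROI therefore reproduces
whole-image analysis field-for-field, which the tests assert identically.

### Benchmarking

Masks are scored by the Jaccard index |A∩B|/|A∪B| (defined as 1 for two
empty masks, with a warning). Skeletons are scored with
Q = connectivity x length x area, the established
connectivity–length–area construction: connectivity penalises the
difference in 8-connected component counts relative to the reference
pixel count; length is the fraction of candidate pixels within a
tolerance (default 2 px) of the reference; area is the converse fraction.
All three lie in [0, 1]; identity scores exactly 1. The selection grid
runs all 4 filters x 2 thinning methods under shared pre-processing and
sorts by Q-score, then Jaccard, with name order as the final
deterministic tie-break.

## The phantom generator

Phantoms provide exact ground truth so every stage is testable without
microscope data. Geometry is drawn first — analytic centrelines with
widths and junction coordinates, rasterised by Bresenham's algorithm for
the truth skeleton (never by thinning the truth mask, whose artefacts
must not contaminate ground truth) — and rendering follows: flat-capped
strokes (with half-pixel axial slack so rounded endpoints stay inside
the mask), a flat or linearly graded background, Gaussian PSF blur, then
noise (Gaussian, or Poisson applied after blur so noise scales with
signal, as photon statistics do).

The default specification is the study condition used throughout the
validation suite: a 260 x 480 px trunk-like ladder (two longitudinal
vessels joined by 10 evenly spaced rungs — two junctions per rung, 20 in
all, separations ≥ 40 px), vessel width 5 px, vessel level 200 on
background 30 (a ~6.7-fold signal-to-background ratio), 1 px PSF blur,
Gaussian noise of sd 4 (~2% of the rendered dynamic range, typical of
bright transgene reporters imaged at 16 bits). The noise default sits
deliberately inside the generator's designed operating envelope — the
regime in which the pipeline recovers junction counts exactly. Beyond
roughly sd 5 under these conditions, CLAHE-amplified boundary noise
produces small attached protrusions in the mask, thinning turns them
into terminal spurs, the inclusive branch rule flags their bases, and
the 30 px greedy retention then packs extra retained points between true
junctions spaced 46 px apart: junction counts inflate by 1–3. That
failure mode is worth knowing about when applying the pipeline to very
noisy material; re-tuning CLAHE tiles or the branch-distance threshold,
or pre-denoising, would be the practical remedies.

What the phantoms deliberately do **not** emulate: anatomical realism,
heterogeneous reporter expression along a vessel, autofluorescent yolk
background, depth-dependent attenuation, or anisotropic PSFs. Passing
the phantom suite therefore demonstrates the pipeline's geometric and
numerical correctness — recovery of known topology and calibrated
geometry under blur and noise — not its biological validity on any
particular transgenic line, which always needs visual inspection of the
refined masks (the pseudo-colour renderings and overlays exist for
exactly that).

## Problem sizes and runtime choices

The validation suite and the acceptance script run phantoms of
260 x 480 px (the default ladder) and smaller, with 100-image oracle
sweeps at 32 x 32 px and 1000-case property checks on point sets; these
sizes exercise every code path while keeping the full suite around a
minute of compute. They are package choices, not limits: the pipeline
itself is routinely run on 1024 x 1024 projections, where the dominant
costs (separable convolutions for six scales, and thinning) remain
vectorised.

## Known limitations

* Input is TIFF (single- or multi-page, 8/16-bit grayscale); vendor
  formats such as CZI must be converted upstream. No time-lapse or tile
  support; analysis is strictly 2D on projections.
* Results export as CSV plus JSON provenance; no native XLSX writer.
* The inclusive branchpoint rule over-flags junction clusters by design
  and relies on the 30 px de-clustering; skeletons with genuine junction
  spacing below 30 px will be under-counted.
* The inscribed-circle diameter convention carries its +1 px bias on
  odd-width vessels; comparisons across conditions are unaffected, but
  absolute widths near the resolution limit should be interpreted with
  that in mind.
* The Q-score's three factors are implemented from the established
  connectivity–length–area construction with a configurable (default
  2 px) tolerance; other tolerance choices change absolute Q values and
  are recorded in the benchmark output for that reason.
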
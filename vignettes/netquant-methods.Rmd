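---
title: "Methods: automated NET quantification in netquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated NET quantification in netquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netquant)
```

## The measurement

NETosis assays image neutrophils in two registered channels: a DNA dye that
stains every nucleus, and an antibody marker intended to stain NETs. The
quantity of interest per field of view (FOV) is

$$\%\mathrm{NET} = 100 \cdot \frac{n_\mathrm{NET}}{n_\mathrm{total}},$$

with counts obtained by thresholding, connected-component labeling and
particle-size filtering. Two regimes exist in practice and `netquant`
implements both:

* **manual** — the operator picks a global marker threshold `t` high enough
  to exclude the weaker staining of resting nuclei; foreground is
  `intensity > t` (strict).
* **automatic** — Bernsen local adaptive thresholding with radius 15 px and
  contrast parameter 35 on both channels, removing the per-experiment
  operator judgement.

In both regimes the **total** count always comes from the DNA channel under
automatic thresholding; only the NET channel differs. Counts are object
counts, never area fractions, because the statistic divides counts.

`percent_net` can exceed 100 when NET structures fragment differently
across the two channels; it is flagged with a warning and never clamped.
A field with `n_total = 0` has no defined percentage: it is marked excluded
and its `percent_net` is `NA`. Per-sample summaries average `%NET` over the
non-excluded FOVs of a group; a single FOV reports a standard deviation of
0 rather than `NA` so downstream tables stay numeric.

## Bernsen thresholding

For every pixel $p$, let $lo$ and $hi$ be the minimum and maximum intensity
in the circular neighborhood of radius $r$ centered on $p$ (disk
$\{dr^2+dc^2 \le r^2\}$, center included, clipped at the image border so no
padding values participate), $mid = (lo+hi)/2$ and the local contrast
$hi - lo$. Then

* if $hi - lo \ge c$: $p$ is foreground iff $\mathrm{intensity}(p) > mid$;
* otherwise the neighborhood is considered homogeneous and the whole region
  is assigned by $mid \ge$ half-scale, where half-scale is $2^{b-1}$ for
  bit depth $b$ (128 for 8-bit, 32768 for 16-bit).

Numerical choices, fixed so results are exactly reproducible:

* the "contrast" parameter is the Bernsen local-contrast threshold — the
  only free parameter of the method besides the radius;
* the neighborhood is a disk, not a square;
* foreground comparisons are strict (`> mid`, `> t`); the low-contrast rule
  uses `>=` against half-scale;
* `contrast = 0` forces every pixel into the midpoint comparison.

The compiled kernel is validated in the test suite against a brute-force
per-pixel neighborhood scan written independently in R, over ~200 random
8-bit images across radius {1, 3, 15} × contrast {0, 35, 255}; the masks
must be identical. No intensity preprocessing is applied before
thresholding.

## Particle analysis and measurements

Connected components are labeled with 8-connectivity by default (the
particle-analysis convention; 4-connectivity is available). Labels are
assigned in raster-scan order of each component's first pixel, so labeling
is deterministic. Size gates are **inclusive** (`"25-infinity"` is read as
$[25, \infty)$) and areas are pixel counts — never calibrated µm², which
removes a hidden dependence on pixel-size metadata. The per-objective
defaults are:

| objective | min area, total (px²) | min area, NET (px²) |
|-----------|----------------------|---------------------|
| 10×       | 25                   | 75                  |
| 20×       | 100                  | 250                 |

The upper size gate (used to exclude fused structures that cannot be
assigned to individual cells) defaults to `Inf` and is configurable.
Objects touching the image border are retained: excluding them would bias
the count against exactly the large structures the assay is about.

Per object the pipeline reports area, centroid (mean pixel coordinate),
cumulative intensity of each channel over the object's pixels, and the
ordered boundary: the 8-connected outer-boundary pixels, traced clockwise
(Moore neighborhood) from the topmost-then-leftmost boundary pixel, in
0-based `(row, col)` coordinates with the origin at the top-left pixel
center. Pixels revisited by the trace on single-pixel-wide arms are
reported once, at first visit.

## Quality score

$$q = \frac{\text{DNA-mask pixels covered by an accepted object}}
           {\text{DNA-mask foreground pixels}} \in [0, 1].$$

"Accepted" means surviving the total-cell size gates, since that is the
object set assigned to individual cells or NETs. A field with zero DNA
foreground gets $q = 0$ plus a degenerate flag. The exclusion cutoff
`min_quality` defaults to 0.5 — a field where less than half of the stained
DNA is attributable to countable objects is dominated by fused or
out-of-gate structures; the cutoff is configurable and recorded in the run
report, and exclusion only flags rows, it never deletes them.

## Classification across a time course

Mean marker intensity per object (`sum_marker / area`) is normalized by the
maximum per-object mean over **all** fields and time points of the series
(series-wide, not per-image), giving values in $(0, 1]$. An object is
classified as NET iff its area reaches the objective's NET gate **and** its
normalized intensity reaches `intensity_min_net`; ties classify as NET. One
global intensity cutoff (default 0.3) is used for the whole series rather
than per-time-point cutoffs — with series-wide normalization a single
cutoff keeps classifications comparable across time points. The 0.3 default
sits well above the normalized background (~0.05 under the synthetic
models) and well below saturated NET signal; it is configurable and
recorded in the run report.

## Overlap coefficient

The colocalization readout is the Manders overlap coefficient
$R = \sum a_i b_i / \sqrt{\sum a_i^2 \sum b_i^2}$ over raw intensities,
bounded in $[0,1]$ by Cauchy–Schwarz, symmetric, and invariant to positive
rescaling of either channel. No automatic background subtraction or channel
thresholding is applied; an optional ROI mask makes background handling
explicit instead of hidden. Pearson-style correlation is deliberately not
offered here: overlap answers "do the signals co-occur", which is the
question asked of NET markers in tissue.

## The synthetic field generator

`generate_field()` plants three object classes on a blank field and renders
both channels as per-class mean intensity plus additive Gaussian noise,
clipped to the bit depth:

* **resting** nuclei — unions of 2–5 overlapping ellipses (lobulated
  footprints), area sampled within the total-cell gate but strictly below
  the NET gate;
* **spread** (early-activated) nuclei — lobulated footprints at least as
  large as the NET gate but with weak, diffuse DNA and chromatin staining;
* **NETs** — Gaussian-blurred super-ellipses at least twice the NET gate.

Two stain models encode the biological contrast that motivates the
pipeline: `d3d9_like` (marker stains NETs almost exclusively; resting and
spread nuclei sit at background in the marker channel) and
`chromatin_like` (every nucleus carries marker signal; NETs are brightest,
resting and spread nuclei stain weakly at mean 90 of 255). Default 8-bit
means — background 10, DNA 200/150/170 and marker (3D9-like) 0/0/200 for
resting/spread/NET — are chosen so that (a) every stained object clears the
contrast-35 Bernsen criterion against background, and (b) object interiors
larger than the neighborhood stay above half-scale, so low-contrast
interior regions do not punch holes in the mask. Noise is additive Gaussian
with sd 3, small enough that background windows essentially never reach
local contrast 35 yet large enough to exercise robustness; no Poisson or
PSF model is attempted. Placement is rejection sampling of non-overlapping
footprints with a 12 px margin and a retry cap (exceeding it raises a
density error). All randomness comes from one stream fixed by the seed, so
fields are bit-reproducible.

In time courses the 3D9-like marker is absent before ~120 min and ramps
linearly to full strength by 240 min, mimicking a marker whose epitope is
generated during chromatin decondensation; the pan-chromatin marker is
present from time 0.

What passing tests on these fields shows — and does not show: the generator
produces well-separated, noise-perturbed objects with the correct area and
intensity contrasts, so it verifies the counting logic, the gate semantics,
the regime difference and the failure mode of pan-chromatin markers
(spread cells pass the NET gate under automatic thresholding and inflate
%NET, which is exactly the early-time-point overcount the automatic regime
exhibits with such stains: on fields with truth 20% NETs the chromatin-like
model reads ~50% while the NET-selective model stays at 20%). It does not
emulate uneven illumination, focus drift, touching cells, or real chromatin
texture, so agreement here does not certify performance on real
micrographs — parameter conformance and algorithmic correctness do carry
over.

## Problem sizes and runtime choices

Tests and the acceptance script use 512×512 fields (20 fields for
ground-truth recovery, 6 per stain model for the failure-mode comparison,
12–20 objects per field) and ~200 random ≤48×48 images for the oracle
equivalence checks. These sizes give exact integer expectations and
sub-minute runtimes; the generator scales to arbitrary shapes.

## Known limitations

* No watershed splitting of touching nuclei — fused structures are handled
  by the upper size gate, as in the underlying workflow.
* Single-plane 2-D analysis only; multi-page TIFFs are split into
  independent fields, never treated as z-stacks.
* Only unsigned-integer 8/16-bit grayscale TIFFs are accepted.
* The overlap coefficient is computed on raw intensities; thresholded
  Manders variants (M1/M2) and significance testing are out of scope.
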
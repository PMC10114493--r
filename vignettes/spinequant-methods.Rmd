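---
title: "Quantifying dendritic fluorescence clusters, spine morphology and protrusion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic fluorescence clusters, spine morphology and protrusion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinequant)
```

## Scope and model

`spinequant` quantifies fluorescence time-lapses of dendrites in studies of
activity-dependent spine initiation. The measurements it implements are:

1. **Brightness-cluster analysis.** Membrane-apposed protein clusters (for
   example of an F-BAR scaffold protein such as Gas7) appear as bright
   puncta over a diffuse cytoplasmic background. A cluster is defined as a
   connected set of pixels inside a dendrite region of interest whose
   intensity is *strictly greater* than a manually chosen brightness
   threshold on the unit intensity scale. Reported per frame: cluster
   count, per-cluster and total area, per-cluster mean intensity (always
   measured on the raw image), and the mean intensity inside versus
   outside clusters within the ROI.
2. **Observation-path masks.** The ROI is built from a hand-drawn
   one-pixel-wide skeleton curve along the dendrite, dilated by a Euclidean
   disk of 95 px (5 µm at 0.0526 µm/px) to both sides, giving a 191-px-wide
   band. Dendrite length is the step-sum along the skeleton (1 px per
   orthogonal step, √2 px per diagonal step).
3. **Baseline-normalized time series.** For treatment experiments, total
   cluster area and cluster count are divided by their mean over the last
   3 pre-treatment frames (configurable to 4, as used for actin
   depolymerisation experiments), so the baseline mean is exactly 1.
4. **Spine morphometry.** Candidate protrusions with volume ≥ 0.020 µm³,
   length within 0.1–5 µm and maximal width ≤ 3 µm are retained as spines.
   Mushroom: head diameter ≥ 0.35 µm and head/neck ratio ≥ 1.1;
   non-mushroom with volume ≥ 0.040 µm³: stubby; all other: thin.
   Densities are reported per µm of dendrite, total and per class.
5. **Protrusion dynamics.** New protrusions are found frame-over-frame by
   greedy nearest-first matching of arclength positions; rates are
   reported per 10 µm of dendrite per minute, spine gain as new/existing
   spines in percent, and each birth is tested for a spatiotemporally
   preceding cluster (radius 1 µm, at least one frame earlier).
6. **Photometry.** Reference-normalized spine/dendrite intensity ratios
   (median of ≥ 10 spines per neuron), knock-down intensities relative to
   neighbouring somas normalized to a scramble group, and Pearson
   colocalization over an ROI.
7. **Group statistics.** A dispatcher that reproduces the common
   convention: Shapiro–Wilk (α = 0.05) gates parametric tests, Levene's
   test selects Bonferroni versus Games–Howell post hocs after one-way
   ANOVA, with Mann–Whitney, Wilcoxon signed-rank and Kruskal–Wallis on
   the nonparametric branches.

## Key parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `pixel_size_um` | 0.0526 | µm/px | implied by the 95 px = 5 µm mask-growth correspondence; 0.066 µm/px is typical for confocal stacks and can be passed instead |
| growth radius | 95 | px | produces the 191-px observation path |
| `threshold` | 0.4 | unit intensity | the documented example value; in practice set per experiment (or per cell for diffuse markers, with a manual zero-cluster fallback) |
| `connectivity` | 8 | – | matches visual continuity of puncta; 4 available |
| `min_cluster_px` | 4 | px | suppresses single-pixel noise; the procedure itself does not fix a floor |
| `baseline_n_frames` | 3 | frames | last pre-treatment frames averaged to 1; 4 for the actin experiments |
| association `radius_um` | 1.0 | µm | "closely located" is not defined numerically; 1 µm is the spine-neck scale and is a config knob surfaced in every report |
| `min_precede_frames` | 1 | frames | one frame = 3 min; also a knob |
| match radius (tracking) | 0.5 | µm | identifies persistent protrusions across frames |

Threshold comparisons on geometry are inclusive (`minimum of x` reads
≥ x); the brightness threshold itself is strict (`>`), so ties at the
threshold are excluded. Volume thresholds are taken in µm³ rather than
voxel counts: the printed voxel size (0.066 × 0.066 × 0.2 µm ≈ 0.00087 µm³)
is inconsistent with the printed 5-voxel = 0.020 µm³ equivalence, and µm³
is resolution-independent, so the µm³ values are authoritative here.

## The synthetic generator

No imaging data are publicly deposited for this kind of experiment, so the
package ships a seeded generator whose presets encode the study conditions,
and every analysis module is validated against its ground truth.

A frame is a background at 0.05, a straight horizontal dendrite band
(2 µm wide) at diffuse level 0.25, `n_clusters = 8` Gaussian blobs
(σ = 0.30 µm, amplitude 0.45) centred on the band, and i.i.d. Gaussian
noise (sd 0.02), clipped to [0, 1]. The default image is 512 × 512 px
(≈ 27 µm of dendrite). With threshold 0.4 the supra-threshold disk of a
blob with amplitude $A$ over diffuse $d$ has radius
$r = \sigma\sqrt{2\ln(A/(\theta-d))}$, so the generator controls measured
cluster area in closed form.

**Treatment schedule (bicuculline preset).** Total cluster area follows a
piecewise-linear ramp: 1 → 1.5-fold between onset and +6 min, then
1.5 → 2.0-fold by +9 min, then flat. This satisfies simultaneously the two
programmed marks — 1.5-fold total area at +6 min and a doubling of mean
cluster size peaking within the first 10 min (cluster count is constant) —
and growth is confined to the first 12 min. The blob σ scales as the
square root of the ramp; the amplitude is recomputed each frame so
$A/(\theta-d)$ is constant, making the measured area ramp exact up to
pixelation; and the diffuse level is solved in closed form so that summed
band intensity is conserved. That last constraint is the key statistical
structure of the data: overall image intensity stays stable while cluster
intensity rises and diffuse intensity falls (diffuse protein redistributes
into clusters).

**Event program.** Births are Poisson per frame interval: at the
spine-gain rate (14 %/h of existing spines post-treatment, 1 %/h baseline)
for slice-style presets, or at a constant protrusion rate (0.150 or
0.078 / 10 µm / min) for the overexpression presets. Each birth lands at a
cluster (uniform ± 0.5 µm) with the preset precedence probability (0.85
bicuculline, 0.759 overexpression), else at a site ≥ 1.2 µm from every
cluster, and always ≥ 0.2 µm from existing protrusions — a physical
distinctness constraint only, since persistent protrusions keep exact
positions and the greedy matcher consumes zero-distance pairs first, so
detection on noise-free position tables recovers the ground-truth birth
schedule exactly. Protrusions persist once born; 16 existing spines
(≈ 0.6 / µm, the scale of measured densities) populate the dendrite from
frame 1.

**Chosen study sizes** (where the conditions do not fix them): the
bicuculline time-lapse spans 15 + 15 frames at 3 min (45-min epochs);
overexpression videos span 16 frames (45 min); precedence recovery pools
render-free simulations until ≥ 200 births are available; spine-gain
cohorts use 12 neurons of 30–50 spines over 1 h; the rate recovery uses
7 videos. These match the corresponding reported sample sizes where such
exist and otherwise keep every check inside seconds.

**What the generator does not emulate:** optical point-spread functions
and anisotropic blur, photobleaching, dendrite curvature and branching,
crossing dendrites, intensity flicker of individual clusters, cluster
birth/death (beyond an off-by-default count-decay hook), and 3-D
structure. Passing the recovery tests therefore demonstrates that the
measurement code is correct and unbiased under the assumed image model,
not that the threshold-based procedure is robust on arbitrary real data —
threshold choice on real images remains a manual, supervised step.

## Numerical choices

- Cluster membership uses a strict `>` comparison; component labeling is a
  union-find over the pixel-adjacency graph, cross-checked in the test
  suite against an independent flood-fill oracle on every 4 × 4 binary
  pattern at both connectivities.
- Gaussian smoothing (when enabled) affects membership only; kernel is a
  normalized truncated Gaussian with odd extent; convolution uses circular
  boundary handling, and the kernel is shrunk to fit very small images.
- Skeleton length uses the minimum spanning forest of the 8-adjacency
  graph with weights 1/√2, which reproduces the orthogonal-first step sum
  of standard skeleton analysis and is independent of traversal order;
  closed loops in a skeleton would be opened by one edge. Thicker strokes
  are thinned (Zhang–Suen) with a warning.
- Euclidean dilation is computed from the exact distance transform (pixel
  centres within the radius), so a straight line grows to exactly
  2r + 1 px; a Chebyshev-square element is available for cross-checking
  hand-drawn masks grown by tools whose corner behaviour differs.
- Relative series with a zero baseline are flagged undefined rather than
  propagating infinities; zero-cluster frames report NA mean cluster size
  and are excluded from before/after summaries.
- The baseline-mean-equals-1 invariant is tested to 1e-9 relative.
- Ties in greedy event matching are broken by lower arclength; ties in
  cluster association by nearest distance.

## Design decisions taken where the procedure was open

- **Smoothed vs raw intensities.** Cluster *identification* may use the
  smoothed image; cluster *intensities* are always measured on the raw
  projection, since smoothing is described as a supplementary aid for
  identifying regions.
- **Bit depth.** Acquisition bit depth is not fixed by the procedure;
  unit scaling is therefore explicit, with `"bit-depth"` and `"min-max"`
  modes.
- **Cluster persistence for association.** Whether a preceding cluster
  must persist up to the birth frame is unspecified; the implementation
  requires presence at `birth - min_precede_frames` and reports the
  parameters used.
- **Membrane curvature** of proto-protrusions is carried as an annotation
  flag only — it was judged visually in the original workflow and
  computing it would be invention.
- **Normality gate at α = 0.05** per group for the statistics dispatcher;
  the operative level of the convention it reproduces.

## Known limitations

- Spine geometry is consumed from measured tables (as exported by 3-D
  spine-analysis software); the package does not segment spines from raw
  stacks, and manual curation steps are inherently out of scope.
- Protrusion detection operates on 1-D arclength positions (all reported
  quantities are per dendrite length); it does not segment protrusions
  from pixels.
- Automatic threshold selection is deliberately absent; the workflow is
  supervised by design.
- PCC is reported without thresholding, background subtraction, Manders
  coefficients or randomization tests.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates, from scratch:
the 191-px observation-path width; the mean relative total cluster area at
+6 min over four bicuculline-preset time-lapses (programmed 1.5); the
percentage of births with a preceding cluster over ≥ 200 events
(programmed 85 %); the mean 1-h spine gain over 12 neurons (programmed
14 %); and the mean protrusion rate over 7 overexpression videos
(programmed 0.150 / 10 µm / min). Each is computed by running the full
corresponding analysis path, not read from the configuration.
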
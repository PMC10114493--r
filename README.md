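# spinequant

Quantification toolkit for fluorescence-microscopy studies of dendritic
spine initiation. It is written for neurobiologists who image dendrites of
(for example) hippocampal pyramidal neurons expressing a fluorescently
tagged membrane-scaffold protein, and who need reproducible, scriptable
versions of the measurements such studies rely on:

- **Brightness-cluster analysis** of maximum-intensity projections: a
  cluster is a connected set of pixels inside a dendrite ROI whose unit-scale
  intensity exceeds a brightness threshold θ (e.g. 0.4), optionally after
  Gaussian smoothing that agglomerates nearby bright pixels. Per frame the
  cluster count *n*, areas *Aᵢ* (µm²), total area ΣAᵢ, per-cluster mean
  intensities, and the in-cluster vs non-cluster ROI intensity partition
  are reported. Time-lapse series are normalized so the mean of the last 3
  pre-treatment frames equals 1.
- **Observation-path ROIs**: a hand-drawn one-pixel skeleton curve is grown
  95 px (5 µm) to both sides by Euclidean dilation into a 191-px-wide band;
  dendrite length is the 8-connected step sum (1 / √2 px per step).
- **Spine morphometry**: retention (volume ≥ 0.020 µm³, 0.1 ≤ length ≤ 5 µm,
  width ≤ 3 µm) and classification — mushroom if head ≥ 0.35 µm and
  head/neck ≥ 1.1, else stubby if volume ≥ 0.040 µm³, else thin — with
  densities per µm of dendrite.
- **Protrusion dynamics**: frame-over-frame new-protrusion detection,
  rates per 10 µm per minute, spine gain (% of existing spines), and
  association of each birth with a spatiotemporally preceding cluster
  (radius 1 µm, ≥ 1 frame earlier), plus 15-frame epoch pooling.
- **Photometry**: reference-normalized spine/dendrite intensity ratios
  (median over ≥ 10 spines per neuron), knock-down intensity relative to
  neighbouring somas normalized to a scramble group, and Pearson
  colocalization (PCC) over an ROI.
- **Group statistics**: Shapiro–Wilk/Levene-driven dispatch between t,
  Mann–Whitney, Wilcoxon signed-rank, one-way ANOVA with Bonferroni or
  Games–Howell post hocs, and Kruskal–Wallis.

Because raw imaging data of this kind are typically unavailable, the
package includes a **seeded synthetic generator** (`preset_config()`,
`generate_projection()`, `generate_timelapse()`, `generate_spine_table()`,
`generate_coloc_pair()`) producing ground-truthed dendrite images,
time-lapse movies, spine tables and channel pairs whose presets encode the
reference effect sizes: 1.5-fold total cluster area at +6 min after
treatment with mean cluster size doubling by +9 min, 85 % cluster
precedence of new spines, 14 %/h spine gain, and protrusion rates of
0.150 vs 0.078 per 10 µm per minute.

## Worked example

```r
library(spinequant)

cfg  <- preset_config("bicuculline", seed = 6)   # treatment preset
sim  <- generate_timelapse(cfg)                  # 30 frames, 3 min apart
mask <- grow_skeleton(sim$skeleton, 95L)         # 191-px observation path

ts <- analyze_timeseries(sim$frames, mask, cluster_params(0.4),
                         treatment_frame = sim$treatment_frame)
dplyr::select(tidy(ts)[14:18, ], frame, time_min, n_clusters,
              total_area_um2, relative_total_area)
#>   frame time_min n_clusters total_area_um2 relative_total_area
#> 1    14       -3          8           4.96               0.992
#> 2    15        0          8           5.01               1.00
#> 3    16        3          8           6.21               1.24
#> 4    17        6          8           7.49               1.50
#> 5    18        9          8           9.98               2.00

summarize_before_after(ts)
#>   before_um2 after_um2 ratio
#> 1      0.625      1.25  2.00
```

The relative total cluster area reaches 1.50 at +6 min and the mean
cluster size (total area / count) doubles at its post-treatment peak —
the two programmed treatment effects, recovered by the full detection
pipeline rather than read from the configuration.

```r
events <- detect_new_protrusions(sim$truth$protrusions)
assoc  <- associate_with_clusters(events, sim$truth$tracks, radius_um = 1)
assoc$percent_from_clusters
#> [1] 40
pool_epochs(assoc$events, sim$treatment_frame, 15L, 30L)
#>   epoch frame_start frame_end n_events n_linked
#> 1 pre             1        15        0        0
#> 2 post           16        30        5        2
```

This short movie produced 5 new protrusions, all in the post-treatment
epoch, 2 of them (40 %) preceded by a nearby cluster — with only a handful
of births per video the precedence percentage is noisy, which is why the
acceptance analysis pools ≥ 200 births before comparing against the
programmed 85 %.

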
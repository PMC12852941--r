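# bactaxis

Single-cell quantification of **where fluorescent signals localize on
rod-shaped bacteria**. The package is built for experiments that image
*E. coli* under phase contrast together with fluorescence channels — e.g.
complement components (C9 of the membrane attack complex, C3b),
membrane-damage dyes (Sytox) or cell-wall labels (HADA) — and that need to
answer, over hundreds of cells per field: does the signal sit at a pole, at
the division septum, or uniformly around the envelope?

It is aimed at microbiologists and image analysts who have (or can plug in)
a cell segmentation and want the downstream single-cell statistics to be
reproducible, filterable and testable.

## What it computes

For each frame of a multichannel stack:

1. **Segmentation post-processing.** The phase channel is cut into 256 × 256
   tiles with 50% overlap (a 1392 × 1040 px frame at 0.102 µm/px gives
   exactly 120 tiles), scored into three classes (background / 3-px membrane
   / cell body) by a pluggable backend, and blended back with a
   squared-triangle spline window. Each 8-connected body component, dilated
   by exactly 3 px (Euclidean disc) to compensate the membrane class,
   becomes one cell instance; cells touching the frame border are dropped.
2. **Growth-stage classification.** Instances are matched to detector boxes
   by highest IoU (confidence as tie-break) and filtered to the desired
   stages (rod-shaped, dividing). An Otsu threshold on the pooled
   cell-length histogram removes residual rod/dividing confusions.
3. **Axial profiling.** The long axis comes from image moments,
   θ = ½·atan2(2µ₁₁, µ₂₀ − µ₀₂), projected from the centroid (c_x, c_y) =
   (m₁₀/m₀₀, m₀₁/m₀₀) to the mask border. N = 21 positions from 5% to 95%
   of the axis length (p₂ = 9.5%, …, p₂₀ = 90.5%) each sample the
   perpendicular chord with bilinear interpolation, reduced by max (or
   mean). Profiles are oriented so the brighter half of a chosen channel
   lies left, and normalized per channel to a maximum of 1.
4. **Gating.** A σ = 5 px Gaussian blur plus triangle threshold on a gate
   channel (e.g. Sytox) selects positive cells.
5. **Aggregation.** Per class/position/channel box-plot statistics (type-7
   quartiles, 1.5 × IQR whiskers), and an **average cell shape** per class
   by iterative mean-Hausdorff minimization (≤ 1000 iterations, 10⁻⁸ early
   stop) over normalized, vertex-equalized contours.

A synthetic scene generator (spherocylindrical rods, constricted dividing
cells, uniform/polar/septal signal models, full ground-truth masks, boxes
and labels) backs the entire test suite — no imaging data is required to
validate the pipeline.

## Worked example

```r
library(bactaxis)

scene <- synth_scene(n_rods = 8, n_dividing = 8, width = 696, height = 520, seed = 42)
cfg   <- pipeline_config(orient_channel = "C9", gate_channel = "Sytox")
res   <- run_pipeline(scene$frame, cfg,
                      backends = list(backend_oracle(scene$truth$semantic)))
res
#> <bactaxis_result> 15 cells (dividing: 8, rod: 7), 1 excluded
res$length_threshold
#> [1] 29.32  # px: rods above / dividing cells below this length were discarded
head(as.data.frame(subset(res$profile_summary, channel == "C9")), 4)
#>      stage channel index position n    q1 median    q3 whisker_lo whisker_hi
#> 1 dividing      C9     1    0.050 8 0.922  0.938 0.971      0.881      1.000
#> 2 dividing      C9     2    0.095 8 0.874  0.912 0.942      0.871      0.974
#> 3 dividing      C9     3    0.140 8 0.925  0.932 0.943      0.919      0.966
#> 4 dividing      C9     4    0.185 8 0.874  0.919 0.956      0.839      0.976
glance(res$shapes$rod)
#>   n_contours n_vertices final_loss initial_loss iterations_used converged
#> 1          7         64     0.0312       0.0355             274 TRUE
```

The scene paints a uniform membrane marker ("C9") on every cell, so the
per-position medians hover near 1 with no left/right trend — the expected
flat profile for full coverage. One of 16 cells fell to the length filter
(`res$log` says why, per cell). `final_loss < initial_loss` confirms the
average rod shape improved on its best-member initialization.
`autoplot(res$profile_summary)` draws the profile distributions;
`autoplot(res$shapes$rod)` the average outline. For polar signals, swap the
generator's channel model — e.g.
`signal_model("polar", pole = "left", amplitude = 1, spread = 5)` — and the
oriented profiles peak at the left end instead.

A thin CLI (`inst/scripts/bactaxis-cli`) exposes `simulate` and `run` verbs
for shell use.

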
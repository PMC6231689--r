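# segmapr

Spatial quantification of apoptosis and signaling in the segmented
*Drosophila* embryonic epidermis.

During mid-embryogenesis the fly epidermis is a row of ~14 repeating
segments delimited by Engrailed (En) stripes. Mutants of the segmentation
cascade (e.g. the pair-rule gene *fushi-tarazu*) show massive, *banded*
apoptosis, and within a normal segment apoptotic cells are not uniformly
distributed: cell death is rare near segment boundaries and enriched
mid-segment, where EGFR pathway activity — sustained by ligand sources
(rhomboid/Spitz, Vein) expressed in stripes flanking each boundary — is at
its lowest. `segmapr` implements the quantitative toolkit behind this kind
of analysis, for developmental biologists working with projected 2D
micrographs:

1. **Segmental event mapping.** En stripes are thresholded, reduced to
   single-pixel skeletons (Zhang–Suen thinning with spur pruning), and each
   detected apoptotic figure (e.g. a cleaved-Dcp1–positive cell, reduced to
   its centroid) is assigned the minimal Euclidean distances d<sub>ant</sub>
   and d<sub>post</sub> to its flanking skeletons. Its normalized position is

   > rel_pos = 100 · d<sub>ant</sub> / (d<sub>ant</sub> + d<sub>post</sub>)  [% of segment width]

   Events within a central band covering 20% of the dorsal–ventral extent
   (the ventral midline, i.e. the developing nervous system) are excluded.
   Per-embryo histograms of rel_pos are averaged across embryos.

2. **Landmark-registered intensity profiles.** A/P intensity traces from
   rectangular ROIs are registered to En peak landmarks by resampling each
   inter-peak interval onto 50 evenly spaced bins, then averaged across
   samples with SEM — the standard way to compare dpERK and reporter
   profiles whose segment widths vary between embryos.

3. **Threshold-survival model.** Each boundary is flanked by two ligand
   sources; signaling is a sum of exponential kernels
   S(x) = Σ A·exp(−|x − x_s|/λ). Where S drops below a survival threshold,
   *hid* is derepressed and cells die. Genotype presets edit the source
   list (*ftz* removes alternate segments' sources, *ptc* adds ectopic
   ones, *EGFR* null removes all), predicting e.g. exactly seven apoptotic
   bands in a 14-segment *ftz* embryo.

4. **Synthetic embryos.** A generator renders stripe + event channels (and
   1D profile samples) with known ground truth — configurable event
   position distributions, ventral-midline events, stripe curvature, jitter
   and noise — so every stage is testable without microscopy data.

## Worked example

```r
library(segmapr)

spec <- embryo_spec(event_count = 300, midline_fraction = 0.2, seed = 42)
res  <- run_mapping_pipeline(run_config(spec = spec, n_embryos = 5, seed = 42))
res$counts
#> $detected: 1317  $unmappable: 0  $midline_excluded: 275  $retained: 1042

h <- res$histogram
data.frame(bin = paste0("[", h$bin_edges_pct[-11], ",", h$bin_edges_pct[-1], ")"),
           mean_frequency = round(h$mean_frequency, 3), sd = round(h$sd, 3))
#>         bin mean_frequency    sd
#> 1    [0,10)          0.024 0.012
#> 2   [10,20)          0.078 0.012
#> 3   [20,30)          0.118 0.022
#> 4   [30,40)          0.133 0.013
#> 5   [40,50)          0.145 0.021
#> 6   [50,60)          0.146 0.017
#> 7   [60,70)          0.124 0.022
#> 8   [70,80)          0.107 0.019
#> 9   [80,90)          0.088 0.009
#> 10 [90,100)          0.037 0.013
```

The five synthetic embryos sowed events with beta(2, 2) intra-segment
positions; the recovered frequency histogram is mid-segment–peaked and
depleted in the boundary bins, and 275 of 1317 events fell in the 20%
ventral-midline band and were excluded. The survival model, under its
shipped calibration:

```r
for (nm in c("wildtype", "ftz", "ptc", "egfr_null")) {
  l <- simulate_scenario(nm)
  cat(sprintf("%-10s %d bands, sub-threshold area %.2f\n",
              nm, count_bands(l), subthreshold_area(l)))
}
#> wildtype   0 bands, sub-threshold area 0.00
#> ftz        7 bands, sub-threshold area 2.46
#> ptc        0 bands, sub-threshold area 0.00
#> egfr_null  1 bands, sub-threshold area 14.00
```

Wild type survives everywhere; losing alternate segments' ligand sources
(*ftz*) produces seven apoptotic bands (area in segment-width units);
ectopic sources (*ptc*) never create new bands; without EGFR the whole
field is one sub-threshold band. Group comparisons use the classical
pooled-variance t test:

```r
tt <- compare_mean_intensity(c(21.4, 23.9, 22.5), c(30.1, 28.7, 31.2))
cat(sprintf("t = %.3f, p = %.5f\n", tt$t, tt$p_value))
#> t = -7.233, p = 0.00194
```

A thin CLI over the same functions lives in `inst/cli/segmapr.R`
(subcommands `generate`, `map`, `profile`, `simulate`).

## Limitations

The pipeline consumes already-projected 2D images; distances are planar
Euclidean, not geodesic on the embryo surface. Stripe segmentation is a
global threshold plus connected components, not a trained pixel
classifier. The survival model is a static landscape — no dynamics, no
cell mechanics. See the methods vignette (`vignettes/segmapr-methods.Rmd`)
for the model's assumptions, parameter choices and numerical conventions.
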
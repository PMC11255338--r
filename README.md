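# polburst

Single-cell quantification of polar protein asymmetry and division-coupled
c-di-GMP bursts in rod-shaped bacteria.

## The problem

Rod-shaped bacteria such as *Myxococcus xanthus* concentrate their motility
machinery and its regulators at the cell poles, and how evenly this material
is allocated between the two poles — and between the two daughters at
division — determines single-cell behaviour. A division-site diguanylate
cyclase can switch on late in cytokinesis and produce a brief burst of the
second messenger c-di-GMP, read out with a ratiometric biosensor, that
symmetrizes the allocation of polar proteins to the daughters. Quantifying
this program requires a chain of measurements on fluorescence images and
segmentation label masks:

* **Polar clusters.** In each segmented cell, a polar cluster is a connected
  set of at least 3 pole-cap pixels whose intensity exceeds
  `mean(cytoplasm) + k·SD(cytoplasm)` (k = 2 by default, 1.5 for
  low-contrast markers). With `F1 ≥ F2` the total fluorescence at the two
  poles, the asymmetry index is

  `ω = (F1 − F2) / (F1 + F2)`

  and cells are binned as unipolar (ω > 0.9), bipolar asymmetric
  (0.9 ≥ ω ≥ 0.2), bipolar symmetric (ω < 0.2), or diffuse (no polar
  signal). Population spread is summarized as median ± MAD, with
  `MAD = median(|xᵢ − median(x)|)`.

* **Division timing.** Labels are linked across time-lapse frames by pixel
  overlap; completion of cytokinesis (t = 0) is the first frame in which
  the two daughters are separate labels. Mid-cell cluster appearance and
  lifetime, and the onset and duration of the high biosensor
  (green/red) ratio, are reported relative to t = 0 in multiples of the
  frame interval.

* **Motility.** From single-cell track tables, per-track speed and the
  number of run-and-reverse direction reversals (heading change ≥ 120°),
  with distribution breadth compared via MAD ratios.

* **Enzyme kinetics.** Product inhibition of a diguanylate cyclase follows
  `V = V0 / (1 + ([cdG]/Kᵢ)ʰ)` and equilibrium binding follows
  `R = Rmax·C / (K_D + C)`; both are fitted by nonlinear least squares with
  standard errors, confidence intervals and an identifiability flag.

* **Age structure.** In a steady-state exponential population the cell-age
  density is `f(a) = (2 ln2/T_d)·2^(−a/T_d)` on `[0, T_d]`, so the fraction
  of cells within the last `w` minutes of the cycle — e.g. cells carrying a
  division-site marker — is `2^(w/T_d) − 1` (about 5% for w = 20 min,
  T_d = 300 min).

Every input the pipeline consumes can be simulated with known ground truth
(spherocylindrical cells with polar clusters, growth/division movies,
biosensor bursts, run-and-reverse tracks, noisy kinetics curves), so each
stage is testable end to end without external data.

## Worked example

```r
library(polburst)

scene   <- make_snapshot_scene(scene_params(n_cells = 40,
                                            polar_fractions = c(0.25, 0.08),
                                            seed = 42))
records <- analyze_snapshot(scene$image, scene$mask)
head(records[, c("label", "pole1_fluor", "pole2_fluor", "omega", "pattern")], 3)
#>   label pole1_fluor pole2_fluor     omega    pattern
#> 1     1    27023.35    8696.586 0.5130682 asymmetric
#> 2     2    19379.32    6185.239 0.5161084 asymmetric
#> 3     3    25702.54    8302.930 0.5116709 asymmetric

summ <- population_summary(records)
summ$pattern_fractions
#>   unipolar asymmetric  symmetric    diffuse
#>          0          1          0          0
```

The generator placed 25% and 8% of each cell's signal at the two poles, so
the true asymmetry index is (0.25 − 0.08)/0.33 ≈ 0.515 — an asymmetric
cell — and the pipeline recovers it per cell (ω ≈ 0.51–0.52 above, median
0.515 ± 0.003 MAD across the population) along with the placed pole
fractions (median 0.25 and 0.08).

Fitting simulated inhibition kinetics (true V0 = 1, Kᵢ = 15 µM, h = 1.8;
5% noise, 3 replicates):

```r
fit <- fit_inhibition(make_kinetics_dataset("inhibition",
                                            list(V0 = 1, Ki = 15, h = 1.8),
                                            seed = 7))
fit
#> <inhibition fit> (n = 24)
#>    estimate     se   lower   upper
#> V0   1.0103 0.0164  0.9762  1.0444
#> Ki  15.6996 0.8460 13.9401 17.4590
#> h    1.8306 0.1503  1.5180  2.1432
#> residual SD: 0.04271 on 21 df
```

And the age-structure prediction for a division-site marker resident for
the last 20 min of a 300-min cell cycle:

```r
age_model_fraction(300, 20, n = 10000, seed = 1)
#> marker-positive: 4.99%  (analytic 4.73%)
```

Full simulate-and-quantify runs with tabular outputs and a manifest go
through `run_pipeline()` (or `inst/scripts/run-pipeline.R` from a shell);
see `?run_pipeline`.

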
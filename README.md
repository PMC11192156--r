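# seedmorph

Automated counting and species identification of tree seeds from flatbed
scans.

Long-term forest monitoring with seed traps requires classifying and
counting thousands of seeds per season — slow, skill-dependent work when
done by hand, especially for co-occurring conifers whose seeds look alike
and weather in the trap. `seedmorph` implements the scan-based alternative
end to end:

1. **Scan I/O** — read black-and-white flatbed scans (uncompressed TIFF,
   1-bit or 8-bit, 600 dpi by convention) and parse collection metadata
   (site, trap, date, species, fill status, replicate) from the file-name
   tag `SITE_TRAP_DATE_SPECIES_FILL_repN.tif`.
2. **Segmentation** — threshold (Otsu or fixed), label 8-connected
   particles, fill interior holes, discard sub-seed debris below a
   calibrated size filter (default 0.2 mm²), and trace each particle's
   exact crack boundary.
3. **Morphometry** — the full ImageJ-style descriptor vector per seed, in
   millimetres: area, perimeter, centroids, bounding box, moment-fitted
   ellipse (Major/Minor/Angle), circularity `4πA/P²`, maximum/minimum Feret
   (caliper) diameters by convex hull + rotating calipers, integrated
   densities, median intensity, aspect ratio `AR = Major/Minor`, roundness
   `1/AR`, and solidity `A/A_hull`.
4. **Classification** — a random forest (default `ntree = 500`,
   `mtry = floor(√26) = 5`) over 26 predictors: 25 measurements (skewness
   and kurtosis are excluded — they are undefined on binary scans) plus the
   categorical collection Site. Gini-split trees on bootstrap samples,
   majority vote, out-of-bag error, mean-decrease-in-Gini importance, an
   importance-threshold refit, and ntree/mtry tuning.
5. **Evaluation** — confusion matrix (actual species in rows), accuracy
   with exact Clopper–Pearson binomial CI, Cohen's kappa, no-information
   rate, per-class sensitivity/precision.
6. **Consensus** — each batch of seeds is scanned twice (rearranged between
   passes); per-species counts from the two scans are reconciled into a
   consensus (elementwise mean; integer variant by largest-remainder
   apportionment) with a discrepancy measure: `½·Σ|c₁−c₂| + ½·|n₁−n₂|`
   seeds in absolute terms, standardized by the mean seeds per scan in
   relative terms.
7. **Synthetic scans** — a generator of winged conifer-like seed
   silhouettes (six species templates, site-dependent mixtures and size
   shifts, damage bites, sub-threshold debris, duplicate arrangements of
   the same seeds) so the whole pipeline is testable with no external data.

The tree ensemble and the pixel geometry (component labeling, hole filling,
crack-boundary tracing) are implemented in C++ via Rcpp; everything else is
plain R.

## Worked example

A synthetic survey: 32 batches (~600 seeds, each scanned twice at 600 dpi),
segmented, measured, split 80/20 per species, classified with a 500-tree
forest, evaluated on the held-out rows, and reconciled across duplicate
scans.

```r
library(seedmorph)

cfg <- pipeline_config(
  sim        = simulation_config(n_batches = 32L, rng_seed = 1L),
  forest     = forest_config(ntree = 500L, mtry = 5L, seed = 1L),
  split_seed = 1L)
res <- run_pipeline("all", "run1", cfg)

print(res$evaluate)
#> Model statistics
#>   Accuracy                          0.9536
#>   95% confidence interval of accuracy (0.9185, 0.9766)
#>   No information rate               0.2785
#>   Kappa                             0.9424
#>   Size of data set                  237 observations
#> Confusion matrix (actual in rows, predicted in columns):
#>       predicted
#> actual ABAM CANO PSME THPL TSHE TSME
#>   ABAM   66    0    0    0    0    0
#>   CANO    0   42    0    0    0    0
#>   PSME    1    0   17    0    0    0
#>   THPL    0    0    0   35    0    0
#>   TSHE    0    0    0    0   20    8
#>   TSME    0    0    0    0    2   46

res$train$model$oob_error
#> [1] 0.0686378

round(head(forest_importance(res$train$model), 8), 1)
#>    Round       AR    Feret    Major MinFeret    Minor     Area    Perim
#>     94.9     85.3     77.3     71.1     65.4     61.8     60.2     59.8

round(mean(sapply(res$consensus$per_batch, `[[`, "discrepancy_rel")), 4)
#> [1] 0.0098
```

Reading the output: the held-out accuracy is 95.4% (exact 95% CI
0.919–0.977) against a no-information rate of 0.28, kappa 0.94; nearly all
confusion sits between the two deliberately similar hemlock-like templates
(TSHE/TSME), size-family descriptors dominate the importance ranking, and
duplicate scans of the same seeds disagree on about 1% of seeds, which is
the classifier's own noise (the true count vectors of the two scans are
identical by construction).

Artifacts land in `run1/`: `scans/*.tif` + `truth.csv`, `features.csv`,
`model.json`, `split.csv`, `calls.csv`, `report.json`, `consensus.csv` and
`manifest.json` (config hash + seeds; reruns with the same seeds are
byte-identical).

A command-line wrapper with the same stages lives at
`inst/cli/seedmorph.R`:

```sh
Rscript inst/cli/seedmorph.R all --out run1 --ntree 500 --seed 1
```

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/seed-classification.Rmd`) describes the measurement
definitions, the classifier contract, the consensus arithmetic, what the
synthetic-scan generator does and does not emulate, and the package's
numerical choices and known limitations.
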
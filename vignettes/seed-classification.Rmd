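---
title: "Seed classification from flatbed scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed classification from flatbed scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement and
classification model, the parameters that matter, what the synthetic-scan
generator emulates (and pointedly does not), and the numerical and design
choices made where the problem left them open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The problem

Seed traps under forest canopy collect seeds mixed with litter. After
drying and sieving, the seeds of a sample are spread on a flatbed scanner
and imaged in black and white at a known resolution (600 dpi by
convention). The task is to count seeds per species per trap. Conifer
seeds of co-occurring species are similar — winged, a few millimetres long,
often weathered or damaged — so classification from shape alone is a
genuine statistical problem rather than a lookup.

The pipeline: segment each scan into particles, measure a standard
morphometric descriptor vector per particle, classify each seed with a
random forest trained on hand-sorted material, and reconcile the two scans
made of every batch (the seeds are rearranged and flipped between passes)
into a consensus count with an explicit between-scan discrepancy.

## Segmentation

* **Thresholding.** Scans are nominally bilevel; `binarize()` accepts
  `"none"` (already binary), a fixed threshold, or Otsu's method
  (maximizing between-class variance; ties resolve to the smallest
  threshold, and a constant image yields an all-background mask so a blank
  scan produces zero particles). Polarity is explicit: dark seeds on a
  white platen by default.
* **Connectivity.** Foreground is 8-connected, background 4-connected —
  the standard particle-analysis convention, preventing diagonally
  touching seed fragments from splitting.
* **Holes.** Interior holes are filled before labeling: a scanning
  artifact inside a seed should not change its measured area. A
  consequence is that debris lying inside a seed's hole is absorbed into
  the seed.
* **Size filter.** Components below `min_area_mm2` (default 0.2 mm²,
  ≈112 px at 600 dpi) are discarded as sub-seed debris. The source
  protocol states the principle but not a value; 0.2 mm² sits well below
  the smallest template seed body (~2.3 mm² for small hemlock-like seeds)
  and well above realistic litter specks. It is configuration, not a
  constant.
* **Boundary.** Each particle's *crack boundary* — the closed polygon
  along pixel edges separating foreground from background — is traced
  exactly (C++). Vertices are pixel-corner coordinates; orientation is
  counter-clockwise in mathematical (y-up) terms, so the shoelace area in
  image coordinates equals the pixel count exactly. At saddle corners the
  walk takes the left turn, keeping an 8-connected component a single
  (weakly simple) loop.
* **Ordering.** Particles are numbered top-to-bottom then left-to-right by
  bounding-box origin, so labels are a property of the image, not of
  traversal order.

## Morphometry

All lengths are calibrated through the pixel size `25.4/dpi` mm. For each
particle:

* **Area** = pixel count × pixel area. **Bounding box** (BX, BY, Width,
  Height) from pixel extents; **centroid** (X, Y) from pixel centers;
  **XM, YM** intensity-weighted (equal to X, Y on constant-intensity
  particles).
* **Ellipse fit.** Second central moments of the pixel set, each pixel a
  unit square (adding 1/12 per axis), eigen-decomposed; both axes then
  rescaled by a common factor so the ellipse area equals the particle
  area. This makes roundness the exact inverse of aspect ratio
  (`Round · AR = 1` to a unit in the last place) — mirroring the reference
  tool's convention. `Angle` is reported in [0°, 180°), y flipped to
  mathematical orientation; an isotropic particle reports 0 by definition.
* **Feret diameters.** Maximum Feret = largest pairwise distance over
  convex-hull vertices of the crack boundary; MinFeret = minimum width
  over hull edges (rotating calipers; the minimum of a convex set is
  attained with a hull edge flush, so scanning edges is exact). Tie-break
  for the reported chord endpoint: smaller y, then smaller x, applied to
  both endpoints lexicographically, so a square's two equal diagonals
  yield a deterministic `FeretX`, `FeretY`, `FeretAngle`. Feret start
  coordinates stay in pixel units (bookkeeping, not geometry).
* **Perimeter and circularity.** `Perim` is the raw crack-polygon length,
  with no smoothing correction — a deliberate, exactly reproducible
  choice. Its known cost: staircase boundaries overestimate smooth
  outlines. For a rasterized disk the crack perimeter tends to the L1
  circumference 8r (a Cauchy–Crofton fact), so a disk's measured
  circularity `4πA/P²` is about `π²/16 ≈ 0.62`, not ~1 as smoothed
  estimators (e.g. ImageJ's corner-weighted tracing) report. Circularity
  is clamped at 1.0. Because the classifier is trained on features
  produced by this same implementation, the shift is a consistent
  reparameterization, not a bias; but `Circ` values are *not* numerically
  interchangeable with ImageJ's. This is the package's one deliberate
  divergence from the reference tool, chosen for exactness over mimicry.
* **Solidity** = area / convex-hull area of the boundary vertices (≥ area
  by construction, so solidity ∈ (0, 1] with no clamp; exactly 1 for
  axis-aligned rectangles).
* **Skewness/kurtosis** of intensities are measured but flagged missing
  when the intensity variance is zero — always, on bilevel scans — which
  is why they are excluded from the predictor set.

## The feature table and split

Predictors are the 25 retained measurements plus the categorical
collection **Site** — 26 in total. Positional measurements (X, Y, XM, YM,
BX, BY, FeretX, FeretY) are retained by default for fidelity to the
"use all available traits" stance, with `include_positional = FALSE`
offered because position on the platen is causally meaningless; on
synthetic data they act as weak noise.

The train/test split is stratified per species: `round(0.8·n)` rows
(half-up, clamped so both sides stay non-empty) per species, seeded.
Because every batch is scanned twice, the default per-row split can place
the two views of one physical seed on opposite sides — replicate leakage
that flatters test accuracy. The paper-faithful per-row mode is the
default; `group_by_batch = TRUE` keeps whole batches on one side and is
the honest option when the estimate itself matters.

## The classifier

The forest contract: `ntree` trees (default 500), each grown to purity on
a bootstrap sample; at each node `mtry` predictors drawn without
replacement (default `floor(√p)` with p = 26, i.e. 5) and the split with
the largest Gini-impurity decrease taken; prediction by majority vote.
Determinism is part of the contract: an own, platform-independent
xorshift generator seeded from the configuration, vote ties resolved to
the first class label, split ties to the first predictor drawn, tuning
ties to the smaller `ntree` then `mtry`. Bit-compatibility with any other
forest implementation is explicitly not a goal; statistical equivalence
is.

Site is one-hot expanded behind a stored vocabulary — prediction on an
unseen site fails loudly rather than silently recoding — and counts as
one logical predictor for the p = 26 accounting; its dummy importances
are summed back into a single `Site` entry.

Importance is mean decrease in Gini in count-scaled units
(`n·G(parent) − n_l·G(l) − n_r·G(r)` summed over a predictor's splits,
averaged over trees). These units grow with training-set size, so an
absolute refit threshold (as in "importance over 50") does not transfer
across datasets; `importance_filter_refit()` therefore also accepts a
quantile form, with the absolute form retained for fidelity.

Out-of-bag error is computed from majority votes over the trees for which
a row was out of bag (rows never out of bag — vanishingly rare at
ntree ≥ 100 — are excluded).

## Evaluation

The accuracy interval is the exact (Clopper–Pearson) two-sided binomial
CI from beta quantiles — reproducing, from printed (successes, n) pairs,
the reference bounds (4889/4889 → lower 0.9992; 800/859 → 0.9123–0.9473)
confirms this is the estimator the original toolchain used. Cohen's kappa
uses the standard `(p_o − p_e)/(1 − p_e)` with the degenerate `p_e = 1`
case defined (1 if also `p_o = 1`, else 0) to avoid 0/0 on single-class
tests. The no-information rate is the modal actual-class frequency.

## Consensus across duplicate scans

Seeds are rearranged between the two scans of a batch, so individual
seeds cannot be matched; consensus is defined on per-species count
vectors. The consensus count is the elementwise mean (half-integers
allowed; the integer variant rounds the mean total half-up and reaches it
by largest-remainder apportionment, ties to species order). The absolute
discrepancy is

> ½·Σ_s |c₁[s] − c₂[s]| + ½·|n₁ − n₂|

— half the L1 distance counts seeds that changed class, and the total
term counts seeds detected in only one scan. The relative discrepancy
divides by the mean of the two scan totals (the symmetric reading of
"the number of seeds on the scan" when there are two scans). Both
interpretations are documented choices, not claims about the original
code. The measure is symmetric, zero iff the count vectors agree, and
satisfies the triangle inequality (it is half an L1 metric plus a
pseudometric); these are tested properties. More than two replicate scans
per batch is out of scope (an error, not silent truncation).

## The synthetic-scan generator

The generator is a stated world, not a tuning dial: its defaults were
fixed while designing the package and are not adjusted to test outcomes.

A seed silhouette is a body ellipse fused with a superellipse wing lobe
(exponent 2.5), randomly rotated and mirrored, optionally damaged by a
circular bite anchored on the body edge *in the body frame* — so the same
physical damage appears, rotated, in both replicate scans of that seed.
Six templates emulate the qualitative range of North American conifer
seed silhouettes at realistic millimetre scales:

| template | body (mm, lognormal median) | aspect | wing/body | note |
|---|---|---|---|---|
| ABAM | 5.5 | 2.0 | 1.3 | large, broad wing |
| PSME | 5.0 | 2.3 | 1.1 | large, narrower wing |
| THPL | 4.0 | 2.4 | 0.35 | short lateral wings |
| CANO | 3.2 | 1.35 | 0.15 | rounded, near-wingless |
| TSME | 3.0 | 2.1 | 1.1 | **confusable pair** with |
| TSHE | 2.6 | 2.0 | 1.2 | small, long-winged |

TSHE/TSME differ only slightly in size and wing, by design: their
individual size distributions overlap heavily, so a correct classifier
should concentrate its confusion there — the qualitative analogue of the
hemlock confusions seen in real data. Body-length sigma is 0.10–0.12
(log scale) and damage probability 0.08–0.12 per seed; CANO's body length
was set (once, during design) to 3.2 mm so that mean silhouette area is
strictly monotone in template body length, a property the test suite
checks. Three sites carry different species mixtures and multiplicative
size shifts (0.94/1.00/1.07), so the Site predictor carries real signal
of both kinds attributed to elevation gradients.

Scans place silhouettes by rejection sampling with 2-px-padded bounding
boxes (no touching, so segmentation recovers each seed as one particle),
sprinkle 1–3 px debris specks that sit far below the default size filter,
and write bilevel TIFFs named by the tag grammar. The default 8–30 seeds
per scan is within the protocol's 1–90 but keeps canvases desk-sized;
tests that do not probe physical fidelity run at 300 dpi to quarter the
pixel work.

What the generator does **not** emulate — and hence what a green
end-to-end test does not establish: grayscale texture, lichen and color
effects, touching or overlapping seeds, partial seeds at scan edges,
non-convex wing damage, within-batch species mixtures, and any real
species' actual morphometric distribution. A green run demonstrates that
the pipeline's machinery is correct and that the classifier recovers
known structure; it says nothing about accuracy on real material.

## Numerical choices, in one place

* Circularity clamped at 1; raw crack-length perimeter (see above).
* `Round = Minor/Major` so `Round·AR = 1` to ≤ 2 ulp.
* Isotropic ellipse fit → `Angle = 0`; vote ties → first class label;
  split ties → first predictor drawn; Feret chord ties → lexicographic by
  (y, x) endpoints; tuning ties → smaller `ntree`, then `mtry`;
  apportionment ties → species order.
* Otsu on a constant image → all background; `binarize("none")` demands
  ≤ 2 intensity levels.
* Half-up rounding for split sizes and integer consensus totals (R's
  banker's rounding would make 0.5-cases depend on parity).
* All randomness flows from explicit integer seeds; the C++ forest uses
  its own generator so results are independent of R's RNG state and kind.

## Known limitations

* Uncompressed baseline TIFF only (1-bit, 8-bit gray, 8-bit RGB via
  luminance); no PNG or compressed TIFF — sufficient for the scanner
  protocol, not a general image library.
* `Circ` is not numerically comparable to ImageJ's (see Morphometry).
* Touching seeds are not split (operators separate seeds on the platen);
  no watershed.
* Exactly two replicate scans per batch are reconciled.
* The importance threshold's absolute scale is data-dependent; use the
  quantile form across datasets.
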
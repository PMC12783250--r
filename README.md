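# scalesuit

Multi-scale habitat-suitability modelling for rare species recorded by
camera-trap networks.

## What problem this solves

Detection/non-detection tables for rare, cryptic mammals are zero-inflated:
across a multi-survey camera network, well under 10% of stations ever record
the species, and presence/absence GLMs predict poorly at such prevalence.
On top of that, habitat selection is scale-dependent — each environmental
predictor influences the species at its own characteristic neighbourhood
size, not at the raster's native resolution. `scalesuit` packages the full
workflow an analyst needs in this setting:

* Gaussian focal-mean smoothing of predictor rasters over a seven-scale
  ladder (0.25–16 km; kernel SD = scale/2, truncated at the scale radius);
* station filtering (≥ 30 days effort, greedy presence-preserving 500 m
  thinning, removal of surveys that never detected the species);
* ten bootstrap-balanced presence/absence replicates (absences matched to
  presences within each survey), each split 4:1 into train/test;
* per-predictor univariate scale optimization by logistic-likelihood AIC,
  then collinearity screening (pairwise |r| > 0.7, then VIF > 5);
* exhaustive all-subsets logistic regression ranked by
  AICc = AIC + 2k(k+1)/(n−k−1), with a ΔAICc < 2 support set;
* a 30-threshold sweep on the held-out rows (sensitivity, specificity,
  TSS = sens + spec − 1, binarised AUC = (sens + spec)/2, Cohen's kappa)
  selecting the optimal threshold and the best replicate;
* continuous Boyce-index validation against independent presence-only
  points (Spearman correlation of the predicted/expected ratio across
  moving suitability windows);
* four-class discretization of the suitability map (equal-width bins,
  closed-left, top bin closed at 1) with protected-area gap analysis by
  pixel-center zonal statistics.

A synthetic-landscape generator (autocorrelated Gaussian random fields, a
known logistic species response acting at known scales, clustered surveys
with calibrated low prevalence, suitability-proportional validation points,
GeoJSON zones) makes the whole pipeline testable without any field data.
Rasters are read and written as plain-text ESRI ASCII grids (`.asc`,
GDAL/QGIS-compatible); tables are CSV, zones GeoJSON.

## Worked example

```r
library(scalesuit)
res <- run_full_analysis(run_config(seed = 7L), out_dir = "run7")
print(res$model)
```

```
<hsm_fit> 3 term(s) + intercept, n = 164, logLik = -76.430, AIC = 160.860, AICc = 161.111
        term estimate std_error z_value   p_value sig
 (Intercept)   0.1211    0.2037  0.5945 5.522e-01
   env1_250m   1.2527    0.2578  4.8586 1.182e-06   *
   env2_500m  -1.1173    0.2458 -4.5457 5.475e-06   *
   env3_250m   0.7282    0.2132  3.4161 6.352e-04   *
```

The selected model (best of ten balanced replicates by test-set binarised
AUC) recovers the three predictors that truly drive the synthetic species
with the right signs and magnitudes. The default demo landscape has
multi-kilometre-smooth predictor fields, so neighbouring scale choices are
nearly collinear and the fitted scales here sit below the generative ones
— the scale-identifiability limitation discussed in the vignette; the
near-zero intercept reflects the balanced 50:50 training data, not the
landscape prevalence. Continuing:

```r
res$prevalence       # 0.1025  — filtered-table prevalence (rare species)
res$boyce$index      # 0.9704  — independent points track predicted suitability
subset(res$protection, class == 4)$fraction_protected
                     # 0.117   — share of High-suitability habitat inside
                     #           the protected network (gap analysis)
```

`run7/` then holds every artifact: scale-selection and ranking tables,
the coefficient table above as CSV, threshold metrics, the Boyce P/E
curve, suitability and class rasters (`.asc`), gap tables and a JSON
manifest (config echo + stage seeds) that is byte-identical across reruns
with the same seed.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/scalesuit.R synth --config cfg.yml --out inputs/   # inputs only
Rscript inst/cli/scalesuit.R all   --config cfg.yml --out run/      # full analysis
```

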
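# spatialTIL

Spatial analysis of tumor-infiltrating lymphocytes (TILs) on whole-slide
image patch lattices, and comparison of lymph-node-metastasis (LNM)
prediction models with and without TIL features.

Digital-pathology pipelines tile a scanned H&E slide into fixed-size patches
and classify each patch as TIL-positive, TIL-negative, or necrotic/other.
`spatialTIL` starts from that patch table and asks two questions a thoracic
oncology group would ask of a lung adenocarcinoma cohort: *how are TILs
distributed in space on each slide*, and *do those spatial features improve
prediction of nodal metastasis over clinical variables alone?*

The package is aimed at computational pathology and biostatistics users who
have patch-level classifier output (or want to prototype against the
included synthetic generator) and want a reproducible, seeded path from
patch labels to model comparison.

## What it computes

* **TIL score** per slide: `n_pos / (n_pos + n_neg)`, necrotic/other
  excluded; per patient, the mean over slides.
* **Hot spot maps**: local Getis-Ord Gi* z-scores of the binarized TIL field
  on the masked lattice,

  `z_i = (Σ_j w_ij x_j − x̄ W_i) / ( S sqrt((n U_i − W_i²)/(n−1)) )`,

  with queen contiguity and self-inclusion by default, rendered blue→white→red.
* **Spatial TIL clusters (sTILCs)**: rendered maps → 1024×1024×3 → a fixed
  random-filter convolutional encoder (4 × [3×3 conv + ReLU + 2×2 maxpool],
  channels 16/8/8/4 → 16,384 features) → PCA at 95% cumulative variance →
  K-means with a consensus vote of silhouette, Davies-Bouldin and
  Calinski-Harabasz over k ∈ {2..6}. With two clusters, the one with the
  lower mean hot fraction is sTILC1 ("TIL-cold"), the other sTILC2
  ("TIL-hot").
* **Model comparison**: probability random forests M1 (age, T stage, TIL
  score, sTILC) vs M2 (age, T stage) on a stratified 8:2 split with 5-fold
  cross-validated hyperparameters; evaluated by AUC, the DeLong test for
  correlated ROC curves, Brier score, exact (all-coalition, interventional)
  Shapley attributions, and decision-curve net benefit.
* **Synthetic cohorts** with known ground truth: connected tissue masks,
  spatially autocorrelated TIL fields at "cold" (8% positive, short-range)
  and "hot" (45% positive, long-range) archetypes, and a logistic LNM
  outcome depending on T stage, age, TIL score, and archetype.

## Worked example

```r
library(spatialTIL)

# simulate a 60-patient cohort with known archetypes
cohort <- generateCohort(cohortSpec(nPatients = 60, seed = 1))
g <- cohort$grids[["P0001"]]
computeTILScore(g)
#> TILScore 0.4485 (597 TIL-positive / 1331 scoreable patches)

# hot spot analysis for one slide
h <- localGiStar(g)
h
#> HotspotMap P0001: 1401 tissue patches on 48 x 48, hot fraction 0.333 (z >= 1.96)
writeHotspotPNG(renderHotspotMap(h), "P0001_hotspots.png")

# spatial TIL clusters for the cohort (k = 2 pins the two-cluster sTILC
# naming; leave it NULL to use the consensus vote's k)
hmaps <- lapply(cohort$grids, localGiStar)
fs <- deriveSpatialClusters(hmaps, kmeansSeed = 1, k = 2)
fs@vote
#> ConsensusVote over k in { 2, 3, 4, 5, 6 }
#>   winners: silhouette= 4  daviesBouldin= 5  calinskiHarabasz= 2
#>   selected k = 4
table(stilcLabels(fs), cohort$truth$archetype)
#>          cold hot
#>   sTILC1   30   0
#>   sTILC2    0  30

# compare LNM models on the clinical table
sc <- splitCohort(cohort$clinical, 0.2, seed = 1)
report <- compareLNMModels(sc$training,
                           list(training = sc$training,
                                validation = sc$validation),
                           seed = 1)
report
#> ModelComparisonReport across 2 cohorts
#>   training: AUC M1=0.992 M2=0.717 | DeLong z=3.404 p=0.000664 | Brier M1=0.050 M2=0.181
#>   validation: AUC M1=0.938 M2=0.875 | DeLong z=0.385 p=0.701 | Brier M1=0.114 M2=0.165
round(report@cohorts$validation$shapley$importance, 4)
#>   age_cat   t_stage til_score     stilc
#>    0.0297    0.0898    0.1669    0.0392
```

The two-means sTILC labels recover the planted archetypes exactly, and the
M1 model (with TIL features) shows the higher AUC and lower Brier score in
both folds, with the TIL score carrying the largest mean |Shapley| value
(higher scores push predicted risk down — the protective direction). On
this 48×48-patch desk-scale cohort the silhouette and Davies-Bouldin
metrics prefer finer partitions of the diffuse dense-TIL class, so the
consensus selects k = 4 while Calinski-Harabasz votes k = 2; the methods
vignette discusses why this is a property of small lattices. At 12
validation patients the DeLong p-value is unstable; cohorts of a few
hundred patients give the comparison its intended resolution.

An end-to-end run with intermediate CSVs, a JSON report and a manifest:

```r
runFullPipeline(runConfig("out/", nPatients = 60))
```

or from a shell via the thin wrapper
`Rscript inst/scripts/stilmap.R pipeline --config config.yaml`.

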
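# libstissue

Tissue discrimination from laser-induced breakdown spectroscopy (LIBS)
spectra of mandibular bone-infiltrating head and neck cancer.

LIBS reads the elemental composition of a tissue micro-volume from the
optical emission of a laser-generated plasma; one laser shot yields one
spectrum. For laser-surgical feedback control in the mandible, four
histologically validated tissue classes must be told apart: **fibrosis**,
the **inferior alveolar nerve**, **tumor stroma**, and **cell-rich tumor**.
The discriminating biomarkers are the per-shot summed peak areas of
Ca-associated emission bins (11 bins, 547.89–650.8 nm), the K doublet
(765.86 / 770.76 nm), and — carried along but not discriminative — the Na
lines (589.14 / 819.42 nm).

This package is aimed at biostatisticians and biomedical-spectroscopy
researchers who want the full analysis chain as tested, reusable code:

* **Spectrum I/O and catalog** — long-format CSV spectra on uniform grids;
  an element-tagged wavelength-bin catalog (the 15 lines above by default,
  configurable via a YAML config).
* **Preprocessing** — per-spectrum constant baseline subtraction (5th
  percentile of out-of-window samples), base-peak normalization (divide by
  the maximum, removing the per-shot gain), and per-bin peak areas as
  discrete sample-sums over each 2 nm window.
* **Electrolyte features** — `ca_sum`, `k_sum`, `na_sum` per shot.
* **Group statistics** — per-class median/IQR; Kruskal–Wallis omnibus test
  (mid-rank H with tie correction, chi-square df = k−1); Dunn's post hoc
  mean-rank z-tests with Bonferroni adjustment over the 6 pairs.
* **Diagnostic accuracy** — pairwise Mann–Whitney AUC
  (AUC = P(X_pos > X_neg), ties half-weighted), DeLong 95% CI, p-value
  against AUC = 0.5, and the Youden-optimal cutoff
  (max J = sensitivity + specificity − 1, midpoint threshold candidates).
* **Metric scales** — per element, the four classes ordered by median with
  Youden cutoffs between median-adjacent classes, partitioning the
  peak-area axis into four decision intervals; `classify()` applies a scale
  to new values.
* **PCA view** — covariance PCA of the 13 Ca+K bin areas, axes anchored by
  healthy-bone / tumor reference spectra, with ranked loading reports.
* **Synthetic cohort generator** — per-class log-normal distributions of
  the element sums calibrated in closed form from published median/IQR
  summaries (`mu = ln m`, `sigma = asinh(IQR/2m)/z0.75`), rendered into
  single-shot spectra whose measurement by the pipeline inverts the
  generation exactly when noise is off. Default class sizes are the study's
  254 / 516 / 821 / 1458 shots.

The methods vignette (`vignettes/libs-tissue-discrimination.Rmd`) documents
the models, parameter choices and limitations in detail.

## Worked example

Generate the study-scale synthetic cohort, run the pipeline, and build the
K metric scale (about half a minute):

```r
library(libstissue)

catalog  <- default_catalog()
spectra  <- generate_dataset(default_model(), dataset_spec(seed = 42),
                             catalog, default_grid())
features <- features_table(preprocess_all(spectra, catalog), catalog)

summarize_groups(features, "Ca")
#>            tissue    n    median       iqr
#> 1        fibrosis  254  5.012621  8.262951
#> 2           nerve  516 63.664552 14.977065
#> 3    tumor_stroma  821 30.107274 40.195489
#> 4 cell_rich_tumor 1458  2.010600  6.402276
```

The recovered class medians sit within a few percent of the calibration
inputs (fibrosis 4.973, nerve 63.64, stroma 30.04, cell-rich 1.974 AU) —
the nerve's bony canal gives it an order of magnitude more Ca than
cell-rich tumor. The K areas separate the classes the other way around:

```r
kw <- kruskal_wallis(split(features$k_sum, features$tissue))
#> Kruskal-Wallis (K): H = 1512.0, df = 3, p < 1e-300

build_metric_scale(features, "K")
#> <metric_scale> K
#>   [0, 2.24932) -> nerve
#>   [2.24932, 4.42125) -> fibrosis
#>   [4.42125, 5.16628) -> tumor_stroma
#>   [5.16628, Inf) -> cell_rich_tumor

classify(c(1.2, 3.3, 6.5), build_metric_scale(features, "K"))
#> [1] "nerve"           "fibrosis"        "cell_rich_tumor"
```

Pairwise ROC rows (here: fibrosis against the other classes by Ca) carry
the oriented AUC, DeLong CI, and the Youden cutoff with its operating
point:

```r
roc <- pairwise_roc_report(features)
#>   positive_class  negative_class    auc  ci_lo  ci_hi cutoff sensitivity specificity
#> 1       fibrosis           nerve 0.9890 0.9780 0.9999 40.513      0.9724      0.9981
#> 3       fibrosis    tumor_stroma 0.8930 0.8697 0.9164 11.928      0.7835      0.8417
#> 5       fibrosis cell_rich_tumor 0.6643 0.6351 0.6935  1.574      0.8543      0.4472
```

Fibrosis separates almost perfectly from nerve by Ca but poorly from
cell-rich tumor — for that pair K is the better element (AUC ≈ 0.97 vs
0.66), which is exactly the element-specific structure the metric scales
encode.

## Analysis workflow

Numbered drivers under `analysis/` chain the stages and write small tables
to `results/` (intermediates go to `scratch/`, regenerable):

```sh
Rscript analysis/01_simulate_features.R   # cohort -> areas + features
Rscript analysis/02_group_statistics.R    # median/IQR, Kruskal-Wallis, Dunn
Rscript analysis/03_roc_scales.R          # 12 ROC rows, Ca + K metric scales
Rscript analysis/04_pca.R                 # anchored PCA, loadings, scores
```

`run_pipeline(out_dir, seed)` performs the same chain in one call and
writes a reproducible report bundle (areas/features CSVs plus
summary/pairwise/roc/scales/pca JSON and a manifest).

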
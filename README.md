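# radtiles

CT radiomics prediction of tumor-infiltrating lymphocyte (TIL) enrichment
in solid tumors, with survival analysis of immunotherapy outcomes.

TIL enrichment in the tumor microenvironment predicts benefit from immune
checkpoint inhibitors in non-small cell lung cancer, but measuring it
requires a biopsy. `radtiles` implements the full computational chain that
links CT texture to a pathology-derived TIL enrichment score (TILes), for
imaging scientists who want a reusable, tested version of that pipeline:

* **TILes scoring** from gridded H&E TIL-density maps. A grid is *inflamed*
  (high intra-tumoral TIL density), *immune-excluded* (high stromal
  density) or a *desert*, and

  TILes = (TME area of inflamed + immune-excluded grids) / (total
  analyzable TME area) ∈ [0, 1],

  with sample-level quality control (≥ 0.5 mm² cancer epithelium, ≥ 10
  evaluable grids; boundaries pass).
* **An 88-feature radiomic extractor** over a masked CT volume, in seven
  categories (18 first-order / 14 shape / 24 GLCM / 16 GLSZM / 5 CDF /
  2 physical / 9 fractal). The gray-level size-zone matrix (GLSZM) block is
  the verified core: with p(i,j) = P(i,j)/N_z and μ = Σ i·p(i,j),

  GLV = Σ p(i,j)(i − μ)²,  LALGLE = (1/N_z) Σ P(i,j) j²/i².

* **The selection pipeline**: per-feature median split (ties to high) →
  pooled-variance t test of TILes at p < 0.005 → alias removal → iterative
  VIF filter at 10 → LASSO (coordinate descent, seeded 10-fold CV, KKT
  verified at 1e-6).
* **The published two-feature predicted-TILes model** (GLV coefficient
  1.71×10⁻³, LALGLE coefficient −2.48×10⁻⁵, intercept unknown → scores up
  to a constant) as a versioned JSON asset.
* **Outcome statistics** by predicted-TILes group: Kaplan-Meier with
  log-log Greenwood intervals, log-rank, univariate → multivariate Cox
  (entry at p < 0.05, Efron ties), Spearman / Wilcoxon / Fisher-with-OR.
* **A synthetic cohort generator**: latent tumor heterogeneity h drives CT
  texture variance up, necrotic low-attenuation volume down, the
  probability of TIL-hot pathology grids up, and hazard down — so the whole
  chain is testable end to end without patient data.

## A worked example

```r
library(radtiles)

run <- full_run(seed = 1, n_subjects = 150)

run$selected
#>  [1] "firstorder_energy"                        "firstorder_minimum"
#>  [3] "firstorder_p10"                           "firstorder_mean"
#>  [5] "firstorder_kurtosis"                      "firstorder_variance"
#>  [7] "glcm_autocorrelation"                     "glcm_correlation"
#>  [9] "glcm_imc1"                                "glcm_sum_entropy"
#> [11] "glszm_small_area_emphasis"                "glszm_gray_level_variance"
#> [13] "glszm_small_area_low_gray_level_emphasis" "cdf_upper_tail_fraction"

cor(run$subjects$score, run$subjects$tiles, method = "spearman")
#> [1] 0.9150718

run$survival$medians
#> # A tibble: 2 x 6
#>   group     n events median ci_lower ci_upper
#>   <chr> <dbl>  <dbl>  <dbl>    <dbl>    <dbl>
#> 1 high     75     59   4.62     2.85     6.49
#> 2 low      75     67   2.69     1.98     4.20

run$survival$cox[, c("term", "hr", "ci_lower", "ci_upper", "p")]
#>       term       hr  ci_lower ci_upper         p
#> 1 grouplow 1.298551 0.9123292 1.848274 0.1469135
```

The generator plants a texture -> TILes -> survival chain. The selection
pipeline fits a model from the 88 extracted features (gray level variance
among the kept features, with a positive coefficient); predicted scores
rank-correlate with the true TILes at rho = 0.92; splitting at the median
predicted score separates the planted survival difference (median
progression-free time 4.6 vs 2.7 months; the low-TILes group's hazard ratio
is 1.30, not significant at this cohort size).

Individual stages are plain functions over data frames:

```r
grids <- read_til_grid_csv("til_grids.csv")
tiles <- tiles_score_cohort(grids)

vol  <- read_volume_nifti("S001_volume.nii.gz")
mask <- roi_mask(array(as.numeric(read_volume_nifti("S001_mask.nii.gz")) > 0.5, dim(vol)))
feats <- extract_features(vol, mask)

predict_tiles(feats, published_model())
```

A thin command-line wrapper with subcommands `simulate`, `tiles`,
`extract`, `select`, `predict`, `survive` and `full-run` is installed at
`inst/exec/radtiles` (all subcommands write a `manifest.json` capturing
every option that shaped the numbers).

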
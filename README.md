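# multiscan

Quantitative evaluation of rapidly acquired, co-registered multicontrast
structural brain MRI, for imaging methodologists who need to know how much
information a one-minute multicontrast scan actually carries. The package
implements the full desk-side evaluation battery around such scans:

- **Label overlap** — Dice scoring of registered label atlases,
  `D = 2|A∩B| / (|A|+|B|)`, global (label-equality pooling) and per region.
- **Coverage and aggregation** — inclusive ≥80% voxel- and region-coverage
  filters for reduced field-of-view scans, zero-excluded regional medians,
  FWHM-specified Gaussian smoothing, 26-connectivity mask dilation.
- **Correspondence and identifiability** — Spearman correspondence maps
  across subjects with Benjamini–Hochberg FDR; the subject × subject
  cross-modality correlation matrix; differential identifiability
  `I_diff = Md(ρ_within) − Md(ρ_between)`; per-subject individual
  identifiability fractions under either modality as reference.
- **Networks** — structural covariance networks (across subjects),
  morphometric similarity networks (within subject, after median/MAD
  normalisation `Z = (x − Md(x)) / MAD(x)` of each regional feature map),
  proportional thresholding, group averaging, and network comparison
  overall or by community blocks.
- **Spatial nulls** — spherical spin permutations (uniform rotations of
  region centroids, hemispherically mirrored, nearest-neighbour
  reassignment) with add-one permutation p-values.
- **Phenotype regression** — edge-wise `edge ~ age + sex` least squares with
  age-stratified 5-fold cross-validated explained-variance scores.
- **Reliability** — test–retest ICC(3,1)
  `(MS_subjects − MS_error) / (MS_subjects + (k−1) MS_error)` per voxel,
  region and network edge.
- **Synthetic phantoms** — a generator of multi-subject, multicontrast,
  spatially autocorrelated volumes with tunable subject signatures,
  hemispheric symmetry, field-of-view truncation, repeat-scan noise and
  planted age/sex effects, whose truth record carries closed-form expected
  within/between correlations — so every stage above is testable end to end
  without downloading any imaging data.

Results are tibbles (or matrices with `tidy()`/`glance()` methods), and the
main result types have `autoplot()` methods.

## Worked example

```r
library(multiscan)

spec <- phantom_spec(n_subjects = 30, n_contrasts = 2, n_regions = 32, seed = 1)
ph   <- generate_phantom(spec)
tabs <- phantom_feature_tables(ph)   # coverage-filtered regional medians

C <- cross_modal_matrix(tabs$T1FLAIR, tabs$T2, feature_space = "regions")
differential_identifiability(C)
#> <identifiability> I_diff = 0.215 (within 0.550 - between 0.334), N = 30
ph$truth$expected_i_diff
#> [1] 0.2470579
```

The phantom plants a subject signature of weight 0.6 coupled across
contrasts at 0.7; the generator's closed form predicts a differential
identifiability of 0.247 and the empirical estimate from 30 subjects and 32
regions lands within sampling error of it. The median within-subject
correlation (0.550) exceeding the between-subject one (0.334) is what makes
subjects identifiable across contrasts:

```r
median(individual_identifiability(C, "modalityA")$fraction)
#> [1] 0.9482759
```

i.e. for the median subject, the own-scan correlation beats ~95% of the
other candidates. Higher-level suites wrap the stages:

```r
rel <- run_reliability_suite(ph, pipeline_config(), contrasts = "T1FLAIR")
dplyr::filter(rel$summary, feature_space == "regions")$md_icc
#> [1] 0.9353165
```

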
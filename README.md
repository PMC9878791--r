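# phenodisc

**Which recorded variables discriminate my groups?**

Phenotyping pipelines — mouse behavioural batteries, clinical test
panels — produce tables of mixed measurements per individual: quantitative
readouts (latencies, counts, thresholds) next to qualitative design
variables (genotype, sex, treatment). `phenodisc` identifies the variables
that best discriminate the levels of one categorical outcome, for
biologists and biostatisticians who need a ranked, publication-ready answer
rather than a single omnibus p-value.

## What it computes

For a table of $n$ individuals with $p_1$ quantitative and $q$ qualitative
variables ($m$ qualitative levels in total):

* **Mixed-data PCA / MFA** — a generalized SVD of the standardized
  quantitative block and the frequency-weighted centered indicator block
  (total inertia $p_1 + m - q$), reducing to correlation-matrix PCA or to
  multiple correspondence analysis at the two pure ends. Variables recorded
  in the same test (declared as `"Test::readout"` column labels) form
  groups; each group is down-weighted by its first eigenvalue
  ($w_g = 1/\lambda_1(g)$, multiple factor analysis) so no test dominates.
  Squared loadings ($r^2$ / correlation ratio $\eta^2$) sum per dimension
  to the eigenvalue.
* **Pre-selection** — greedy removal of one member of each pair with
  $|r| > 0.75$, then the "sel30" rule: keep variables whose squared loading
  on one of the first 3 dimensions reaches 30%. Three nested models result:
  *full*, *decorrelated*, *sel30*.
* **Classifier importance** — binary logistic GLM (|Wald z|), multinomial
  softmax regression (per-class |coefficient|), elastic net tuned over
  $(\alpha, \lambda)$ by CV, and an in-package compiled random forest
  (Gini importance, out-of-bag accuracy); each importance set rescaled so
  the top variable reads 100, plus bootstrap/CV accuracy estimates.
* **Imputation** — stratum mean for isolated missing cells, bootstrapped
  predictive mean matching (K = 5 donors, 10 rounds) for the rest.
* **Outputs** — nine figure folders (partial axes, group contributions,
  2D/3D individual maps, squared loadings, correlation circle, level maps,
  parallel coordinates, importance dot plots, cumulative variance), each
  figure with a machine-readable TSV twin, plus a JSON run manifest.

## Worked example

Simulate a 112-animal cohort (3 genotypes × 2 sexes, 12 traits: 3 with an
additive gene-dosage effect, 1 with a non-monotone heterozygote effect,
8 pure noise, 2% missing cells) and run the full analysis:

```r
library(phenodisc)

cohort <- generate_cohort(synthetic_spec(seed = 42))
cohort$table
#> pheno_table: 112 individuals x 14 variables
#>   dependent:    genotype
#>   conditioning: sex
#>   predictors:   12 quantitative, 0 qualitative
#>   missing cells: 22; imputed cells: 0

cfg <- pd_config(dependent = "genotype", conditioning = "sex", seed = 42,
                 n_trees = 300, classifiers = c("multiglm", "glmnet", "rf"))
res <- run_pipeline(cohort$table, cfg, outdir = "out")  # writes plots + TSVs

res$models$sel30$variables
#> [1] "SigLin1"    "SigLin2"    "SigLin3"    "SigNonLin1"
```

The sel30 model recovered exactly the four planted signal variables and
discarded all eight noise traits. Its factor space concentrates the
variance (dimension 1 is the gene-dosage axis, dimension 2 the
heterozygote-deviation + sex axis):

```r
res$models$sel30$cumulative_variance
#>  dim eigenvalue percentage cumulative
#>    1      2.095      39.13       39.1
#>    2      1.527      28.52       67.6
#>    3      0.625      11.67       79.3
#>    ...
#>    6      0.298       5.57      100.0
```

Random-forest importance ranks the non-monotone trait first — exactly the
effect a linear classifier underrates — with the three dosage traits close
behind; resampled accuracy for the 3-genotype outcome is ~0.74 for all
three classifiers:

```r
imp <- res$models$sel30$importances
imp[imp$classifier == "rf", c("variable", "scaled")]
#>    variable scaled
#>  SigNonLin1  100.0
#>     SigLin2   87.1
#>     SigLin3   80.9
#>     SigLin1   78.4

sapply(res$models$sel30$accuracy, function(a) round(a$mean, 3))
#> multiglm   glmnet       rf
#>    0.741    0.734    0.737
```

`out/` then contains, per model, the nine output folders
(`partialAxes_Plot1` … `cumulativeVariance`), the selection report and the
manifest.

## Command line

```sh
Rscript inst/cli/phenodisc simulate --out cohort.csv --truth truth.json --seed 5
Rscript inst/cli/phenodisc run --input cohort.csv --dependent genotype \
    --conditioning sex --id id --outdir results --seed 5
```

Exit codes: 0 success, 2 configuration error, 3 data error, 4 stage failure.

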
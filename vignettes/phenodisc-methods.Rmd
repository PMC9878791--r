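---
title: "Methods: mixed-data factor analysis and classifier-based phenotype discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-data factor analysis and classifier-based phenotype discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A phenotyping pipeline records, for every animal or patient, a table of
mixed measurements: quantitative test readouts (latencies, counts,
thresholds) alongside qualitative design variables (genotype, sex,
treatment). The scientific question is usually not "is there any effect"
but *which recorded variables carry the discrimination* between the levels
of one categorical outcome — typically genotype. `phenodisc` answers this
with three complementary layers: an unsupervised mixed-data factor
analysis, two feature pre-selection rules, and supervised variable-importance
ranking by four classifiers.

# The factor model

## Mixed-data PCA

Let the table hold $p_1$ quantitative variables and $q$ qualitative
variables with $m$ levels in total, over $n$ individuals. `pcamix()`
performs the generalized SVD of the concatenated matrix

* quantitative block: each column centered and divided by its population
  standard deviation, then by $\sqrt{n}$;
* qualitative block: the centered indicator matrix, with the column of
  level $s$ scaled by $1/\sqrt{n_s}$ ($n_s$ = level count), i.e. the
  correspondence-analysis metric $n/n_s$ folded into the matrix.

A plain SVD of this matrix then realizes the generalized decomposition:
eigenvalues are squared singular values, individual coordinates are
$F = \sqrt{n}\,U D$, and the total inertia is exactly
$p_1 + (m - q)$. With $q = 0$ the method reduces to PCA of the correlation
matrix; with $p_1 = 0$, to multiple correspondence analysis whose
eigenvalues are $q$ times those of the correspondence analysis of the
indicator table. Both reductions are verified against independent oracles
in the test suite on dozens of random instances.

The *squared loading* of a variable on a dimension is the squared
correlation $r^2$ for a quantitative variable and the correlation ratio
$\eta^2$ for a qualitative one; per dimension, squared loadings sum to the
eigenvalue. Axis signs are fixed deterministically (the largest-magnitude
loading of each axis is made positive); eigenvalues below $10^{-10}$ are
treated as rank deficiency and dropped; all eigen-identities are tested at
relative tolerance $10^{-8}$.

## Group weighting (MFA)

Several readouts of one behavioural test form a group (declared with
`"Test::variable"` column labels). A test that records many correlated
readouts would otherwise dominate the leading dimensions. `mfamix()` gives
every variable of group $g$ the metric weight $1/\lambda_1(g)$, where
$\lambda_1(g)$ is the first eigenvalue of the mixed-data PCA of group $g$
alone — equivalently, dividing the group's columns by
$\sqrt{\lambda_1(g)}$ — and reruns the global analysis on the weighted
ensemble. After weighting, no group can contribute more than 1 to any
global eigenvalue, and re-analyzing a single group's weighted variables
yields first eigenvalue exactly 1 (a test-suite invariant). Descriptions of
this step sometimes say the variables are divided "by the first
eigenvalue"; classical MFA — and this package — divides the *inertia* by
$\lambda_1$, i.e. the values by its square root. Group contributions,
partial axes (correlations of each group's own dimensions with the global
ones) and partial individual coordinates (whose group average returns the
global coordinates) are derived from the same decomposition. Ungrouped
variables are singleton groups.

The dependent variable participates in the factor analysis as an ordinary
qualitative variable — its levels are plotted in the component maps — but
is never handed to a classifier as a predictor.

# Pre-processing

* **Low-information filter.** Quantitative variables with fewer than 3
  unique values and qualitative variables with fewer than 2 observed
  levels are removed; a degenerate dependent variable is an error.
* **Imputation.** A (variable, stratum) pair with exactly one missing cell
  — strata being the conditioning design cells, e.g. genotype × sex — is
  filled with the stratum mean. Everything else goes through bootstrapped
  additive-regression predictive mean matching: per bootstrap round, a
  linear regression of the target on all other variables (one-hot encoded)
  is fitted on a resample of the complete cases; the missing case and all
  complete cases are predicted; the K = 5 complete cases with the closest
  predictions donate, and one donor's *observed* value is drawn uniformly.
  Ten rounds are averaged for quantitative targets (modal category for
  qualitative ones). Every single-round value is a member of the observed
  donor pool — deliberately not a group mean, so imputations carry
  realistic biological variability. Variables are imputed in increasing
  order of missingness, completed columns serving later fits. "Additive
  regression" is realized as linear least squares; spline basis expansion
  is a possible extension but the donor-matching semantics, which is the
  point of the method, does not depend on it. A warning (not an error) is
  raised when any stratum holds fewer than 10 individuals, where no
  imputation is really defensible.
* **Scaling.** Quantitative variables are standardized to mean 0, unit
  sample (n−1) standard deviation; the constants are kept so group
  summaries and parallel plots can be reported on the original scale.

# Feature pre-selection and the three models

**Correlation filter.** Pearson $r$ between quantitative pairs,
point-biserial $r$ for quantitative–binary pairs, Cramér's V (reported,
never used for removal — it is unsigned and on a different scale) for
qualitative pairs, each with a two-sided p-value (descriptive, unadjusted).
While any removable pair exceeds the threshold (default $|r| > 0.75$), the
member of the worst pair with the larger mean absolute correlation to all
other variables is removed; ties break by column order. Conditioning
variables are design variables and are never auto-removed; their violations
are logged and the partner is removed instead.

**Contribution rule.** After the MFA on the decorrelated set, a variable
enters the reduced model when its contribution to at least one of the first
3 dimensions reaches 30%. Contribution is measured on the squared-loading
scale — $r^2$ for quantitative variables, $\eta^2$ for qualitative ones, so
sex competes with the traits on the same footing — computed on the
*unweighted* data (MFA group weights must not change what "associated with
the dimension" means). The unsquared reading ($|r| \ge 0.30$) is available
as `contribution_scale = "correlation"`, but it is far too permissive to
act as a selector: in simulation, dimensions 2–3 are partly noise mixtures
and most pure-noise variables pass $|r| \ge 0.30$ with one of them, whereas
under the squared reading the selector retains all planted signal variables
while admitting at most a couple of noise variables (see the acceptance
suite). The squared reading is also the conventional meaning of a
variable's percentage contribution to a component.

The three analysis models are nested: **full** (everything after the
low-information filter — analyzed even when correlated variables remain,
so the analyst can see what removal changes), **decorrelated**, and
**sel30** (the contribution-selected subset).

# Classifiers and importance

The importance of a variable is deliberately classifier-specific; no single
definition is canonical, so each definition is explicit:

| classifier | model | raw importance | tuning |
|---|---|---|---|
| `glm` | binary logistic regression | absolute Wald $z$ | — |
| `multiglm` | softmax (multinomial) regression, decay $10^{-4}$ | per-class absolute standardized coefficient | — |
| `glmnet` | elastic net (binomial / grouped multinomial) | per-class absolute coefficient at the selected penalty | $\alpha \in \{0.1,\dots,1\}$, $\lambda$ path of 50, by CV classification error |
| `rf` | random forest, 500 CART trees, $\texttt{mtry}=\lfloor\sqrt p\rfloor$, Gini | mean decrease in impurity (classwide) | — |

Qualitative predictors take the maximum over their dummy columns. Within
every classifier × model × class the importances are rescaled so the top
variable reads exactly 100 (all zero stays all zero). Under perfect
separation the GLM's Wald statistics degenerate; importances then come from
a weakly ridge-regularized refit and the output is flagged. The forest is
implemented in compiled code inside the package (bootstrap per tree,
per-node feature subsampling, out-of-bag votes) and is seed-deterministic.

The division of labour matters scientifically: the linear-in-features
classifiers are the sensitive instruments for gene-dosage (additive)
effects, while the forest also captures non-monotone effects — e.g. a trait
on which only heterozygotes deviate is invisible to a WT-vs-Homo logistic
contrast (the class means cancel exactly) but is found by the forest. A
multinomial model *does* see such an effect through its heterozygote-class
coefficients; the binary GLM is therefore the clean linear counterpart in
that contrast.

**Accuracy.** Estimated by resampling: 25 bootstrap rounds
(train-on-resample, test out-of-bag) by default, or stratified k-fold CV.
The bootstrap variant is known to be *pessimistically biased* for
uninformative predictors — classes over-represented in a resample are
under-represented out-of-bag, and an overfit model votes with the in-bag
composition — which is visible as below-chance accuracy under label
permutation (~26% instead of 33% for three balanced classes). For
calibration questions use the stratified CV method, which is what the
acceptance suite does; the null then sits at 33% as it should.

# The synthetic cohort

`generate_cohort()` draws the world the pipeline assumes: 3 genotypes
(WT/Het/Homo dosage 0/1/2) × 2 sexes with unbalanced stratum sizes
(defaults 36/39/37 per genotype, 57 F / 55 M, n = 112 — the shape of a
mid-size mouse phenotyping cohort), 12 quantitative traits of which 3 carry
an additive dosage shift of 0.8 within-stratum SD per mutant allele (a
strong but realistic behavioural effect), 1 is non-monotone (heterozygotes
shifted by 1.2 SD, homozygous classes equal — the hardest pattern for
linear contrasts), and 8 are pure noise; a 0.5 SD sex effect rides on the
linear traits so sex is a genuine conditioning variable; traits are normal
within stratum, partly organized into `"Test::readout"` groups; 2% of
trait cells are missing completely at random (a `mar_by_sex` switch makes
missingness sex-dependent to stress the imputer). These values were fixed
once, before any test was run, and are not tuned.

What a green test on this cohort does **not** establish: robustness to
heavy-tailed or count-valued readouts (one optional log-normal trait only),
to informative missingness beyond MAR-by-sex, to measurement batch
effects, or to cohorts where groups of readouts are strongly
cross-correlated between tests. Real phenotyping data have all of these.

# Numerical choices and degenerate inputs

* Eigen-tolerances: $10^{-8}$ relative in tests, $10^{-10}$ rank cutoff.
* Importance rescaling computes `100 * (raw/max)` in that order so the
  maximum is exactly 100 in floating point.
* Ties in the correlation-removal rule break by input column order; ties
  in forest splits resolve to the first-encountered best split; donor ties
  in PMM break by row order before the seeded uniform draw.
* All randomness derives from one master seed through fixed per-stage
  offsets, so every stage is independently reproducible and a rerun is
  bit-identical.
* Degenerate inputs raise named errors (`pd_zero_variance`,
  `pd_degenerate_dependent`, `pd_too_few_complete`, ...); a pipeline stage
  failure reports the stage name and keeps prior outputs.

# Known limitations

* Importance definitions are stand-ins; the literature offers no canonical
  formula for "importance" in any of the four families, and permutation
  importance for the forest is the obvious alternative to impurity
  decrease (configurable in spirit, impurity is the default here).
* PMM runs on the full table with conditioning variables as predictors
  rather than within conditioning strata; with very small strata the
  within-stratum alternative would starve the donor pool.
* The p-values attached to the correlation matrix are raw and descriptive;
  no multiplicity correction is applied or intended.
* Single completed dataset: the pipeline does not pool multiple
  imputations (Rubin's rules) — downstream variance estimates ignore
  imputation uncertainty.
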
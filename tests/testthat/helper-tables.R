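# fixtures are built in code: a minimal hand-made table and a quick wrapper
# around the synthetic generator

tiny_table <- function(n = 12, seed = 1) {
  set.seed(seed)
  data <- data.frame(
    genotype = rep(c("WT", "Mut"), length.out = n),
    sex = rep(c("F", "F", "M"), length.out = n),
    weight = rnorm(n, 20, 2),
    latency = rnorm(n, 5, 1),
    stringsAsFactors = FALSE)
  roles <- c(genotype = "dependent", sex = "conditioning",
             weight = "predictor", latency = "predictor")
  types <- c(genotype = "qualitative", sex = "qualitative",
             weight = "quantitative", latency = "quantitative")
  pheno_table(data, sprintf("M%02d", seq_len(n)), roles, types)
}

quick_cohort <- function(seed = 1, missing_rate = 0, ...) {
  generate_cohort(synthetic_spec(seed = seed, missing_rate = missing_rate, ...))
}

# impute + scale a cohort table the way the pipeline does
prep_table <- function(tab, seed = 1) {
  tab <- suppressWarnings(impute_group_mean(tab))
  if (anyNA(as.matrix(tab$data))) {
    tab <- impute_pmm(tab, imputation_spec(seed = seed))
  }
  scale_features(tab)
}
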
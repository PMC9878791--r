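#' Run configuration
#'
#' Collects every analyst-tunable parameter of the discrimination pipeline in
#' one validated object. The two scientific thresholds default to the values
#' recommended for phenotyping cohorts: predictor pairs correlated beyond
#' `correlation_threshold` are considered redundant and one of each pair is
#' removed, and a variable enters the reduced ("sel30%") model when its
#' association with at least one of the first `n_dims_selection` factor
#' dimensions reaches `contribution_threshold`.
#'
#' @param dependent Name of the dependent (outcome) column, e.g. `"genotype"`.
#' @param id Name of the identifier column, or `NULL` if rows carry no ids.
#' @param conditioning Character vector of conditioning (design) columns such
#'   as sex or treatment; used for duplicate detection, stratified imputation
#'   and group summaries. May be empty.
#' @param correlation_threshold Absolute Pearson/point-biserial correlation
#'   above which one member of a predictor pair is removed. In (0, 1],
#'   default 0.75.
#' @param contribution_threshold Minimum contribution of a variable to a
#'   retained factor dimension for inclusion in the reduced model. In (0, 1),
#'   default 0.30.
#' @param contribution_scale `"squared"` (default; contribution = squared
#'   loading, i.e. r-squared or eta-squared) or `"correlation"` (threshold
#'   the unsquared |r|); see [select_contributing()].
#' @param n_dims_selection Number of leading dimensions inspected by the
#'   contribution rule (default 3).
#' @param n_dims_variance Number of dimensions reported in the cumulative
#'   variance table (default 10).
#' @param seed Master seed; all randomness in the pipeline is derived from it.
#' @param na_strings Cell spellings treated as missing on import.
#' @param type_overrides Named character vector forcing a column to
#'   `"quantitative"` or `"qualitative"`, overriding type inference.
#' @param anonymize Replace input identifiers with generated unique ones
#'   (default `TRUE`).
#' @param imputation See [imputation_spec()]; defaults used when `NULL`.
#' @param classifiers Character subset of
#'   `c("glm", "multiglm", "glmnet", "rf")` to run.
#' @param n_trees,n_boot_accuracy Random-forest size and number of bootstrap
#'   resamples for accuracy estimation.
#' @param sheet Sheet name for XLSX input (first sheet when `NULL`).
#' @return An object of class `pd_config`.
#' @examples
#' cfg <- pd_config(dependent = "genotype", conditioning = "sex", seed = 1)
#' cfg$correlation_threshold
#' @export
pd_config <- function(dependent,
                      id = NULL,
                      conditioning = character(),
                      correlation_threshold = 0.75,
                      contribution_threshold = 0.30,
                      contribution_scale = c("squared", "correlation"),
                      n_dims_selection = 3L,
                      n_dims_variance = 10L,
                      seed = 1L,
                      na_strings = c("", "NA", "NaN", "na"),
                      type_overrides = character(),
                      anonymize = TRUE,
                      imputation = NULL,
                      classifiers = c("glm", "multiglm", "glmnet", "rf"),
                      n_trees = 500L,
                      n_boot_accuracy = 25L,
                      sheet = NULL) {
  stopifnot(is.character(dependent), length(dependent) == 1L)
  if (!(correlation_threshold > 0 && correlation_threshold <= 1)) {
    stop("pd_bad_threshold: correlation_threshold must lie in (0, 1]")
  }
  if (!(contribution_threshold > 0 && contribution_threshold < 1)) {
    stop("pd_bad_threshold: contribution_threshold must lie in (0, 1)")
  }
  if (n_dims_selection < 1L || n_dims_variance < 1L) {
    stop("pd_bad_threshold: n_dims values must be >= 1")
  }
  classifiers <- match.arg(classifiers, c("glm", "multiglm", "glmnet", "rf"),
                           several.ok = TRUE)
  if (is.null(imputation)) imputation <- imputation_spec(seed = seed)
  structure(list(
    dependent = dependent,
    id = id,
    conditioning = as.character(conditioning),
    correlation_threshold = correlation_threshold,
    contribution_threshold = contribution_threshold,
    contribution_scale = match.arg(contribution_scale),
    n_dims_selection = as.integer(n_dims_selection),
    n_dims_variance = as.integer(n_dims_variance),
    seed = as.integer(seed),
    na_strings = na_strings,
    type_overrides = type_overrides,
    anonymize = isTRUE(anonymize),
    imputation = imputation,
    classifiers = classifiers,
    n_trees = as.integer(n_trees),
    n_boot_accuracy = as.integer(n_boot_accuracy),
    sheet = sheet
  ), class = "pd_config")
}

#' Imputation settings
#'
#' @param method `"pmm"` (bootstrapped additive-regression predictive mean
#'   matching, used whenever a variable has more than one missing cell per
#'   conditioning stratum) or `"group_mean"` only.
#' @param k Number of donor candidates whose predictions are closest to the
#'   missing case's prediction; the imputed value is drawn uniformly among
#'   their observed values. Default 5.
#' @param n_bootstrap Number of bootstrap refits averaged for quantitative
#'   targets (a single draw when 1). Default 10.
#' @param seed Seed for the imputation random stream.
#' @return An object of class `pd_imputation_spec`.
#' @export
imputation_spec <- function(method = c("pmm", "group_mean"), k = 5L,
                            n_bootstrap = 10L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(k >= 1L, n_bootstrap >= 1L)
  structure(list(method = method, k = as.integer(k),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "pd_imputation_spec")
}

#' @export
print.pd_config <- function(x, ...) {
  cat("phenodisc run configuration\n")
  cat("  dependent:    ", x$dependent, "\n")
  cat("  conditioning: ",
      if (length(x$conditioning)) paste(x$conditioning, collapse = ", ")
      else "(none)", "\n")
  cat("  |r| removal threshold:    ", x$correlation_threshold, "\n")
  cat("  contribution threshold:   ", x$contribution_threshold,
      "on dims 1..", x$n_dims_selection, "\n")
  cat("  classifiers: ", paste(x$classifiers, collapse = ", "), "\n")
  cat("  seed:        ", x$seed, "\n")
  invisible(x)
}

# Derive a reproducible child seed from the master seed for a named pipeline
# stage. Keeps every stream below 2^31 and independent of evaluation order.
derive_seed <- function(seed, stream) {
  offsets <- c(impute = 101L, glm = 211L, multiglm = 307L, glmnet = 401L,
               rf = 503L, accuracy = 601L, synthetic = 701L, selection = 811L)
  off <- offsets[[stream]]
  (as.integer(seed) * 1009L + off) %% 2147483629L
}
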
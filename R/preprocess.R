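#' Remove variables that cannot inform the discrimination
#'
#' Quantitative variables with fewer than 3 unique non-missing values and
#' qualitative variables with fewer than 2 observed levels are dropped: the
#' former cannot support an error estimate, the latter cannot separate
#' anything. The dependent variable is never dropped; if it fails the rule
#' the analysis is not salvageable and an error is raised instead.
#' Idempotent.
#'
#' @param x A [pheno_table].
#' @return List with elements `table` (filtered) and `removed` (named
#'   character vector: variable -> reason).
#' @export
drop_low_information <- function(x) {
  dep <- dependent_var(x)
  if (length(unique(stats::na.omit(x$data[[dep]]))) < 2L) {
    stop("pd_degenerate_dependent: dependent variable has fewer than 2 levels")
  }
  removed <- character(0)
  for (v in setdiff(names(x$data), dep)) {
    vals <- stats::na.omit(x$data[[v]])
    if (x$var_types[[v]] == "quantitative" && length(unique(vals)) < 3L) {
      removed[v] <- "fewer than 3 unique values"
    } else if (x$var_types[[v]] == "qualitative" && length(unique(vals)) < 2L) {
      removed[v] <- "fewer than 2 observed levels"
    }
  }
  list(table = keep_vars(x, setdiff(names(x$data), names(removed))),
       removed = removed)
}

stratum_key <- function(x, conditioning) {
  if (!length(conditioning)) return(rep("all", nrow(x$data)))
  do.call(paste, c(lapply(conditioning, function(v) as.character(x$data[[v]])),
                   sep = ":"))
}

#' Impute isolated missing values by the conditioning-stratum mean
#'
#' Applies only to (variable, stratum) cells where the stratum — defined by
#' the conditioning variables, e.g. genotype x sex — contains exactly one
#' missing value for that variable; that cell is set to the stratum mean of
#' the observed values. Strata with two or more missing cells are left for
#' [impute_pmm()]. A warning is emitted when any stratum holds fewer than 10
#' individuals, where imputation of any kind is questionable.
#'
#' @param x A [pheno_table].
#' @param conditioning Stratifying variables (defaults to the declared
#'   conditioning variables plus the dependent).
#' @return The table with single missing cells filled and `imputed` updated.
#' @export
impute_group_mean <- function(x, conditioning = NULL) {
  if (is.null(conditioning)) {
    conditioning <- c(dependent_var(x), conditioning_vars(x))
  }
  strata <- stratum_key(x, conditioning)
  small <- names(which(table(strata) < 10L))
  if (length(small)) {
    warning("conditioning stratum with fewer than 10 individuals: ",
            paste(small, collapse = ", "),
            " - imputation is not recommended at this group size")
  }
  log_rows <- list()
  for (v in predictor_vars(x, "quantitative")) {
    col <- x$data[[v]]
    for (s in unique(strata)) {
      idx <- which(strata == s)
      miss <- idx[is.na(col[idx])]
      if (length(miss) != 1L) next
      obs <- col[setdiff(idx, miss)]
      if (!length(obs) || all(is.na(obs))) {
        stop("pd_empty_stratum: no observed values for '", v, "' in stratum ", s)
      }
      col[miss] <- mean(obs, na.rm = TRUE)
      x$imputed[miss, v] <- TRUE
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        id = x$ids[miss], variable = v, stratum = s, method = "group_mean",
        donors = NA_character_, value = col[miss])
    }
    x$data[[v]] <- col
  }
  x$imputation_log <- rbind(x$imputation_log, do.call(rbind, log_rows))
  x
}

# numeric design matrix of all variables except `exclude`; qualitative
# variables one-hot encoded, remaining NAs mean-filled (fit-time only)
design_for_imputation <- function(x, exclude) {
  vars <- setdiff(names(x$data), exclude)
  cols <- list()
  for (v in vars) {
    if (x$var_types[[v]] == "quantitative") {
      col <- x$data[[v]]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      cols[[v]] <- col
    } else {
      f <- as.character(x$data[[v]])
      f[is.na(f)] <- "(missing)"
      levs <- unique(f)
      for (l in levs[-1]) cols[[paste0(v, "=", l)]] <- as.numeric(f == l)
    }
  }
  if (!length(cols)) return(matrix(1, nrow(x$data), 0))
  do.call(cbind, cols)
}

#' Impute by bootstrapped additive-regression predictive mean matching
#'
#' For every remaining missing cell of each variable (in increasing order of
#' missingness, so earlier completions can serve as predictors): draw a
#' bootstrap resample of the complete cases, fit a regression of the target
#' on all other variables, predict the missing case and every complete case,
#' take the `k` complete cases whose predictions are closest to the missing
#' case's prediction, and impute by drawing one of those donors' observed
#' values uniformly at random. With `n_bootstrap > 1` the rounds are averaged
#' for quantitative targets; qualitative targets take the modal drawn
#' category. Every single-round value is by construction a member of the
#' observed donor pool, which keeps imputations inside the support of the
#' data — deliberately not the stratum mean.
#'
#' @param x A [pheno_table].
#' @param spec An [imputation_spec()].
#' @return The table, missing cells filled, `imputed` mask and
#'   `imputation_log` updated.
#' @export
impute_pmm <- function(x, spec = imputation_spec()) {
  stopifnot(inherits(spec, "pd_imputation_spec"))
  set.seed(derive_seed(spec$seed, "impute"))
  miss_count <- vapply(x$data, function(c) sum(is.na(c)), 0L)
  targets <- names(sort(miss_count[miss_count > 0L]))
  log_rows <- list()
  for (v in targets) {
    col <- x$data[[v]]
    miss <- which(is.na(col))
    comp <- which(!is.na(col))
    if (length(comp) < spec$k) {
      stop("pd_too_few_complete: variable '", v, "' has ", length(comp),
           " complete cases but k = ", spec$k)
    }
    X <- design_for_imputation(x, v)
    qualitative <- x$var_types[[v]] == "qualitative"
    yv <- if (qualitative) as.character(col) else col
    draws <- matrix(if (qualitative) NA_character_ else NA_real_,
                    nrow = length(miss), ncol = spec$n_bootstrap)
    donor_log <- vector("list", length(miss))
    for (b in seq_len(spec$n_bootstrap)) {
      boot <- sample(comp, length(comp), replace = TRUE)
      yfit <- if (qualitative) as.numeric(factor(yv[boot])) else yv[boot]
      fit <- stats::lm.fit(cbind(1, X[boot, , drop = FALSE]), yfit)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred_all <- drop(cbind(1, X) %*% beta)
      for (i in seq_along(miss)) {
        d <- abs(pred_all[comp] - pred_all[miss[i]])
        donors <- comp[order(d, comp)][seq_len(spec$k)]
        pick <- donors[sample.int(spec$k, 1L)]
        draws[i, b] <- yv[pick]
        donor_log[[i]] <- union(donor_log[[i]], x$ids[pick])
      }
    }
    filled <- if (qualitative) {
      apply(draws, 1L, function(r) names(which.max(table(r))))
    } else {
      rowMeans(draws)
    }
    if (qualitative) {
      newcol <- as.character(col); newcol[miss] <- filled
      x$data[[v]] <- newcol
    } else {
      col[miss] <- filled
      x$data[[v]] <- col
    }
    x$imputed[miss, v] <- TRUE
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      id = x$ids[miss], variable = v, stratum = NA_character_, method = "pmm",
      donors = vapply(donor_log, paste, "", collapse = ","),
      value = as.character(filled))
  }
  x$imputation_log <- rbind(
    if (!is.null(x$imputation_log)) transform(x$imputation_log, value = as.character(value)),
    do.call(rbind, log_rows))
  x
}

#' Standardize the quantitative variables
#'
#' Centers every quantitative non-dependent variable to mean 0 and scales it
#' to unit sample standard deviation (n - 1 denominator), so variables
#' recorded on different scales contribute comparably to the factor analysis
#' and the classifiers. Qualitative variables are untouched. The centering
#' and scaling constants are stored on the table so group summaries can be
#' reported on the original scale. Must run after imputation.
#'
#' @param x A [pheno_table] with no missing quantitative cells.
#' @return The standardized table, constants in `$scaling`.
#' @export
scale_features <- function(x) {
  quant <- names(x$var_types)[x$var_types == "quantitative" &
                                x$var_roles != "dependent"]
  centers <- scales <- stats::setNames(numeric(0), character(0))
  for (v in quant) {
    col <- x$data[[v]]
    if (anyNA(col)) stop("pd_missing_at_scaling: '", v,
                         "' still has missing values; impute first")
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) {
      stop("pd_zero_variance: '", v, "' has zero variance (should have been dropped)")
    }
    centers[v] <- mean(col)
    scales[v] <- s
    x$data[[v]] <- (col - centers[v]) / s
  }
  x$scaling <- list(center = centers, scale = scales)
  x
}
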
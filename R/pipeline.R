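#' Run the full three-model discrimination analysis
#'
#' Orchestrates: import, anonymization, low-information filtering, imputation
#' (stratum mean for isolated holes, then predictive mean matching),
#' standardization, correlation-based removal, the contribution-based
#' pre-selection, and — for each of the three variable models —
#' group-weighted multiple factor analysis, the four importance classifiers,
#' resampled accuracy, and the nine plot/table outputs.
#'
#' The three models are: `full` (all variables surviving the
#' low-information filter, including any highly correlated ones),
#' `decorrelated` (after greedy |r|-threshold removal; the basis for the
#' pre-selection), and `sel30` (variables associated with at least one of
#' the three leading dimensions above the contribution threshold). Binary
#' logistic GLM runs only when the dependent variable has exactly two
#' levels; with more levels that slot is covered by the multinomial model.
#'
#' @param input A file path (XLSX/CSV/TSV) or a ready [pheno_table].
#' @param config A [pd_config()].
#' @param outdir Output directory (created). `NULL` disables all file
#'   output and plot rendering; results are only returned.
#' @return Invisibly, a list: `table` (preprocessed), `selection`,
#'   `models` (per model: variables, `mfa`, `cumulative_variance`,
#'   `importances`, `accuracy`), and `manifest` (config echo, input
#'   checksum, per-stage timings, output files, skipped plots).
#' @export
run_pipeline <- function(input, config, outdir = NULL) {
  stopifnot(inherits(config, "pd_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    now <- proc.time()[["elapsed"]]
    timings[stage] <<- round(now - t0, 3)
    t0 <<- now
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pd_stage_failure[", name, "]: ", conditionMessage(e), call. = FALSE)
    })
    tick(name)
    res
  }

  checksum <- NA_character_
  tab <- if (inherits(input, "pheno_table")) input else {
    checksum <- unname(tools::md5sum(input))
    stage("read", read_pheno_table(input, config))
  }
  if (config$anonymize) tab <- stage("anonymize", anonymize_ids(tab))
  li <- stage("drop_low_information", drop_low_information(tab))
  tab <- li$table
  had_na <- anyNA(as.matrix(tab$data))
  if (had_na) {
    tab <- stage("impute_group_mean",
                 suppressWarnings(impute_group_mean(tab)))
    if (anyNA(as.matrix(tab$data))) {
      tab <- stage("impute_pmm", impute_pmm(tab, config$imputation))
    }
  }
  tab <- stage("scale", scale_features(tab))

  report <- stage("correlation", {
    r <- correlation_matrix(tab)
    remove_correlated(r, config$correlation_threshold)
  })
  dep <- dependent_var(tab)
  full_vars <- setdiff(names(tab$data), dep)
  decor_vars <- report$kept

  mfa_on <- function(vars) {
    v <- c(vars, dep)   # the dependent participates as a qualitative variable
    v <- names(tab$data)[names(tab$data) %in% v]
    res <- mfamix(tab$data[, v, drop = FALSE], tab$var_types[v],
                  tab$var_groups[v], ndim = config$n_dims_variance)
    attr(res, "individual_groups") <- stratum_key(tab, c(dep, conditioning_vars(tab)))
    res
  }
  mfa_decor <- stage("mfa_decorrelated", mfa_on(decor_vars))
  sel <- stage("select_contributing",
               select_contributing(mfa_decor, config$contribution_threshold,
                                   config$n_dims_selection, exclude = dep,
                                   scale = config$contribution_scale))
  sel_vars <- intersect(decor_vars, sel)

  models <- list(full = full_vars, decorrelated = decor_vars, sel30 = sel_vars)
  summaries <- group_summaries(tab)
  y <- factor(tab$data[[dep]])
  outputs <- character(0)
  skipped <- character(0)
  results <- list()
  for (mname in names(models)) {
    vars <- models[[mname]]
    if (!length(vars)) {
      skipped[paste0("model:", mname)] <- "no variables selected"
      next
    }
    mfa <- if (mname == "decorrelated") mfa_decor else mfa_on(vars)
    cv <- cumulative_variance(mfa, config$n_dims_variance)

    pred <- tab$data[, vars, drop = FALSE]
    imps <- list(); accs <- list()
    for (clf in config$classifiers) {
      if (clf == "glm" && nlevels(y) != 2L) {
        skipped[paste0(mname, ":glm")] <- "dependent has >2 levels; covered by multiglm"
        next
      }
      imp <- switch(clf,
        glm = fit_glm_importance(pred, y),
        multiglm = fit_multiglm_importance(pred, y),
        glmnet = fit_glmnet_importance(pred, y, seed = config$seed),
        rf = fit_rf_importance(pred, y, n_trees = config$n_trees,
                               seed = config$seed))
      params <- switch(clf,
        glmnet = attr(imp, "tuning"),
        rf = list(n_trees = config$n_trees),
        list())
      acc <- assess_accuracy(pred, y, clf, n_resamples = config$n_boot_accuracy,
                             seed = config$seed, params = params)
      imp$model <- mname
      imps[[clf]] <- imp
      accs[[clf]] <- acc
    }
    importances <- do.call(rbind, imps)
    results[[mname]] <- list(variables = vars, mfa = mfa,
                             cumulative_variance = cv,
                             importances = importances, accuracy = accs)
    tick(paste0("classify_", mname))

    if (!is.null(outdir)) {
      mdir <- file.path(outdir, mname)
      man <- render_all(mfa = mfa, selection = report,
                        importances = importances, summaries = summaries,
                        style = style_spec(), outdir = mdir,
                        scaling = tab$scaling)
      outputs <- c(outputs, man$files)
      if (length(man$skipped)) {
        skipped[paste0(mname, ":", names(man$skipped))] <- man$skipped
      }
      acc_df <- data.frame(classifier = names(accs),
                           accuracy = vapply(accs, `[[`, 0, "mean"),
                           sd = vapply(accs, `[[`, 0, "sd"))
      outputs <- c(outputs,
                   write_tsv_twin(acc_df, file.path(mdir, "accuracy.tsv")),
                   write_tsv_twin(cv, file.path(mdir, "eigenvalues.tsv")))
      tick(paste0("render_", mname))
    }
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    outputs <- c(outputs, write_selection_report(report, file.path(outdir, "selection")))
    outputs <- c(outputs,
                 write_pheno_table(tab, file.path(outdir, "normalized_table.tsv")))
  }
  manifest <- list(
    config = unclass(config[c("dependent", "conditioning",
                              "correlation_threshold", "contribution_threshold",
                              "n_dims_selection", "n_dims_variance", "seed",
                              "classifiers")]),
    input_checksum = checksum,
    version = as.character(utils::packageVersion("phenodisc")),
    timings = as.list(timings),
    removed_low_information = names(li$removed),
    removed_correlated = report$removed,
    models = lapply(models, identity),
    outputs = outputs,
    skipped = as.list(skipped))
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(list(table = tab, selection = report, models = results,
                 manifest = manifest))
}
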
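# One-hot encode a predictor data.frame into a numeric matrix (first level
# of each qualitative variable dropped); returns the column -> variable map
# so dummy columns can be collapsed back to variable-level importances.
encode_predictors <- function(data) {
  cols <- list(); var_of <- character(0)
  for (v in names(data)) {
    col <- data[[v]]
    if (is.numeric(col)) {
      cols[[v]] <- col; var_of <- c(var_of, v)
    } else {
      f <- factor(col)
      for (l in levels(f)[-1]) {
        cols[[paste0(v, "=", l)]] <- as.numeric(f == l)
        var_of <- c(var_of, v)
      }
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, var_of = stats::setNames(var_of, colnames(X)))
}

# standardize columns of an encoded matrix (constant columns left at 0)
standardize_matrix <- function(X) {
  s <- apply(X, 2L, stats::sd)
  s[s == 0] <- 1
  scale(X, scale = s)
}

# collapse per-column raw importances to per-variable (max over dummies),
# then rescale so the most important variable scores exactly 100
importance_rows <- function(classifier, class, raw_cols, var_of) {
  vars <- unique(var_of)
  raw <- vapply(vars, function(v) max(raw_cols[var_of == v]), 0)
  # ratio first: guarantees the top variable scores exactly 100
  scaled <- if (max(raw) > 0) 100 * (raw / max(raw)) else raw * 0
  data.frame(classifier = classifier, class = class, variable = vars,
             raw = unname(raw), scaled = unname(scaled),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variable importance from a binary logistic GLM
#'
#' Fits a logistic regression of the (two-level) dependent variable on the
#' standardized, one-hot-encoded predictors and scores each variable by the
#' absolute Wald z-statistic of its coefficient (max over the dummy columns
#' of a qualitative variable), rescaled so the top variable reads 100. Under
#' perfect separation the Wald statistics degenerate; the importances are
#' then taken from a weakly ridge-regularized refit and the result is
#' flagged via the `"note"` attribute.
#'
#' @param data data.frame of predictor columns (numeric or categorical).
#' @param y Dependent variable with exactly 2 observed levels.
#' @return data.frame (classifier, class, variable, raw, scaled).
#' @export
fit_glm_importance <- function(data, y) {
  y <- factor(y)
  if (nlevels(y) != 2L) {
    stop("pd_not_binary: glm needs a 2-level dependent variable; use fit_multiglm_importance for ",
         nlevels(y), " levels")
  }
  enc <- encode_predictors(data)
  X <- standardize_matrix(enc$X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), as.integer(y) - 1L,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (!sep && fit$converged) {
    # Wald z = coef / se from the final IRLS weights
    w <- fit$weights
    XtWX <- crossprod(cbind(1, X) * sqrt(w))
    covb <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(covb)) sep <- TRUE else {
      z <- fit$coefficients / sqrt(diag(covb))
      raw <- abs(z[-1])
    }
  }
  if (sep || !fit$converged) {
    rfit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 0.01, standardize = FALSE)
    raw <- abs(as.vector(rfit$beta))
  }
  out <- importance_rows("glm", levels(y)[2], raw, enc$var_of)
  attr(out, "note") <- if (sep) "separation: weakly regularized refit" else NULL
  out
}

#' Variable importance from a multinomial log-linear model
#'
#' Fits a softmax (multinomial logistic) regression with a small quadratic
#' weight decay on the standardized encoded predictors and scores each
#' variable, per dependent-variable class, by the absolute value of its
#' class coefficient, rescaled to a within-class maximum of 100.
#'
#' @inheritParams fit_glm_importance
#' @param y Dependent variable with at least 2 levels.
#' @param decay Quadratic penalty on the non-intercept coefficients.
#' @return data.frame with one row set per class.
#' @export
fit_multiglm_importance <- function(data, y, decay = 1e-4) {
  y <- factor(y)
  enc <- encode_predictors(data)
  X <- standardize_matrix(enc$X)
  fit <- multinom_fit(X, y, decay = decay)
  B <- fit$coefficients[-1, , drop = FALSE]
  do.call(rbind, lapply(levels(y), function(cl) {
    importance_rows("multiglm", cl, abs(B[, cl]), enc$var_of)
  }))
}

#' Variable importance from an elastic-net GLM
#'
#' Tunes the mixing parameter alpha and penalty lambda by cross-validated
#' classification error (binomial or grouped multinomial family as the
#' number of classes dictates), then scores each variable per class by the
#' absolute coefficient at the selected penalty; variables shrunk to zero
#' get importance 0.
#'
#' @inheritParams fit_multiglm_importance
#' @param alphas Grid of elastic-net mixing values in (0, 1].
#' @param nlambda Length of the lambda path glmnet builds per alpha.
#' @param nfolds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return data.frame with attribute `"tuning"` = chosen (alpha, lambda).
#' @export
fit_glmnet_importance <- function(data, y, alphas = seq(0.1, 1, by = 0.1),
                                  nlambda = 50L, nfolds = 5L, seed = 1L) {
  if (!length(alphas) || !nlambda) stop("pd_degenerate_grid: empty tuning grid")
  y <- factor(y)
  enc <- encode_predictors(data)
  X <- standardize_matrix(enc$X)
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  set.seed(derive_seed(seed, "glmnet"))
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  best <- NULL
  for (a in alphas) {
    cv <- cv.glmnet_quiet(X, y, fam, a, foldid, nlambda)
    i <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(alpha = a, lambda = cv$lambda[i], cvm = cv$cvm[i],
                   fit = cv$glmnet.fit)
    }
  }
  co <- stats::coef(best$fit, s = best$lambda)
  rows <- if (fam == "binomial") {
    importance_rows("glmnet", levels(y)[2], abs(as.vector(co)[-1]), enc$var_of)
  } else {
    do.call(rbind, lapply(levels(y), function(cl) {
      importance_rows("glmnet", cl, abs(as.vector(co[[cl]])[-1]), enc$var_of)
    }))
  }
  attr(rows, "tuning") <- list(alpha = best$alpha, lambda = best$lambda)
  rows
}

cv.glmnet_quiet <- function(X, y, fam, alpha, foldid, nlambda) {
  suppressWarnings(glmnet::cv.glmnet(
    X, y, family = fam, alpha = alpha, foldid = foldid,
    nlambda = nlambda, type.measure = "class", standardize = FALSE,
    type.multinomial = "grouped"))
}

#' Variable importance from a random forest
#'
#' Grows a forest of CART trees (bootstrap per tree, `mtry` candidate
#' features per node, Gini impurity) and scores each variable by its mean
#' decrease in impurity, rescaled to a maximum of 100. The forest captures
#' non-linear and non-monotone genotype effects that a linear-in-features
#' classifier cannot represent. Out-of-bag accuracy is attached as the
#' `"oob_accuracy"` attribute.
#'
#' @inheritParams fit_multiglm_importance
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node Minimum node size (default 1).
#' @param seed Seed for the forest's randomness.
#' @return data.frame; RF impurity importance is classwide, reported with
#'   class `"(all)"`.
#' @export
fit_rf_importance <- function(data, y, n_trees = 500L, mtry = NULL,
                              min_node = 1L, seed = 1L) {
  stopifnot(n_trees >= 1L)
  y <- factor(y)
  enc <- encode_predictors(data)
  X <- enc$X     # trees are scale-invariant; no standardization needed
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(derive_seed(seed, "rf"))
  fit <- .rf_fit(X, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                 as.integer(mtry), as.integer(min_node), NULL)
  out <- importance_rows("rf", "(all)", fit$importance, enc$var_of)
  oob <- fit$oob_pred
  seen <- !is.na(oob)
  attr(out, "oob_accuracy") <- mean(oob[seen] == (as.integer(y)[seen] - 1L))
  out
}

pd_train_predict <- function(classifier, Xtr, ytr, Xte, params) {
  K <- nlevels(ytr)
  switch(classifier,
    glm = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, Xtr), as.integer(ytr) - 1L,
                       family = stats::binomial()))
      eta <- drop(cbind(1, Xte) %*% ifelse(is.na(fit$coefficients), 0,
                                           fit$coefficients))
      levels(ytr)[(eta > 0) + 1L]
    },
    multiglm = {
      fit <- multinom_fit(Xtr, ytr, decay = params$decay %||% 1e-4)
      predict_multinom(fit, Xte)
    },
    glmnet = {
      fam <- if (K == 2L) "binomial" else "multinomial"
      fit <- suppressWarnings(glmnet::glmnet(
        Xtr, ytr, family = fam, alpha = params$alpha %||% 0.5,
        lambda = params$lambda %||% 0.01, standardize = FALSE,
        type.multinomial = "grouped"))
      drop(stats::predict(fit, Xte, type = "class"))
    },
    rf = {
      fit <- .rf_fit(Xtr, as.integer(ytr) - 1L, K,
                     as.integer(params$n_trees %||% 500L),
                     as.integer(params$mtry %||% max(1L, floor(sqrt(ncol(Xtr))))),
                     1L, Xte)
      levels(ytr)[fit$test_pred + 1L]
    },
    stop("pd_bad_classifier: ", classifier))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resampled predictive accuracy of a classifier
#'
#' Estimates how well a classifier predicts each observation's class by
#' repeated resampling: bootstrap (train on a resample, test on the
#' out-of-bag rows; the default, 25 resamples) or stratified k-fold
#' cross-validation. A resample that misses a class in training is redrawn
#' (at most 10 retries, then an error). The same seed gives a bit-identical
#' estimate.
#'
#' @inheritParams fit_multiglm_importance
#' @param classifier One of `"glm"`, `"multiglm"`, `"glmnet"`, `"rf"`.
#' @param n_resamples Bootstrap resamples (or folds when `method = "cv"`).
#' @param method `"boot"` or `"cv"`.
#' @param seed Seed for the resampling stream.
#' @param params Named list of classifier settings (alpha, lambda, n_trees,
#'   mtry, decay) forwarded to the underlying fit.
#' @return List: `mean`, `sd`, `resamples` (per-resample accuracies).
#' @export
assess_accuracy <- function(data, y, classifier, n_resamples = 25L,
                            method = c("boot", "cv"), seed = 1L,
                            params = list()) {
  method <- match.arg(method)
  y <- factor(y)
  enc <- encode_predictors(data)
  X <- standardize_matrix(enc$X)
  set.seed(derive_seed(seed, "accuracy"))
  n <- nrow(X)
  acc <- numeric(0)
  if (method == "boot") {
    for (b in seq_len(n_resamples)) {
      for (try in seq_len(10L)) {
        tr <- sample.int(n, n, replace = TRUE)
        te <- setdiff(seq_len(n), tr)
        if (length(te) && nlevels(droplevels(y[tr])) == nlevels(y)) break
        if (try == 10L) stop("pd_resample_failed: a class is too rare to resample")
      }
      pred <- pd_train_predict(classifier, X[tr, , drop = FALSE], y[tr],
                               X[te, , drop = FALSE], params)
      acc[b] <- mean(pred == as.character(y[te]))
    }
  } else {
    fold <- unsplit(lapply(split(seq_len(n), y), function(i) {
      sample(rep_len(seq_len(n_resamples), length(i)))
    }), y)
    for (f in seq_len(n_resamples)) {
      te <- which(fold == f); tr <- which(fold != f)
      if (nlevels(droplevels(y[tr])) < nlevels(y)) {
        stop("pd_resample_failed: a class is too rare for ", n_resamples, "-fold CV")
      }
      pred <- pd_train_predict(classifier, X[tr, , drop = FALSE], y[tr],
                               X[te, , drop = FALSE], params)
      acc[f] <- mean(pred == as.character(y[te]))
    }
  }
  list(mean = mean(acc), sd = stats::sd(acc), resamples = acc)
}

#' Stratum summaries of the quantitative variables
#'
#' Mean, SD, standard error and t-based 95% confidence limits of every
#' quantitative variable per dependent-level x conditioning stratum
#' (genotype x sex by default), reported on the original measurement scale
#' (the standardization recorded by [scale_features()] is undone). Strata of
#' size 1 get `NA` spread estimates.
#'
#' @param x A [pheno_table].
#' @param conf_level Confidence level, default 0.95.
#' @return data.frame: variable, stratum, n, mean, sd, se, lower, upper.
#' @export
group_summaries <- function(x, conf_level = 0.95) {
  strat_vars <- c(dependent_var(x), conditioning_vars(x))
  strata <- stratum_key(x, strat_vars)
  rows <- list()
  for (v in predictor_vars(x, "quantitative")) {
    col <- x$data[[v]]
    if (!is.null(x$scaling) && v %in% names(x$scaling$center)) {
      col <- col * x$scaling$scale[[v]] + x$scaling$center[[v]]
    }
    for (s in unique(strata)) {
      vals <- col[strata == s & !is.na(col)]
      n <- length(vals)
      m <- if (n) mean(vals) else NA_real_
      sdv <- if (n > 1L) stats::sd(vals) else NA_real_
      se <- sdv / sqrt(n)
      tq <- if (n > 1L) stats::qt(1 - (1 - conf_level) / 2, n - 1) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = s, n = n, mean = m, sd = sdv, se = se,
        lower = m - tq * se, upper = m + tq * se)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
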
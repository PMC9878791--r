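#' Correlation matrix of the explanatory variables
#'
#' Computes, for every pair of non-dependent variables: Pearson r between two
#' quantitative variables; point-biserial r (Pearson on a 0/1 coding) between
#' a quantitative variable and a binary qualitative one; Cramer's V between
#' two qualitative variables. Cramer's V is reported for inspection only and
#' never drives removal — it is not signed and lives on a different scale.
#' Each r carries its two-sided p-value (t distribution on n - 2 df, raw,
#' descriptive); V carries the chi-squared p-value.
#'
#' @param x A [pheno_table] (quantitative variables imputed).
#' @return An object of class `pd_selection_report`: `r` (correlation
#'   matrix), `p` (p-values), `method` (per-cell: pearson / pointbiserial /
#'   cramers_v / `NA`), `flagged` (pairs with removable |r| above the
#'   threshold — filled by [remove_correlated()]).
#' @export
correlation_matrix <- function(x) {
  vars <- setdiff(names(x$data), dependent_var(x))
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  meth <- matrix(NA_character_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    vi <- vars[i]; vj <- vars[j]
    ti <- x$var_types[[vi]]; tj <- x$var_types[[vj]]
    ci <- x$data[[vi]]; cj <- x$data[[vj]]
    ok <- !(is.na(ci) | is.na(cj))
    if (sum(ok) < 3L) next
    if (ti == "quantitative" && tj == "quantitative") {
      rv <- stats::cor(ci[ok], cj[ok]); m <- "pearson"
    } else if (ti != tj) {
      qv <- if (ti == "quantitative") ci else cj
      fv <- as.character(if (ti == "quantitative") cj else ci)
      levs <- unique(fv[ok])
      if (length(levs) != 2L) next   # point-biserial needs a binary factor
      rv <- stats::cor(qv[ok], as.numeric(fv[ok] == levs[2]))
      m <- "pointbiserial"
    } else {
      tab <- table(ci[ok], cj[ok])
      if (any(dim(tab) < 2L)) next
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rv <- sqrt(chi$statistic / (sum(tab) * (min(dim(tab)) - 1)))
      r[i, j] <- r[j, i] <- unname(rv)
      p[i, j] <- p[j, i] <- chi$p.value
      meth[i, j] <- meth[j, i] <- "cramers_v"
      next
    }
    n <- sum(ok)
    tt <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
    r[i, j] <- r[j, i] <- rv
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), n - 2)
    meth[i, j] <- meth[j, i] <- m
  }
  structure(list(r = r, p = p, method = meth,
                 conditioning = conditioning_vars(x),
                 flagged = NULL, kept = NULL, removed = NULL),
            class = "pd_selection_report")
}

#' Greedy removal of highly correlated variables
#'
#' While any removable pair exceeds the threshold in absolute correlation,
#' the member of the worst pair with the larger mean absolute correlation to
#' all other variables is removed (ties broken by column order, later column
#' removed). Conditioning variables (sex, treatment) are design variables and
#' are never auto-removed; when one exceeds the threshold this is logged in
#' the flagged pairs and its partner is removed instead. Only Pearson and
#' point-biserial entries participate.
#'
#' @param report A [correlation_matrix()] result.
#' @param threshold Absolute correlation above which a pair is unacceptable
#'   (default 0.75).
#' @return The report with `kept`, `removed` and `flagged` filled in.
#' @export
remove_correlated <- function(report, threshold = 0.75) {
  stopifnot(inherits(report, "pd_selection_report"))
  r <- abs(report$r)
  r[report$method == "cramers_v"] <- NA     # informative only
  diag(r) <- NA
  kept <- rownames(r)
  removed <- character(0)
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0), p = numeric(0))
  a <- r
  repeat {
    sub <- a[kept, kept, drop = FALSE]
    if (all(is.na(sub)) || max(sub, na.rm = TRUE) <= threshold) break
    w <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    v1 <- kept[w[1]]; v2 <- kept[w[2]]
    flagged <- rbind(flagged, data.frame(
      var1 = v1, var2 = v2, r = report$r[v1, v2], p = report$p[v1, v2]))
    cand <- setdiff(c(v1, v2), report$conditioning)
    drop_var <- if (length(cand) == 0L) {
      NA_character_    # both conditioning: flag, never remove
    } else if (length(cand) == 1L) {
      cand
    } else {
      m1 <- mean(sub[v1, ], na.rm = TRUE)
      m2 <- mean(sub[v2, ], na.rm = TRUE)
      if (m1 > m2) v1 else if (m2 > m1) v2 else
        kept[max(w)]                       # tie: later column goes
    }
    if (is.na(drop_var)) { a[v1, v2] <- a[v2, v1] <- NA; next }
    removed <- c(removed, drop_var)
    kept <- setdiff(kept, drop_var)
  }
  report$flagged <- flagged
  report$kept <- kept
  report$removed <- removed
  report
}

#' Select the variables contributing to the leading dimensions
#'
#' A variable enters the reduced model when its contribution to at least one
#' of the first `n_dims` factor dimensions reaches `threshold`. On the
#' default `"squared"` scale the contribution is the squared loading —
#' squared Pearson correlation with the dimension scores for quantitative
#' variables, the correlation ratio eta^2 for qualitative ones — so a
#' qualitative design variable like sex competes on the same scale; this is
#' the conventional meaning of a variable "contributing 30%" to a component.
#' `scale = "correlation"` instead thresholds the unsquared association
#' (|r|, or sqrt(eta^2)), a far more permissive reading. Associations are
#' measured on the unweighted data; MFA group weights do not alter them.
#'
#' @param mfa A [mfamix()] (or [pcamix()]) result fitted on the decorrelated
#'   variable set, dependent variable included as a qualitative participant.
#' @param threshold Contribution threshold in (0, 1), default 0.30.
#' @param n_dims Leading dimensions examined, default 3 (capped at rank).
#' @param exclude Variables never returned as selected (the dependent
#'   variable; it is still evaluated and reported).
#' @param scale `"squared"` (default) or `"correlation"`; see above.
#' @return Character vector of selected variable names, in input order, with
#'   attribute `"assoc"` holding every variable's max association (unsquared
#'   scale).
#' @export
select_contributing <- function(mfa, threshold = 0.30, n_dims = 3L,
                                exclude = character(0),
                                scale = c("squared", "correlation")) {
  stopifnot(inherits(mfa, "pd_factor"))
  scale <- match.arg(scale)
  if (!(threshold > 0 && threshold < 1)) {
    stop("pd_bad_threshold: contribution threshold must lie in (0, 1)")
  }
  n_dims <- min(n_dims, nrow(mfa$eig))
  score <- apply(mfa$assoc[, seq_len(n_dims), drop = FALSE], 1L, max)
  cut <- if (scale == "squared") sqrt(threshold) else threshold
  sel <- names(score)[score >= cut]
  sel <- setdiff(sel, exclude)
  structure(sel, assoc = score)
}

#' @export
print.pd_selection_report <- function(x, ...) {
  k <- nrow(x$r)
  cat(sprintf("selection report: %d explanatory variables\n", k))
  off <- abs(x$r); diag(off) <- NA
  off[x$method == "cramers_v"] <- NA
  cat(sprintf("  max off-diagonal |r|: %.3f\n", max(off, na.rm = TRUE)))
  if (!is.null(x$removed)) {
    cat("  removed:", if (length(x$removed)) paste(x$removed, collapse = ", ")
        else "(none)", "\n")
  }
  invisible(x)
}

#' Write a selection report to TSV files
#'
#' @param report A [pd_selection_report][correlation_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_selection_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "correlation_matrix.tsv"),
             file.path(dir, "flagged_pairs.tsv"))
  utils::write.table(data.frame(variable = rownames(report$r), report$r,
                                check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  flagged <- report$flagged
  if (is.null(flagged)) flagged <- data.frame(var1 = character(0),
                                              var2 = character(0),
                                              r = numeric(0), p = numeric(0))
  utils::write.table(flagged, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
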
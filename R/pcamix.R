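#' @useDynLib phenodisc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

EIG_TOL <- 1e-10

# Build the weighted, metric-adjusted matrix W whose plain SVD realizes the
# generalized SVD of mixed-data PCA:
#   quantitative column j -> z_j / sqrt(n), z standardized with the
#     population (1/n) standard deviation;
#   level s of a qualitative variable -> (g_s - p_s) / sqrt(n_s), i.e. the
#     centered indicator carrying the correspondence-analysis metric n/n_s.
# Row metric 1/n and column metrics are thereby folded into W, so total
# inertia = ||W||_F^2 = p1 + (m - q). `col_weights` (per variable) multiply a
# variable's columns by sqrt(w) — the MFA group weighting hook.
build_mixed_matrix <- function(data, types, col_weights = NULL) {
  n <- nrow(data)
  if (n < 3L) stop("pd_too_few_rows: need at least 3 individuals")
  cols <- list()
  colvar <- character(0)
  level_of <- character(0)
  for (v in names(data)) {
    w <- if (is.null(col_weights)) 1 else col_weights[[v]]
    if (types[[v]] == "quantitative") {
      xcol <- data[[v]]
      if (anyNA(xcol)) stop("pd_missing_cells: missing values in '", v, "'")
      s <- stats::sd(xcol) * sqrt((n - 1) / n)
      if (s < EIG_TOL) stop("pd_zero_variance: '", v, "' is constant")
      cols[[v]] <- sqrt(w) * (xcol - mean(xcol)) / (s * sqrt(n))
      colvar <- c(colvar, v); level_of <- c(level_of, NA_character_)
    } else {
      f <- as.character(data[[v]])
      if (anyNA(f)) stop("pd_missing_cells: missing values in '", v, "'")
      levs <- sort(unique(f))
      if (length(levs) < 2L) stop("pd_zero_variance: '", v, "' has a single level")
      for (l in levs) {
        g <- as.numeric(f == l)
        ns <- sum(g)
        cols[[paste0(v, "=", l)]] <- sqrt(w) * (g - ns / n) / sqrt(ns)
        colvar <- c(colvar, v); level_of <- c(level_of, l)
      }
    }
  }
  W <- do.call(cbind, cols)
  list(W = W, colvar = colvar, level_of = level_of, n = n)
}

#' Principal component analysis of mixed quantitative/qualitative data
#'
#' Performs the generalized singular value decomposition of the concatenated
#' standardized quantitative block and centered, frequency-weighted indicator
#' block. With only quantitative variables this reduces to PCA of the
#' correlation matrix; with only qualitative variables, to multiple
#' correspondence analysis with total inertia m - q (m levels over q
#' variables). Total inertia of the mixed analysis is p1 + (m - q).
#'
#' Axis signs are made deterministic by forcing the largest-magnitude loading
#' of each dimension to be positive. Dimensions with eigenvalue below 1e-10
#' are treated as rank-deficient and dropped.
#'
#' @param data data.frame of variables (numeric or character/factor columns),
#'   no missing cells.
#' @param types Named character vector over `names(data)`,
#'   `"quantitative"`/`"qualitative"`. Defaults to numeric columns being
#'   quantitative.
#' @param ndim Maximum number of dimensions to retain (default: full rank).
#' @param col_weights Named per-variable metric weights (used by [mfamix()]);
#'   `NULL` for ordinary analysis.
#' @return An object of class `pd_factor` with elements:
#'   \describe{
#'     \item{eig}{data.frame: eigenvalue, percentage of variance, cumulative
#'       percentage, per retained dimension.}
#'     \item{scores}{n x r individual coordinates; population variance of
#'       dimension d equals its eigenvalue.}
#'     \item{quant_cor}{Pearson correlations of each quantitative variable
#'       with each dimension.}
#'     \item{level_coord}{barycentric coordinates of each qualitative level.}
#'     \item{sqload}{squared loadings per variable x dimension: squared
#'       correlation for quantitative variables, correlation ratio eta^2 for
#'       qualitative ones (times the variable's metric weight, if any); per
#'       dimension they sum to the eigenvalue.}
#'     \item{total_inertia}{p1 + (m - q).}
#'   }
#' @examples
#' d <- data.frame(x = rnorm(20), y = rnorm(20),
#'                 g = rep(c("a", "b"), 10))
#' res <- pcamix(d)
#' res$eig
#' @export
pcamix <- function(data, types = NULL, ndim = NULL, col_weights = NULL) {
  if (is.null(types)) {
    types <- vapply(data, function(c) if (is.numeric(c)) "quantitative" else "qualitative", "")
  }
  bm <- build_mixed_matrix(data, types, col_weights)
  W <- bm$W
  n <- bm$n
  sv <- svd(W)
  lambda <- sv$d^2
  keep <- which(lambda > EIG_TOL)
  if (!length(keep)) stop("pd_rank_zero: input has no variance")
  if (!is.null(ndim)) keep <- keep[seq_len(min(ndim, length(keep)))]
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|v| entry of each axis positive
  for (k in seq_along(keep)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  lambda <- lambda[keep]
  r <- length(lambda)
  dn <- paste0("dim", seq_len(r))

  scores <- sqrt(n) * U %*% diag(d, r)
  colnames(scores) <- dn

  total <- sum(sv$d^2)
  eig <- data.frame(dim = seq_len(r), eigenvalue = lambda,
                    percentage = 100 * lambda / total,
                    cumulative = cumsum(100 * lambda / total))

  # per-column contributions (d * v)^2; variable squared loading = sum over
  # its columns — r^2 (quantitative) or eta^2 (qualitative), times weight
  contrib <- (V %*% diag(d, r))^2
  vars <- unique(bm$colvar)
  sqload <- matrix(0, length(vars), r, dimnames = list(vars, dn))
  for (j in seq_along(bm$colvar)) {
    sqload[bm$colvar[j], ] <- sqload[bm$colvar[j], ] + contrib[j, ]
  }

  quant <- names(types)[types == "quantitative" & names(types) %in% names(data)]
  quant_cor <- NULL
  if (length(quant)) {
    quant_cor <- matrix(NA_real_, length(quant), r, dimnames = list(quant, dn))
    for (v in quant) quant_cor[v, ] <- drop(stats::cor(data[[v]], scores))
  }
  # weight-free association of every variable with every dimension:
  # |r| for quantitative, sqrt(eta^2) for qualitative — this is what the
  # contribution-based pre-selection thresholds, so MFA group weights must
  # not leak into it
  assoc <- matrix(NA_real_, length(vars), r, dimnames = list(vars, dn))
  if (length(quant)) assoc[quant, ] <- abs(quant_cor)
  qual <- names(types)[types == "qualitative" & names(types) %in% names(data)]
  if (length(qual)) {
    tot <- colSums(sweep(scores, 2, colMeans(scores))^2)
    for (v in qual) {
      f <- as.character(data[[v]])
      betw <- rowsum(scores, f)        # level sums
      ns <- as.vector(table(f)[rownames(betw)])
      bss <- colSums((sweep(betw, 1, ns, "/") -
                        rep(colMeans(scores), each = nrow(betw)))^2 * ns)
      assoc[v, ] <- sqrt(pmin(1, bss / tot))
    }
  }
  level_coord <- NULL
  if (length(qual)) {
    lev_rows <- which(!is.na(bm$level_of))
    level_coord <- matrix(NA_real_, length(lev_rows), r,
                          dimnames = list(colnames(W)[lev_rows], dn))
    for (j in lev_rows) {
      v <- bm$colvar[j]; l <- bm$level_of[j]
      idx <- as.character(data[[v]]) == l
      level_coord[paste0(v, "=", l), ] <- colMeans(scores[idx, , drop = FALSE])
    }
  }

  structure(list(eig = eig, scores = scores, quant_cor = quant_cor,
                 level_coord = level_coord, sqload = sqload, assoc = assoc,
                 V = V, d = d, colvar = bm$colvar, level_of = bm$level_of,
                 W = W, n = n, types = types[names(data)],
                 col_weights = col_weights,
                 total_inertia = total),
            class = "pd_factor")
}

#' @export
print.pd_factor <- function(x, ...) {
  cat(sprintf("%s: %d individuals, %d variables, %d dimensions retained\n",
              if (inherits(x, "pd_mfa")) "mfamix" else "pcamix",
              x$n, length(unique(x$colvar)), nrow(x$eig)))
  print(utils::head(x$eig, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-dimension and cumulative explained variance
#'
#' @param result A [pcamix()]/[mfamix()] result.
#' @param n_dims Number of leading dimensions to report (capped at the rank).
#' @return data.frame: dim, eigenvalue, percentage, cumulative percentage.
#' @examples
#' res <- pcamix(data.frame(a = rnorm(10), b = rnorm(10)))
#' cumulative_variance(res, 2)
#' @export
cumulative_variance <- function(result, n_dims) {
  stopifnot(inherits(result, "pd_factor"), n_dims >= 1L)
  utils::head(result$eig, n_dims)
}

#' Cosine similarity of variable trajectories in factor space
#'
#' For every pair of variable coordinate vectors restricted to the leading
#' `dims` dimensions, returns dot(u, v) / (|u| |v|): 1 for arrows following
#' the same trajectory, 0 for orthogonal ones, -1 for opposing ones. Rows are
#' the quantitative variables (correlation vectors) and qualitative levels
#' (barycentric coordinates), so the dependent variable's classes can be
#' compared against the explanatory variables directly.
#'
#' @param result A [pcamix()]/[mfamix()] result.
#' @param dims Number of leading dimensions (default 3, capped at rank).
#' @param variables Optional subset of row names to keep.
#' @return Symmetric matrix with unit diagonal; `NA` where a coordinate
#'   vector has zero norm.
#' @export
cosine_similarity <- function(result, dims = 3L, variables = NULL) {
  stopifnot(inherits(result, "pd_factor"))
  dims <- min(dims, nrow(result$eig))
  coords <- rbind(
    if (!is.null(result$quant_cor)) result$quant_cor[, seq_len(dims), drop = FALSE],
    if (!is.null(result$level_coord)) result$level_coord[, seq_len(dims), drop = FALSE])
  if (!is.null(variables)) coords <- coords[rownames(coords) %in% variables, , drop = FALSE]
  nrm <- sqrt(rowSums(coords^2))
  sim <- (coords %*% t(coords)) / outer(nrm, nrm)
  sim[nrm < EIG_TOL, ] <- NA_real_
  sim[, nrm < EIG_TOL] <- NA_real_
  diag(sim)[nrm >= EIG_TOL] <- 1
  sim
}
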
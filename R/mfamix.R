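#' Multiple factor analysis of mixed data with group weighting
#'
#' Variables recorded in the same test form a group; a behavioural test that
#' records many readouts would otherwise dominate the leading dimensions.
#' MFA prevents this by giving every variable of group g the metric weight
#' `1 / lambda1(g)`, where `lambda1(g)` is the first eigenvalue of a
#' mixed-data PCA of group g alone (equivalently: dividing the group's
#' columns by `sqrt(lambda1)`), and then running the global mixed-data PCA on
#' the weighted ensemble. After weighting no group can contribute more than 1
#' to any global eigenvalue, and re-analyzing any single group's weighted
#' variables yields a first eigenvalue of exactly 1.
#'
#' Ungrouped variables are treated as singleton groups (their own first
#' eigenvalue then standardizes them to weight `1/lambda1` as well).
#'
#' @param data data.frame of variables, no missing cells.
#' @param types Named type vector as in [pcamix()].
#' @param groups Named character vector over `names(data)` giving each
#'   variable's group label; `NA` entries become singleton groups.
#' @param ndim Maximum dimensions retained.
#' @return An object of classes `pd_mfa`, `pd_factor`: all [pcamix()] fields
#'   (squared loadings carry the group weights, so per-dimension sums still
#'   equal the eigenvalues) plus
#'   \describe{
#'     \item{group_weights}{named vector 1/lambda1(g).}
#'     \item{group_contrib}{groups x dims matrix; non-negative, per-dimension
#'       sums equal the eigenvalues.}
#'     \item{partial_axes}{per group, correlations of the group's own
#'       dimensions with the global dimensions.}
#'     \item{partial_coords}{per group, the individuals' partial coordinates
#'       (their group-mean equals the global coordinates).}
#'   }
#' @examples
#' d <- data.frame(a = rnorm(30), b = rnorm(30), g = rep(c("x","y","z"), 10))
#' res <- mfamix(d, groups = c(a = "t1", b = "t1", g = NA))
#' res$group_weights
#' @export
mfamix <- function(data, types = NULL, groups = NULL, ndim = NULL) {
  if (is.null(types)) {
    types <- vapply(data, function(c) if (is.numeric(c)) "quantitative" else "qualitative", "")
  }
  vars <- names(data)
  if (is.null(groups)) groups <- stats::setNames(rep(NA_character_, length(vars)), vars)
  groups <- groups[vars]
  groups[is.na(groups)] <- vars[is.na(groups)]   # singleton groups

  glevels <- unique(groups)
  sub_fits <- list()
  weights <- stats::setNames(numeric(length(vars)), vars)
  for (g in glevels) {
    gv <- vars[groups == g]
    fit <- tryCatch(
      pcamix(data[, gv, drop = FALSE], types[gv]),
      error = function(e) stop("pd_group_failed: mixed PCA of group '", g,
                               "' failed: ", conditionMessage(e)))
    sub_fits[[g]] <- fit
    weights[gv] <- 1 / fit$eig$eigenvalue[1]
  }

  res <- pcamix(data, types, ndim = ndim, col_weights = weights)
  r <- nrow(res$eig)
  dn <- paste0("dim", seq_len(r))

  contrib <- matrix(0, length(glevels), r, dimnames = list(glevels, dn))
  for (g in glevels) {
    gv <- vars[groups == g]
    contrib[g, ] <- colSums(res$sqload[gv, , drop = FALSE])
  }

  partial_axes <- lapply(sub_fits, function(fit) {
    pa <- stats::cor(fit$scores, res$scores)
    rownames(pa) <- paste0("group.", rownames(pa))
    pa
  })

  G <- length(glevels)
  partial_coords <- list()
  for (g in glevels) {
    cols <- which(res$colvar %in% vars[groups == g])
    Fg <- G * sqrt(res$n) *
      (res$W[, cols, drop = FALSE] %*% res$V[cols, , drop = FALSE])
    colnames(Fg) <- dn
    partial_coords[[g]] <- Fg
  }

  res$group_weights <- stats::setNames(weights[!duplicated(groups)], glevels)
  res$group_weights <- vapply(glevels, function(g) weights[[vars[groups == g][1]]], 0)
  res$group_contrib <- contrib
  res$partial_axes <- partial_axes
  res$partial_coords <- partial_coords
  res$groups <- groups
  class(res) <- c("pd_mfa", class(res))
  res
}
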
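# independent oracles ---------------------------------------------------------

# PCA oracle: eigendecomposition of the correlation matrix
pca_oracle_eig <- function(X) eigen(stats::cor(X), symmetric = TRUE)$values

# MCA oracle: correspondence analysis of the raw indicator matrix; the mixed
# analysis' eigenvalues equal q times the CA eigenvalues of G
mca_oracle_eig <- function(df) {
  q <- ncol(df)
  G <- do.call(cbind, lapply(df, function(f) {
    stats::model.matrix(~ factor(f) - 1)
  }))
  P <- G / sum(G)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- svd(S)$d^2
  q * ev[ev > 1e-10]
}

rand_quant <- function(n, p) {
  as.data.frame(matrix(stats::rnorm(n * p), n, p,
                       dimnames = list(NULL, paste0("v", seq_len(p)))))
}

rand_qual <- function(n, q) {
  as.data.frame(lapply(stats::setNames(seq_len(q), paste0("f", seq_len(q))),
                       function(i) sample(letters[seq_len(sample(2:4, 1))], n,
                                          replace = TRUE)),
                stringsAsFactors = FALSE)
}

test_that("pcamix matches the eigendecomposition and CA oracles on 50 random instances", {
  set.seed(101)
  for (i in 1:25) {
    X <- rand_quant(sample(10:40, 1), sample(2:6, 1))
    expect_equal(pcamix(X)$eig$eigenvalue, pca_oracle_eig(X), tolerance = 1e-8)
  }
  for (i in 1:25) {
    df <- rand_qual(sample(20:50, 1), sample(2:4, 1))
    df <- df[, vapply(df, function(c) length(unique(c)) > 1, TRUE), drop = FALSE]
    if (!ncol(df)) next
    expect_equal(pcamix(df)$eig$eigenvalue, mca_oracle_eig(df), tolerance = 1e-8)
  }
})

test_that("two correlated quantitative variables give eigenvalues 1 +/- r", {
  set.seed(7)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  r <- cor(x, y)
  expect_equal(sort(pcamix(data.frame(x, y))$eig$eigenvalue),
               sort(c(1 - abs(r), 1 + abs(r))), tolerance = 1e-10)
})

test_that("a 3-level qualitative variable alone has total inertia m - q = 2", {
  set.seed(8)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 10))
  res <- pcamix(d)
  expect_equal(res$total_inertia, 2)
  expect_equal(sum(res$eig$eigenvalue), 2, tolerance = 1e-10)
})

test_that("mixed-analysis invariants hold on random mixed instances", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(20:40, 1)
    d <- cbind(rand_quant(n, sample(2:4, 1)), rand_qual(n, sample(1:3, 1)))
    d <- d[, !duplicated(names(d)), drop = FALSE]
    res <- pcamix(d)
    p1 <- sum(vapply(d, is.numeric, TRUE))
    m <- sum(vapply(d[!vapply(d, is.numeric, TRUE)],
                    function(c) length(unique(c)), 0L))
    q <- ncol(d) - p1
    # inertia conservation
    expect_equal(res$total_inertia, p1 + (m - q), tolerance = 1e-8)
    expect_true(all(diff(res$eig$eigenvalue) <= 1e-12))     # descending
    expect_true(all(res$eig$eigenvalue >= -1e-8))
    # squared loadings in [0,1], per-dimension sums equal the eigenvalue
    expect_true(all(res$sqload >= -1e-8 & res$sqload <= 1 + 1e-8))
    expect_equal(unname(colSums(res$sqload)), res$eig$eigenvalue,
                 tolerance = 1e-8)
    # score orthogonality
    gram <- crossprod(res$scores) / n
    expected_gram <- diag(res$eig$eigenvalue, nrow(res$eig))
    dimnames(expected_gram) <- dimnames(gram)
    expect_equal(gram, expected_gram, tolerance = 1e-8)
    # cumulative variance non-decreasing, reaching 100 at full rank
    expect_true(all(diff(res$eig$cumulative) >= -1e-10))
    expect_equal(max(res$eig$cumulative), 100, tolerance = 1e-6)
    # qualitative squared loadings are the correlation ratio eta^2
    for (v in names(d)[!vapply(d, is.numeric, TRUE)]) {
      f <- d[[v]]
      eta2 <- vapply(seq_len(nrow(res$eig)), function(k) {
        sc <- res$scores[, k]
        sum(tapply(sc, f, function(s) length(s) * (mean(s) - mean(sc))^2)) /
          sum((sc - mean(sc))^2)
      }, 0)
      expect_equal(unname(res$sqload[v, ]), eta2, tolerance = 1e-8)
    }
  }
})

test_that("axis signs are deterministic given fixed input", {
  set.seed(9)
  X <- rand_quant(25, 4)
  r1 <- pcamix(X); r2 <- pcamix(X)
  expect_identical(r1$scores, r2$scores)
  for (k in seq_len(nrow(r1$eig))) {
    expect_gt(r1$V[which.max(abs(r1$V[, k])), k], 0)
  }
})

test_that("MFA weighting normalizes groups and balances identical ones", {
  set.seed(10)
  n <- 30
  d <- data.frame(x = rnorm(n), y = rnorm(n),
                  g = sample(c("a", "b", "c"), n, TRUE),
                  stringsAsFactors = FALSE)
  base <- pcamix(d)
  # lone group: eigenvalues rescaled by 1/lambda1, first becomes exactly 1
  mf <- mfamix(d, groups = stats::setNames(rep("all", 3), names(d)))
  expect_equal(mf$eig$eigenvalue[1], 1, tolerance = 1e-10)
  expect_equal(mf$eig$eigenvalue,
               base$eig$eigenvalue / base$eig$eigenvalue[1], tolerance = 1e-10)

  # within-group first-eigenvalue-1 invariant on a multi-group analysis
  d2 <- cbind(d, data.frame(u = rnorm(n), v2 = rnorm(n)))
  gr <- c(x = "t1", y = "t1", g = NA, u = "t2", v2 = "t2")
  mf2 <- mfamix(d2, groups = gr)
  for (g in unique(stats::na.omit(gr))) {
    gv <- names(gr)[!is.na(gr) & gr == g]
    w <- mf2$group_weights[[g]]
    sub <- pcamix(d2[, gv, drop = FALSE])
    expect_equal(w * sub$eig$eigenvalue[1], 1, tolerance = 1e-10)
  }
  # group contributions: non-negative, per-dimension sums equal eigenvalues
  expect_true(all(mf2$group_contrib >= -1e-10))
  expect_equal(unname(colSums(mf2$group_contrib)), mf2$eig$eigenvalue,
               tolerance = 1e-8)

  # identical duplicated groups contribute 50% each to dimension 1
  d3 <- data.frame(a = d$x, b = d$y, a2 = d$x, b2 = d$y)
  mf3 <- mfamix(d3, groups = c(a = "g1", b = "g1", a2 = "g2", b2 = "g2"))
  expect_equal(unname(mf3$group_contrib[, 1] / mf3$eig$eigenvalue[1]),
               c(0.5, 0.5), tolerance = 1e-8)

  # partial coordinates average to the global coordinates
  avg <- Reduce(`+`, mf3$partial_coords) / length(mf3$partial_coords)
  expect_equal(avg, mf3$scores, tolerance = 1e-8)
})

test_that("cumulative_variance reports simple arithmetic correctly", {
  # eigenvalues {2, 1, 1}: construct from data with that correlation structure
  res <- structure(list(eig = data.frame(dim = 1:3, eigenvalue = c(2, 1, 1),
                                         percentage = c(50, 25, 25),
                                         cumulative = c(50, 75, 100))),
                   class = "pd_factor")
  cv <- cumulative_variance(res, 3)
  expect_equal(cv$cumulative, c(50, 75, 100))
  expect_equal(cumulative_variance(res, 2)$cumulative, c(50, 75))
})

test_that("cosine similarity: identity, orthogonality, scale invariance, zero norm", {
  fake <- structure(list(
    eig = data.frame(dim = 1:2, eigenvalue = c(1, 1),
                     percentage = c(50, 50), cumulative = c(50, 100)),
    quant_cor = rbind(a = c(1, 0), b = c(0, 1), c = c(2, 2) / sqrt(8),
                      d = c(0.5, 0.5), z = c(0, 0)),
    level_coord = NULL), class = "pd_factor")
  sim <- cosine_similarity(fake, dims = 2)
  expect_equal(sim["a", "a"], 1)
  expect_equal(sim["a", "b"], 0)
  expect_equal(sim["c", "d"], 1)        # (1,1) direction vs (2,2) direction
  expect_true(is.na(sim["z", "a"]))
})
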
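planted_binary <- function(n = 200, p_noise = 9, seed = 1, nonlinear = FALSE) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * (p_noise + 1)), n,
                            dimnames = list(NULL, c("x1", paste0("n", seq_len(p_noise))))))
  y <- if (nonlinear) {
    factor(ifelse(X$x1^2 > stats::median(X$x1^2), "hi", "lo"))
  } else {
    factor(ifelse(X$x1 > 0, "hi", "lo"))
  }
  list(X = X, y = y)
}

test_that("glm importance: planted signal tops, single predictor scales to 100, >2 classes rejected", {
  d <- planted_binary(seed = 41)
  imp <- fit_glm_importance(d$X, d$y)
  expect_equal(imp$scaled[imp$variable == "x1"], 100)
  expect_true(all(imp$scaled >= 0 & imp$scaled <= 100))

  one <- fit_glm_importance(d$X[, "n1", drop = FALSE], d$y)
  expect_equal(one$scaled, 100)

  expect_error(fit_glm_importance(d$X, factor(rep(c("a", "b", "c"), length.out = 200))),
               "pd_not_binary")
})

test_that("glm under the null: no variable is systematically top and accuracy is at chance", {
  tops <- character(0)
  for (s in 1:5) {
    set.seed(500 + s)
    X <- as.data.frame(matrix(rnorm(500 * 5), 500,
                              dimnames = list(NULL, paste0("v", 1:5))))
    y <- factor(sample(c("a", "b"), 500, TRUE))
    imp <- fit_glm_importance(X, y)
    tops <- c(tops, imp$variable[which.max(imp$scaled)])
    if (s == 1) {
      acc <- assess_accuracy(X, y, "glm", n_resamples = 5, method = "cv",
                             seed = s)
      expect_lt(abs(acc$mean - max(table(y)) / 500), 0.05)
    }
  }
  expect_gt(length(unique(tops)), 1L)
})

test_that("multinomial importance agrees with binary glm rankings and sees ordinal signal", {
  # graded true effects so every variable has a meaningful rank (rank
  # agreement on pure-noise predictors would be vacuous)
  set.seed(42)
  n <- 400
  X <- as.data.frame(matrix(rnorm(n * 6), n,
                            dimnames = list(NULL, paste0("v", 1:6))))
  eta <- as.matrix(X) %*% seq(0.25, 1.5, length.out = 6)
  y <- factor(ifelse(stats::runif(n) < stats::plogis(eta), "hi", "lo"))
  g <- fit_glm_importance(X, y)
  m <- fit_multiglm_importance(X, y)
  m_hi <- m[m$class == levels(y)[2], ]
  rho <- cor(g$scaled[match(m_hi$variable, g$variable)], m_hi$scaled,
             method = "spearman")
  expect_gt(rho, 0.8)

  # 3 balanced classes with means (-1, 0, 1) on x: outer classes rank x first
  set.seed(43)
  n <- 240
  cls <- rep(c("lo", "mid", "hi"), each = n / 3)
  X <- data.frame(x = rnorm(n, rep(c(-1, 0, 1), each = n / 3)),
                  n1 = rnorm(n), n2 = rnorm(n))
  m3 <- fit_multiglm_importance(X, cls)
  for (cl in c("lo", "hi")) {
    sub <- m3[m3$class == cl, ]
    expect_equal(sub$variable[which.max(sub$scaled)], "x")
  }
  # constant predictor gets zero raw importance
  X$flat <- 1
  m4 <- fit_multiglm_importance(X, cls)
  expect_equal(max(m4$raw[m4$variable == "flat"]), 0, tolerance = 1e-6)
})

test_that("elastic net: full shrinkage nulls everything; near-zero ridge matches multinomial", {
  set.seed(44)
  n <- 300
  X <- as.data.frame(matrix(rnorm(n * 6), n,
                            dimnames = list(NULL, paste0("v", 1:6))))
  eta <- as.matrix(X) %*% seq(0.25, 1.5, length.out = 6)
  y <- factor(ifelse(stats::runif(n) < stats::plogis(eta), "hi", "lo"))
  enc <- phenodisc:::encode_predictors(X)
  fit <- glmnet::glmnet(enc$X, y, family = "binomial", alpha = 1, lambda = 1e3)
  expect_true(all(abs(as.vector(fit$beta)) == 0))

  # alpha=0, lambda -> 0 recovers the unpenalized ranking
  m <- fit_multiglm_importance(X, y)
  fit0 <- glmnet::glmnet(scale(enc$X), y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
  r_ridge <- abs(as.vector(fit0$beta))
  m_hi <- m[m$class == levels(y)[2], ]
  expect_gt(cor(r_ridge, m_hi$raw[match(colnames(enc$X), m_hi$variable)],
                method = "spearman"), 0.9)
})

test_that("elastic net recovers planted signals in the top ranks", {
  set.seed(45)
  n <- 210
  cls <- rep(c("WT", "Het", "Homo"), each = n / 3)
  dose <- rep(0:2, each = n / 3)
  X <- data.frame(s1 = rnorm(n, dose), s2 = rnorm(n, 0.8 * dose),
                  s3 = rnorm(n, -dose),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  imp <- fit_glmnet_importance(X, cls, seed = 45)
  best <- aggregate(scaled ~ variable, imp, max)
  top3 <- best$variable[order(-best$scaled)][1:3]
  expect_setequal(top3, c("s1", "s2", "s3"))
  expect_true(is.list(attr(imp, "tuning")))
  expect_error(fit_glmnet_importance(X, cls, alphas = numeric(0)),
               "pd_degenerate_grid")
})

test_that("random forest finds a pure non-linear signal that glm misses", {
  d <- planted_binary(n = 300, seed = 46, nonlinear = TRUE)
  rf <- fit_rf_importance(d$X, d$y, n_trees = 300, seed = 46)
  expect_equal(rf$variable[which.max(rf$scaled)], "x1")
  expect_gt(attr(rf, "oob_accuracy"), 0.7)

  g <- fit_glm_importance(d$X, d$y)
  expect_gt(rank(-g$scaled)[g$variable == "x1"], 3)   # glm ranks it low

  # duplicated top predictor: importance splits but both beat the noise
  X2 <- d$X
  X2$x1b <- d$X$x1 + rnorm(300, sd = 0.01)
  rf2 <- fit_rf_importance(X2, d$y, n_trees = 300, seed = 47)
  noise_max <- max(rf2$scaled[!rf2$variable %in% c("x1", "x1b")])
  expect_gt(min(rf2$scaled[rf2$variable %in% c("x1", "x1b")]), noise_max)
})

test_that("forest importance stabilizes with more trees and is seed-deterministic", {
  d <- planted_binary(n = 120, p_noise = 5, seed = 48)
  imp_of <- function(n_trees, seed) {
    fit_rf_importance(d$X, d$y, n_trees = n_trees, seed = seed)$scaled
  }
  spread <- function(n_trees) {
    reps <- vapply(1:6, function(s) imp_of(n_trees, s), numeric(6))
    mean(apply(reps, 1, sd))
  }
  expect_gt(spread(1), spread(250))
  expect_identical(imp_of(100, 3), imp_of(100, 3))
})

test_that("accuracy assessment: separable data, determinism, resample handling", {
  set.seed(49)
  X <- data.frame(x = c(rnorm(30, -5), rnorm(30, 5)))
  y <- rep(c("a", "b"), each = 30)
  acc <- assess_accuracy(X, y, "glm", n_resamples = 10, seed = 2)
  expect_equal(acc$mean, 1.0)

  a1 <- assess_accuracy(X, y, "rf", n_resamples = 5, seed = 3,
                        params = list(n_trees = 50))
  a2 <- assess_accuracy(X, y, "rf", n_resamples = 5, seed = 3,
                        params = list(n_trees = 50))
  expect_identical(a1, a2)

  # a class too rare for stratified CV errors out
  yr <- c(rep("a", 59), "b")
  expect_error(assess_accuracy(X, yr, "glm", n_resamples = 5, method = "cv"),
               "pd_resample_failed")
})

test_that("group summaries: arithmetic, degenerate strata, CI coverage", {
  d <- data.frame(genotype = c("WT", "WT", "WT", "Het"),
                  v = c(1, 2, 3, 5), stringsAsFactors = FALSE)
  tab <- pheno_table(d, paste0("i", 1:4),
                     c(genotype = "dependent", v = "predictor"),
                     c(genotype = "qualitative", v = "quantitative"))
  gs <- group_summaries(tab)
  wt <- gs[gs$stratum == "WT", ]
  expect_equal(wt$mean, 2)
  expect_equal(wt$sd, 1)
  expect_equal(wt$se, 1 / sqrt(3))
  het <- gs[gs$stratum == "Het", ]
  expect_equal(het$n, 1L)
  expect_true(is.na(het$sd))

  # coverage: the reported 95% CI covers the true mean ~95% of the time
  set.seed(50)
  hits <- 0L; total <- 0L
  for (i in 1:250) {
    dd <- data.frame(genotype = rep(c("WT", "Het"), each = 30),
                     v = rnorm(60, 5, 1), stringsAsFactors = FALSE)
    tt <- pheno_table(dd, paste0("i", 1:60),
                      c(genotype = "dependent", v = "predictor"),
                      c(genotype = "qualitative", v = "quantitative"))
    g <- group_summaries(tt)
    hits <- hits + sum(g$lower <= 5 & 5 <= g$upper)
    total <- total + nrow(g)
  }
  expect_gt(hits / total, 0.92)
  expect_lt(hits / total, 0.98)
})
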
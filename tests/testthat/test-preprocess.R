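make_missing_table <- function(y, x, dep = NULL, seed = 1) {
  n <- length(y)
  set.seed(seed)
  if (is.null(dep)) dep <- rep(c("WT", "Het"), length.out = n)
  d <- data.frame(genotype = dep, y = y, x = x, stringsAsFactors = FALSE)
  pheno_table(d, sprintf("i%03d", seq_len(n)),
              c(genotype = "dependent", y = "predictor", x = "predictor"),
              c(genotype = "qualitative", y = "quantitative", x = "quantitative"))
}

test_that("low-information filter drops the right variables and is idempotent", {
  n <- 12
  d <- data.frame(
    genotype = rep(c("WT", "Het"), 6),
    binaryish = rep(c(0, 1), 6),              # 2 unique values -> dropped
    constfac = rep("WT", n),                  # 1 level -> dropped
    boundary = rep(c(1.1, 2.2, 3.3, 3.3), 3), # 3 unique -> kept
    ok = rnorm(n), stringsAsFactors = FALSE)
  tab <- pheno_table(d, sprintf("i%02d", 1:n),
                     stats::setNames(c("dependent", rep("predictor", 4)), names(d)),
                     stats::setNames(c("qualitative", "quantitative", "qualitative",
                                       "quantitative", "quantitative"), names(d)))
  res <- drop_low_information(tab)
  expect_setequal(names(res$removed), c("binaryish", "constfac"))
  expect_setequal(names(res$table$data), c("genotype", "boundary", "ok"))
  res2 <- drop_low_information(res$table)
  expect_length(res2$removed, 0)
  expect_equal(res2$table$data, res$table$data)

  tab$data$genotype <- rep("WT", n)
  expect_error(drop_low_information(tab), "pd_degenerate_dependent")
})

test_that("scaling standardizes, is idempotent up to tolerance, errors on zero variance", {
  tab <- make_missing_table(y = c(1, 2, 3, 4), x = c(2, 4, 6, 8))
  sc <- scale_features(tab)
  expect_equal(mean(sc$data$y), 0)
  expect_equal(sd(sc$data$y), 1)
  expect_equal(sc$data$y[1:3][order(sc$data$y[1:3])], sc$data$y[1:3]) # order kept
  sc2 <- scale_features(sc)
  expect_equal(sc2$data$y, sc$data$y, tolerance = 1e-12)

  tab0 <- make_missing_table(y = rep(10, 4), x = 1:4)
  expect_error(scale_features(tab0), "pd_zero_variance")
  tabna <- make_missing_table(y = c(1, NA, 3, 4), x = 1:4)
  expect_error(scale_features(tabna), "pd_missing_at_scaling")
})

test_that("group-mean imputation fills only single-NA strata with the stratum mean", {
  d <- data.frame(genotype = rep(c("WT", "Het"), each = 3),
                  v = c(2, 4, NA, 2, NA, NA), stringsAsFactors = FALSE)
  tab <- pheno_table(d, sprintf("i%d", 1:6),
                     c(genotype = "dependent", v = "predictor"),
                     c(genotype = "qualitative", v = "quantitative"))
  out <- suppressWarnings(impute_group_mean(tab, conditioning = "genotype"))
  expect_equal(out$data$v[3], 3)             # mean of 2, 4
  expect_true(out$imputed[3, "v"])
  expect_true(all(is.na(out$data$v[5:6])))   # two NAs -> left for PMM
  expect_false(any(out$imputed[c(1, 2, 4), "v"]))
  expect_warning(impute_group_mean(tab, conditioning = "genotype"),
                 "fewer than 10")
})

test_that("PMM imputations are donors' observed values and never touch observed cells", {
  set.seed(11)
  n <- 60
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.5)
  y_full <- y
  miss <- sample(n, 8)
  y[miss] <- NA
  tab <- make_missing_table(y, x)
  out <- impute_pmm(tab, imputation_spec(k = 5, n_bootstrap = 1, seed = 3))
  # single-round draws must be members of the observed donor pool
  expect_true(all(out$data$y[miss] %in% y_full[-miss]))
  expect_true(all(out$imputed[miss, "y"]))
  # conservation: observed cells untouched
  expect_equal(out$data$y[-miss], y[-miss])
  expect_equal(out$data$x, x)
  # determinism
  out2 <- impute_pmm(tab, imputation_spec(k = 5, n_bootstrap = 1, seed = 3))
  expect_identical(out$data, out2$data)
  # k larger than the complete cases errors
  expect_error(impute_pmm(tab, imputation_spec(k = 55)), "pd_too_few_complete")
})

test_that("PMM beats column-mean imputation on a linear signal", {
  # y = 2x + e, n = 200, 10% missing: compare both against the withheld truth
  set.seed(42)
  n <- 200
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  miss <- sample(n, 20)
  y_obs <- y
  y_obs[miss] <- NA
  tab <- make_missing_table(y_obs, x)
  out <- impute_pmm(tab, imputation_spec(k = 5, n_bootstrap = 10, seed = 7))
  rmse_pmm <- sqrt(mean((out$data$y[miss] - y[miss])^2))
  rmse_mean <- sqrt(mean((mean(y_obs, na.rm = TRUE) - y[miss])^2))
  expect_lt(rmse_pmm, rmse_mean)
})

test_that("qualitative targets fall back to modal donor categories", {
  set.seed(5)
  n <- 40
  x <- c(rnorm(20, -2), rnorm(20, 2))
  g <- rep(c("low", "high"), each = 20)
  g[c(3, 25)] <- NA
  d <- data.frame(genotype = rep(c("WT", "Het"), 20), g = g, x = x,
                  stringsAsFactors = FALSE)
  tab <- pheno_table(d, sprintf("i%d", 1:n),
                     c(genotype = "dependent", g = "predictor", x = "predictor"),
                     c(genotype = "qualitative", g = "qualitative", x = "quantitative"))
  out <- impute_pmm(tab, imputation_spec(k = 5, n_bootstrap = 5, seed = 1))
  expect_equal(out$data$g[3], "low")
  expect_equal(out$data$g[25], "high")
})
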
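test_that("mean squares match the hand-computed decomposition", {
  X <- matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)
  ms <- mean_squares(X)
  expect_equal(ms$MSR, 8)
  expect_equal(ms$MSC, 1.5)
  expect_equal(ms$MSE, 0)
  # constant matrix: all zero
  ms0 <- mean_squares(matrix(7, 4, 3))
  expect_equal(c(ms0$MSR, ms0$MSC, ms0$MSE), c(0, 0, 0))
  # adding a constant leaves all three unchanged
  set.seed(10)
  Y <- matrix(rnorm(20), 5, 4)
  msa <- mean_squares(Y); msb <- mean_squares(Y + 13.7)
  expect_equal(msa[c("MSR", "MSC", "MSE")], msb[c("MSR", "MSC", "MSE")])
  expect_error(mean_squares(matrix(1:2, 1, 2)), "n >= 2")
})

test_that("the two-way sum-of-squares identity holds", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:8, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k, sd = runif(1, 0.5, 20)), n, k)
    ms <- mean_squares(X)
    ss_tot <- sum((X - mean(X))^2)
    ss_parts <- ms$MSR * (n - 1) + ms$MSC * (k - 1) + ms$MSE * (n - 1) * (k - 1)
    expect_equal(ss_parts, ss_tot, tolerance = 1e-9)
  }
})

test_that("icc_a1 matches its printed identities", {
  # identical columns, non-constant rows -> exactly 1
  v <- c(1, 5, 2, 8, 3)
  expect_equal(icc_a1(cbind(v, v)), 1.0)
  expect_equal(icc_a1(cbind(v, v, v)), 1.0)
  # worked 3x2 example: (8 - 0) / (8 + 0 + (2/3)(1.5 - 0)) = 8/9
  expect_equal(icc_a1(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)), 8 / 9)
  # fully constant matrix is undefined, not a number
  expect_warning(res <- icc_a1(matrix(4, 3, 2)), "undefined")
  expect_true(is.na(res))
})

test_that("icc_a1 equals the brute-force two-way ANOVA oracle", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(2:8, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k, mean = runif(1, -5, 5), sd = runif(1, 0.2, 10)),
                n, k)
    expect_equal(icc_a1(X), icc_a1_oracle(X), tolerance = 1e-9)
  }
})

test_that("icc_a1 is bounded by 1 and invariant to common affine transforms", {
  set.seed(30)
  for (i in 1:20) {
    X <- matrix(rnorm(24), 8, 3)
    v <- icc_a1(X)
    expect_lte(v, 1)
    a <- runif(1, 0.1, 5); b <- runif(1, -50, 50)
    expect_equal(icc_a1(a * X + b), v, tolerance = 1e-9)
  }
})

test_that("closed-form offset and scaling limits hold at n = 10,000", {
  set.seed(40)
  v <- rnorm(10000, 0, 1)
  expect_equal(icc_a1(cbind(v, v + 1)), 2 / 3, tolerance = 0.01)
  set.seed(41)
  w <- rnorm(10000, 5, 1)
  a <- 1.2; s2 <- 1; m <- 5
  closed <- 2 * a * s2 / ((1 + a^2) * s2 + (1 - a)^2 * m^2)
  expect_equal(icc_a1(cbind(w, a * w)), closed, tolerance = 0.01)
})

test_that("pearson_corr behaves as the product-moment coefficient", {
  x <- c(1, 2, 3)
  expect_equal(pearson_corr(x, 2 * x + 3), 1.0)
  expect_equal(pearson_corr(x, -x), -1.0)
  expect_equal(pearson_corr(x, c(1, 3, 2)), 0.5)
  expect_warning(res <- pearson_corr(x, c(2, 2, 2)), "constant")
  expect_true(is.na(res))
  expect_error(pearson_corr(1:3, 1:4), "equal length")
  # invariant under per-sequence positive affine transforms
  set.seed(50)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson_corr(2 * a + 1, 0.3 * b - 7), pearson_corr(a, b))
})

test_that("pairwise matrices are symmetric, unit-diagonal, pairwise complete", {
  df <- rbind(
    make_records(c("s1", "s2", "s3", "s4"), method = "m1",
                 volume = c(1, 2, 3, 4) * 1000),
    make_records(c("s1", "s2", "s3"), method = "m2",
                 volume = c(1, 2, 3) * 1000),
    make_records(c("s1", "s2", "s3", "s4"), method = "m3",
                 volume = c(4, 3, 2, 1) * 1000))
  am <- pairwise_agreement(df, metric = "ICC")
  expect_equal(am$values, t(am$values))
  expect_equal(unname(diag(am$values)), rep(1, 3))
  expect_equal(am$n["m1", "m2"], 3L)       # pairwise deletion
  expect_equal(am$n["m1", "m3"], 4L)
  expect_equal(am$values["m1", "m2"], 1.0) # identical values where shared
  pm <- pairwise_agreement(df, metric = "PCC")
  expect_equal(pm$values["m1", "m3"], -1.0)
  # insufficient overlap -> NA, not fabricated
  df2 <- rbind(make_records("s1", method = "m1", volume = 1),
               make_records("s2", method = "m2", volume = 2))
  am2 <- pairwise_agreement(df2, metric = "PCC")
  expect_true(is.na(am2$values["m1", "m2"]))
})

test_that("agreement ratings use left-closed conventional bands", {
  expect_equal(rate_agreement(c(0.3, 0.5, 0.69, 0.7, 0.89, 0.9, 0.95)),
               c("poor", "fair", "fair", "good", "good", "excellent",
                 "excellent"))
})

test_that("ANOVA and Tukey comparison of method means", {
  # groups that are permutations of the same values: F = 0, p = 1
  v <- c(1, 2, 3, 4, 5)
  df <- data.frame(method = rep(c("a", "b", "c"), each = 5),
                   volume_mm3 = c(v, rev(v), sample(v)))
  res <- compare_method_means(df)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # two groups 100 SDs apart
  set.seed(60)
  df2 <- data.frame(method = rep(c("a", "b"), each = 50),
                    volume_mm3 = c(rnorm(50, 0, 1), rnorm(50, 100, 1)))
  res2 <- compare_method_means(df2)
  expect_lt(res2$p, 1e-10)
  expect_lt(res2$tukey$p_adj[1], 1e-6)
  # F equals the two-step sums-of-squares oracle
  set.seed(61)
  df3 <- data.frame(method = rep(c("a", "b", "c"), times = c(4, 5, 6)),
                    volume_mm3 = rnorm(15, 10, 2))
  res3 <- compare_method_means(df3)
  g <- split(df3$volume_mm3, df3$method)
  gm <- mean(df3$volume_mm3)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, 1))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  f_oracle <- (ssb / (3 - 1)) / (ssw / (15 - 3))
  expect_equal(res3$F, f_oracle, tolerance = 1e-10)
  expect_error(compare_method_means(df3[1:4, ]), ">= 2 methods")
})

test_that("triangle writer places the metrics in the documented layout", {
  set.seed(70)
  df <- rbind(
    make_records(sprintf("s%d", 1:10), method = "m1", volume = rnorm(10, 5)),
    make_records(sprintf("s%d", 1:10), method = "m2", volume = rnorm(10, 5)))
  pcc <- pairwise_agreement(df, "PCC")
  icc <- pairwise_agreement(df, "ICC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_agreement_triangle(pcc, icc, path)
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  expect_equal(tab$method, c("m1", "m2"))
  expect_equal(as.numeric(tab[1, "m2"]), round(pcc$values[1, 2], 2))
  expect_equal(as.numeric(tab[2, "m1"]), round(icc$values[2, 1], 2))
  expect_equal(tab[1, "m1"], "")
  lg <- agreement_long(pcc)
  expect_equal(nrow(lg), 1)
  expect_true(lg$rating %in% c("poor", "fair", "good", "excellent"))
})
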
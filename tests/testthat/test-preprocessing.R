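test_that("hemisphere merging sums left and right", {
  df <- rbind(
    make_records("s1", hemisphere = "left", volume = 1000),
    make_records("s1", hemisphere = "right", volume = 1100),
    make_records("s2", volume = 2500))  # already merged, passes unchanged
  out <- merge_hemispheres(cohort_table(df))
  expect_equal(out$hemisphere, c("both", "both"))
  expect_equal(out$volume_mm3[out$subject_id == "s1"], 2100)
  expect_equal(out$volume_mm3[out$subject_id == "s2"], 2500)
})

test_that("a lone hemisphere becomes a failed record", {
  df <- rbind(
    make_records("s1", hemisphere = "left", volume = 1000),
    make_records("s2", hemisphere = "left", volume = 900),
    make_records("s2", hemisphere = "right", volume = 950))
  out <- merge_hemispheres(cohort_table(df))
  expect_true(is.na(out$volume_mm3[out$subject_id == "s1"]))
  expect_equal(out$volume_mm3[out$subject_id == "s2"], 1850)
})

test_that("duplicate hemisphere rows are an integrity error", {
  df <- rbind(
    make_records("s1", hemisphere = "left", volume = 1000),
    make_records("s1", hemisphere = "left", volume = 1001))
  expect_error(cohort_table(df), "duplicate")
  # same check inside merge for a pre-built frame
  tab <- cohort_table(make_records("s1", hemisphere = "left", volume = 1000))
  tab2 <- rbind(as.data.frame(tab), as.data.frame(tab))
  class(tab2) <- c("cohort_table", "data.frame")
  expect_error(merge_hemispheres(tab2), "duplicate")
})

test_that("caudate and accumbens merge into one region", {
  df <- rbind(
    make_records("s1", region = "caudate_nucleus", volume = 7000),
    make_records("s1", region = "accumbens", volume = 500),
    make_records("s1", method = "m5", region = "caudate_accumbens",
                 volume = 7280),
    make_records("s1", region = "thalamus", volume = 12000))
  out <- merge_caudate_accumbens(cohort_table(df), premerged_methods = "m5")
  ca <- out[out$region == "caudate_accumbens", ]
  expect_equal(ca$volume_mm3[ca$method == "m1"], 7500)
  expect_equal(ca$volume_mm3[ca$method == "m5"], 7280)  # unchanged
  expect_false(any(out$region %in% c("caudate_nucleus", "accumbens")))
  expect_equal(out$volume_mm3[out$region == "thalamus"], 12000)
})

test_that("a failed source region fails the combined region", {
  df <- rbind(
    make_records("s1", region = "caudate_nucleus", volume = 7000),
    make_records("s1", region = "accumbens", volume = NA),
    make_records("s2", region = "caudate_nucleus", volume = 6800))
  out <- merge_caudate_accumbens(cohort_table(df))
  expect_true(all(is.na(out$volume_mm3)))
})

test_that("failure exclusion removes exactly the failed records", {
  df <- rbind(
    make_records("s1", volume = 6000),
    make_records("s1", region = "thalamus", volume = NA),
    make_records("s1", method = "m2", volume = 0),   # zero volume = failed
    make_records("s2", volume = 5800))
  res <- exclude_failures(cohort_table(df))
  expect_equal(nrow(res$table), 2)
  rep <- res$report
  expect_equal(rep$n_failures[rep$method == "m1" & rep$region == "thalamus"], 1)
  expect_equal(rep$n_failures[rep$method == "m2" & rep$region == "hippocampus"], 1)
  expect_equal(rep$n_failures[rep$method == "m1" & rep$region == "hippocampus"], 0)
  # identity on a clean table
  clean <- cohort_table(make_records(c("s1", "s2"), volume = c(1, 2)))
  res2 <- exclude_failures(clean)
  expect_equal(as.data.frame(res2$table), as.data.frame(clean))
})

test_that("outlier detection follows the single-pass population-z rule", {
  expect_equal(detect_outliers(rep(7, 10)), rep(FALSE, 10))  # SD = 0 branch
  vals <- c(rep(0, 999), 100)
  mask <- detect_outliers(vals)  # default threshold 5
  expect_equal(which(mask), 1000L)
  # hand evaluation: mean 0.1, sd sqrt(9990/999), z = 99.9/sd ~ 31.6
  z <- (100 - mean(vals)) / sd(vals)
  expect_equal(z, 31.59, tolerance = 1e-3)
  expect_error(detect_outliers(5), "at least 2")
})

test_that("outlier z-scores are invariant under common affine transforms", {
  set.seed(8)
  v <- rnorm(200)
  v[7] <- 30
  m0 <- detect_outliers(v, 5)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- runif(1, -100, 100)
    expect_equal(detect_outliers(a * v + b, 5), m0)
  }
})

test_that("region exclusion uses the union rule across methods", {
  n <- 40
  base <- function(meth, region, v) {
    make_records(sprintf("s%02d", 1:n), method = meth, region = region,
                 volume = v)
  }
  set.seed(4)
  v1 <- rnorm(n, 6000, 100); v2 <- v1
  v1[1] <- 6000 + 100 * 50   # s01 outlying for m1 only
  v2[2] <- 6000 - 100 * 50   # s02 outlying for m2 only
  vth <- rnorm(n, 12000, 150)
  df <- rbind(base("m1", "hippocampus", v1), base("m2", "hippocampus", v2),
              base("m1", "thalamus", vth), base("m2", "thalamus", vth))
  res <- apply_region_exclusion(cohort_table(df), threshold = 5)
  # both flagged subjects leave the hippocampus for BOTH methods
  hip <- res$table[res$table$region == "hippocampus", ]
  expect_false(any(hip$subject_id %in% c("s01", "s02")))
  expect_equal(res$report$included_n[["hippocampus"]], n - 2)
  # but stay included for the thalamus (per-region scope)
  tha <- res$table[res$table$region == "thalamus", ]
  expect_true(all(c("s01", "s02") %in% tha$subject_id))
  expect_equal(res$report$included_n[["thalamus"]], n)
  # report reconciles: included = N - |union of flagged|
  expect_equal(res$report$included_n[["hippocampus"]],
               n - length(res$report$excluded_subjects$hippocampus))
})

test_that("a subject flagged by two methods is excluded once", {
  n <- 30
  set.seed(5)
  v <- rnorm(n, 6000, 100)
  v[3] <- 6000 + 100 * 60  # outlying for both methods (shared values)
  df <- rbind(
    make_records(sprintf("s%02d", 1:n), method = "m1", volume = v),
    make_records(sprintf("s%02d", 1:n), method = "m2", volume = v))
  res <- apply_region_exclusion(cohort_table(df), threshold = 5)
  expect_equal(res$report$excluded_subjects$hippocampus, "s03")
  expect_equal(res$report$included_n[["hippocampus"]], n - 1)
})

test_that("AD records are never auto-excluded by z", {
  n <- 30
  set.seed(6)
  df <- rbind(
    make_records(sprintf("n%02d", 1:n), volume = rnorm(n, 6000, 100)),
    make_records("a01", group = "AD", volume = 100))  # extreme patient
  res <- apply_region_exclusion(cohort_table(df), threshold = 5)
  expect_true("a01" %in% res$table$subject_id)
})

test_that("exclusion is idempotent when no new outliers emerge", {
  n <- 50
  set.seed(9)
  v <- rnorm(n, 6000, 100); v[1] <- 6000 + 100 * 40
  df <- make_records(sprintf("s%02d", 1:n), volume = v)
  r1 <- apply_region_exclusion(cohort_table(df), threshold = 5)
  r2 <- apply_region_exclusion(r1$table, threshold = 5)
  expect_equal(nrow(r2$table), nrow(r1$table))
})
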
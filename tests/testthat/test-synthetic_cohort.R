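test_that("the same config and seed reproduce the cohort byte for byte", {
  cfg <- tiny_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(a, p1); write_cohort_table(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zero distortion makes all methods identical and ICC-v exactly 1", {
  cfg <- tiny_config(seed = 3, n_nd = 60, n_ad = 0)
  coh <- as.data.frame(generate_cohort(cfg))
  wide <- split(coh$volume_mm3, coh$method)
  expect_equal(wide$m1, wide$m2, tolerance = 0)
  prep <- preprocess_cohort(generate_cohort(cfg))
  nd <- subset(as.data.frame(prep$table), region == "hippocampus")
  am <- pairwise_agreement(nd, metric = "ICC")
  expect_equal(am$values["m1", "m2"], 1.0)
  expect_equal(unname(diag(am$values)), c(1, 1))
})

test_that("an offset of one population SD pushes downstream ICC-v to ~ 2/3", {
  sd_pop <- 0.12 * 6000
  cfg <- generator_config(
    n_nd = 10000, n_ad = 0,
    regions = list(hippocampus = region_params(6000, 70, 0, 0.12, 1, 0, 0)),
    methods = list(m1 = method_distortion(),
                   m2 = method_distortion(offset = sd_pop)),
    seed = 9)
  prep <- preprocess_cohort(generate_cohort(cfg))
  nd <- as.data.frame(prep$table)
  am <- pairwise_agreement(nd, metric = "ICC")
  expect_equal(am$values["m1", "m2"], 2 / 3, tolerance = 0.02)
})

test_that("generated ND ages are uniform (chi-square on deciles)", {
  cfg <- tiny_config(seed = 21, n_nd = 2000, n_ad = 0)
  set.seed(cfg$seed)
  subj <- generate_subjects(cfg)
  bins <- cut(subj$age[subj$group == "ND"],
              breaks = seq(cfg$age_range_nd[1], cfg$age_range_nd[2],
                           length.out = 11), include.lowest = TRUE)
  p <- suppressWarnings(chisq.test(table(bins)))$p.value
  expect_gt(p, 0.01)
})

test_that("true_z is standard normal for ND latent volumes", {
  cfg <- recovery_config(seed = 13, n_nd = 10000)
  set.seed(cfg$seed)
  lat <- generate_latent(cfg, generate_subjects(cfg))
  z <- true_z(cfg, lat$age, lat$sex, lat$height, lat$hippocampus, "hippocampus")
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("true_z is 0 on the configured median and negative under atrophy", {
  cfg <- tiny_config(seed = 1)
  p <- cfg$regions$hippocampus
  m <- p$median_at_ref_age + p$age_slope * (80 - p$ref_age) +
    p$sex_effect * 1 + p$height_effect * (175 - 170)
  expect_equal(true_z(cfg, 80, 1, 175, m, "hippocampus"), 0)
  expect_error(true_z(cfg, 80, 1, 175, m, "cerebellum"), "unknown region")
  # atrophy factor 0.8 drags patient z below zero on average
  set.seed(cfg$seed)
  lat <- generate_latent(cfg, generate_subjects(cfg))
  ad <- lat[lat$group == "AD", ]
  zad <- true_z(cfg, ad$age, ad$sex, ad$height, ad$hippocampus, "hippocampus")
  expect_lt(mean(zad), 0)
})

test_that("failures and outliers are injected at the configured rates", {
  cfg <- tiny_config(
    seed = 17, n_nd = 1000, n_ad = 0,
    distortions = list(m1 = method_distortion(failure_rate = 0.02,
                                              outlier_rate = 0.01)))
  coh <- generate_cohort(cfg)
  inj <- attr(coh, "provenance")$injected$m1
  # provenance reconciles with the emitted table: each failed measurement
  # yields two missing hemisphere rows
  expect_equal(sum(is.na(coh$volume_mm3)), 2 * inj$n_failures)
  # counts are binomial draws over n_subjects x n_regions trials
  ntrials <- 1000 * 2
  expect_gt(inj$n_failures, qbinom(1e-5, ntrials, 0.02))
  expect_lt(inj$n_failures, qbinom(1 - 1e-5, ntrials, 0.02))
  expect_gt(inj$n_outliers, qbinom(1e-5, ntrials, 0.01))
  expect_lt(inj$n_outliers, qbinom(1 - 1e-5, ntrials, 0.01))
  # zero rates inject nothing
  cfg0 <- tiny_config(seed = 17, n_nd = 200, n_ad = 0)
  expect_equal(sum(is.na(generate_cohort(cfg0)$volume_mm3)), 0)
})

test_that("the default configuration matches the study conditions", {
  cfg <- default_config()
  expect_silent(validate_generator_config(cfg))
  expect_equal(cfg$n_nd, 988L)
  expect_equal(cfg$n_ad, 42L)
  expect_equal(cfg$age_range_nd, c(45, 95))
  expect_equal(cfg$age_range_ad, c(71, 91))
  expect_length(cfg$regions, 6)
  expect_length(cfg$methods, 5)
  # hippocampus median within the span of published per-method means
  expect_gt(cfg$regions$hippocampus$median_at_ref_age, 3652)
  expect_lt(cfg$regions$hippocampus$median_at_ref_age, 8766)
  expect_equal(cfg$regions$thalamus$median_at_ref_age, 12400, tolerance = 0.05)
  # atrophy concentrated in hippocampus/amygdala
  expect_lt(cfg$ad_atrophy[["hippocampus"]], cfg$ad_atrophy[["thalamus"]])
})

test_that("invalid configurations are refused before sampling", {
  expect_error(tiny_config(n_nd = 1), "n_nd")
  expect_error(
    generator_config(10, 2, age_range_nd = c(60, 60),
                     regions = list(a = region_params(100)),
                     methods = list(m = method_distortion())),
    "non-degenerate")
  expect_error(
    generator_config(10, 2, regions = list(a = region_params(100)),
                     methods = list(m = method_distortion()),
                     ad_atrophy = c(a = 1.5)),
    "atrophy")
  expect_error(region_params(-5), "median_at_ref_age")
  expect_error(method_distortion(scale = 0), "scale")
})

test_that("hemispheres are emitted as a fixed 48/52 split of the total", {
  cfg <- tiny_config(seed = 2, n_nd = 20, n_ad = 0)
  coh <- as.data.frame(generate_cohort(cfg))
  l <- coh[coh$hemisphere == "left", ]
  r <- coh[coh$hemisphere == "right", ]
  key <- function(d) paste(d$subject_id, d$method, d$region)
  m <- match(key(l), key(r))
  expect_equal(l$volume_mm3 / (l$volume_mm3 + r$volume_mm3[m]),
               rep(0.48, nrow(l)))
})
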
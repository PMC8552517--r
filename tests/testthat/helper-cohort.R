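# shared fixtures: all built in code at test time

# minimal long-format record builder
make_records <- function(subject_id, age = 70, sex = 1, height = 170,
                         group = "ND", method = "m1", region = "hippocampus",
                         hemisphere = "both", volume = 6000) {
  data.frame(subject_id = subject_id, age = age, sex = sex, height = height,
             group = group, method = method, region = region,
             hemisphere = hemisphere, volume_mm3 = volume,
             stringsAsFactors = FALSE)
}

# small two-region, two-method config for fast pipeline tests
tiny_config <- function(seed = 1, n_nd = 300, n_ad = 20,
                        distortions = NULL, atrophy = NULL) {
  regions <- list(
    hippocampus = region_params(6000, 70, -25, 0.12, 1, 350, 18),
    thalamus = region_params(12400, 70, -40, 0.13, 1, 700, 40)
  )
  if (is.null(distortions)) {
    distortions <- list(m1 = method_distortion(), m2 = method_distortion())
  }
  if (is.null(atrophy)) atrophy <- c(hippocampus = 0.8, thalamus = 0.95)
  generator_config(n_nd = n_nd, n_ad = n_ad, regions = regions,
                   methods = distortions, ad_atrophy = atrophy, seed = seed)
}

# single clean region/method, identity transform: well-specified for the
# LMS fitter, used by the parameter-recovery and calibration checks
recovery_config <- function(seed = 1, n_nd = 2000) {
  generator_config(
    n_nd = n_nd, n_ad = 0,
    regions = list(hippocampus = region_params(6000, 70, -25, 0.12, 1, 350, 18)),
    methods = list(m1 = method_distortion()),
    ad_atrophy = NULL, seed = seed)
}

# independent ICC(A,1) oracle: two-way ANOVA table built with stats::lm
icc_a1_oracle <- function(X) {
  n <- nrow(X); k <- ncol(X)
  d <- data.frame(y = as.vector(X),
                  row = factor(rep(seq_len(n), times = k)),
                  col = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::lm(y ~ row + col, data = d))
  MSR <- a["row", "Mean Sq"]; MSC <- a["col", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# brute-force AUC by pair enumeration with the 1/2 tie rule
auc_enum <- function(z_nd, z_ad) {
  s <- 0
  for (a in z_nd) for (b in z_ad) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(z_nd) * length(z_ad))
}
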
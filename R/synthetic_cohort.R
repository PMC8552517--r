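#' @title Synthetic cohort generator
#' @name synthetic_cohort
#' @description Generates volume cohorts with the statistical structure the
#'   downstream analysis assumes: a latent true volume per subject and
#'   region, drawn from an age-dependent skewed population distribution
#'   (inverse Yeo-Johnson of a Gaussian), observed by several measurement
#'   methods that each apply a systematic scaling and offset plus independent
#'   noise, with rare segmentation failures and gross outliers. Disease
#'   (AD) reduces latent volumes by region-specific atrophy factors.
NULL

#' Population parameters for one brain region
#'
#' The population median volume is linear in age,
#' `m(t) = median_at_ref_age + age_slope * (t - ref_age)`, shifted additively
#' by sex and height. On the transformed (Yeo-Johnson, `skew_lambda`) scale
#' the distribution is Gaussian with location `psi(m)` and standard
#' deviation `psi'(m) * coef_variation * m`, so the raw-scale coefficient of
#' variation is approximately `coef_variation` and the raw-scale median is
#' exactly `m`.
#'
#' @param median_at_ref_age Median volume at `ref_age`, mm^3.
#' @param ref_age Reference age, years.
#' @param age_slope Change of the median per year, mm^3/year (typically
#'   negative: atrophy).
#' @param coef_variation Dimensionless coefficient of variation.
#' @param skew_lambda Yeo-Johnson lambda of the true-volume distribution
#'   (1 = Gaussian, < 1 right-skewed).
#' @param sex_effect Additive male minus female difference, mm^3.
#' @param height_effect Additive effect per cm of height above 170, mm^3/cm.
#' @return A list of class `region_params`.
#' @export
region_params <- function(median_at_ref_age, ref_age = 70, age_slope = 0,
                          coef_variation = 0.13, skew_lambda = 1,
                          sex_effect = 0, height_effect = 0) {
  stopifnot(median_at_ref_age > 0, coef_variation > 0)
  structure(list(median_at_ref_age = median_at_ref_age, ref_age = ref_age,
                 age_slope = age_slope, coef_variation = coef_variation,
                 skew_lambda = skew_lambda, sex_effect = sex_effect,
                 height_effect = height_effect),
            class = "region_params")
}

#' Systematic distortion of one measurement method
#'
#' Observed volume = `scale * latent + offset + N(0, noise_sd)`, with a
#' probability `failure_rate` of a failed segmentation (missing volume) and
#' `outlier_rate` of a gross error of `outlier_magnitude` population SDs.
#'
#' @param scale Multiplicative factor (> 0).
#' @param offset Additive shift, mm^3.
#' @param noise_sd Independent measurement noise SD, mm^3.
#' @param failure_rate,outlier_rate Probabilities in \[0, 1\].
#' @param outlier_magnitude Gross-error size in population SDs.
#' @param premerged_caudate If `TRUE` the method reports caudate nucleus and
#'   accumbens as a single region (as model-based methods may), instead of
#'   the two separate source regions.
#' @return A list of class `method_distortion`.
#' @export
method_distortion <- function(scale = 1, offset = 0, noise_sd = 0,
                              failure_rate = 0, outlier_rate = 0,
                              outlier_magnitude = 8,
                              premerged_caudate = FALSE) {
  stopifnot(scale > 0, noise_sd >= 0,
            failure_rate >= 0, failure_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  structure(list(scale = scale, offset = offset, noise_sd = noise_sd,
                 failure_rate = failure_rate, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 premerged_caudate = premerged_caudate),
            class = "method_distortion")
}

#' Full parameterization of a synthetic cohort
#'
#' @param n_nd,n_ad Group sizes (reference non-demented; AD patients).
#' @param age_range_nd,age_range_ad Uniform age ranges, years.
#' @param regions Named list of [region_params()].
#' @param methods Named list of [method_distortion()].
#' @param ad_atrophy Named numeric vector of multiplicative factors in
#'   (0, 1\] applied to AD latent volumes, per region.
#' @param caudate_fraction Fraction of the caudate+accumbens volume assigned
#'   to the caudate nucleus when a method reports the two source regions
#'   separately.
#' @param male_fraction Probability a subject is male, per group
#'   (length-2: ND, AD).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_nd, n_ad, age_range_nd = c(45, 95),
                             age_range_ad = c(71, 91), regions, methods,
                             ad_atrophy = NULL, caudate_fraction = 0.93,
                             male_fraction = c(0.438, 0.595), seed = 1L) {
  cfg <- structure(list(n_nd = as.integer(n_nd), n_ad = as.integer(n_ad),
                        age_range_nd = as.numeric(age_range_nd),
                        age_range_ad = as.numeric(age_range_ad),
                        regions = regions, methods = methods,
                        ad_atrophy = ad_atrophy,
                        caudate_fraction = caudate_fraction,
                        male_fraction = male_fraction,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#' @param config A [generator_config()].
#' @return The config, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_generator_config <- function(config) {
  if (!inherits(config, "generator_config")) stop("not a generator_config")
  with(config, {
    if (n_nd < 2) stop("n_nd must be >= 2")
    if (n_ad < 0) stop("n_ad must be >= 0")
    if (diff(age_range_nd) <= 0 || diff(age_range_ad) <= 0) {
      stop("age ranges must be non-degenerate")
    }
    if (length(regions) < 1 || is.null(names(regions))) {
      stop("regions must be a named list")
    }
    if (length(methods) < 1 || is.null(names(methods))) {
      stop("methods must be a named list")
    }
    for (r in names(regions)) {
      p <- regions[[r]]
      if (p$median_at_ref_age <= 0 || p$coef_variation <= 0) {
        stop("invalid region params for ", r)
      }
    }
    if (!is.null(ad_atrophy)) {
      if (!all(names(ad_atrophy) %in% names(regions))) {
        stop("ad_atrophy names must be region names")
      }
      if (any(ad_atrophy <= 0 | ad_atrophy > 1)) {
        stop("ad_atrophy factors must be in (0, 1]")
      }
    }
    if (caudate_fraction <= 0 || caudate_fraction >= 1) {
      stop("caudate_fraction must be in (0, 1)")
    }
  })
  invisible(config)
}

#' Default synthetic cohort configuration
#'
#' Six regions whose medians and coefficients of variation approximate
#' published reference-population volumetry (thalamus ~ 12,400 mm^3,
#' hippocampus ~ 6,000 mm^3, CV ~ 0.13), 988 reference subjects uniform over
#' ages 45-95, 42 AD patients over ages 71-91, and five nominal measurement
#' methods with distinct systematic scalings/offsets, noise levels and
#' failure rates (one method reports caudate and accumbens pre-merged).
#' Disease-related volume reduction is concentrated in the hippocampus and
#' amygdala.
#'
#' @param seed Integer RNG seed stored in the config.
#' @return A [generator_config()].
#' @export
default_config <- function(seed = 1L) {
  regions <- list(
    hippocampus = region_params(6000, 70, -25, 0.135, 0.8, 350, 18),
    amygdala = region_params(2200, 70, -8, 0.13, 1.0, 140, 7),
    caudate_accumbens = region_params(7800, 70, -20, 0.14, 1.0, 420, 24),
    thalamus = region_params(12400, 70, -40, 0.13, 1.0, 700, 40),
    putamen = region_params(8250, 70, -35, 0.13, 0.9, 480, 26),
    globus_pallidus = region_params(2300, 70, -7, 0.13, 1.0, 150, 7)
  )
  methods <- list(
    m1 = method_distortion(1.00, 0, 120, failure_rate = 0.001, outlier_rate = 0.001),
    m2 = method_distortion(1.12, -300, 150, failure_rate = 0.009, outlier_rate = 0.002),
    m3 = method_distortion(0.92, 500, 130, failure_rate = 0, outlier_rate = 0.001),
    m4 = method_distortion(1.05, 200, 200, failure_rate = 0, outlier_rate = 0.002),
    m5 = method_distortion(0.95, -150, 100, failure_rate = 0, outlier_rate = 0.001,
                           premerged_caudate = TRUE)
  )
  ad_atrophy <- c(hippocampus = 0.80, amygdala = 0.83, caudate_accumbens = 0.96,
                  thalamus = 0.95, putamen = 0.95, globus_pallidus = 0.97)
  generator_config(n_nd = 988, n_ad = 42, age_range_nd = c(45, 95),
                   age_range_ad = c(71, 91), regions = regions,
                   methods = methods, ad_atrophy = ad_atrophy, seed = seed)
}

# population median curve m(t, sex, height) for one region
pop_median <- function(params, age, sex, height) {
  params$median_at_ref_age + params$age_slope * (age - params$ref_age) +
    params$sex_effect * sex + params$height_effect * (height - 170)
}

# transformed-scale SD yielding raw-scale CV ~ coef_variation (delta method)
pop_scale <- function(params, m) {
  yeo_johnson_deriv(m, params$skew_lambda) * params$coef_variation * m
}

#' Generative z-score of a latent volume
#'
#' Returns the z-score implied by the configured population curves: the
#' Yeo-Johnson-transformed distance of `latent_volume` from the population
#' median at the given age/sex/height, in transformed-scale SD units. Latent
#' ND volumes have `true_z ~ N(0, 1)` by construction; this is the oracle
#' for parameter-recovery tests of the normative fitter.
#'
#' @param config A [generator_config()].
#' @param age,sex,height Subject covariates (vectors recycled together).
#' @param latent_volume Latent true volume, mm^3.
#' @param region Region name present in `config$regions`.
#' @return Numeric z-scores.
#' @export
true_z <- function(config, age, sex, height, latent_volume, region) {
  if (!region %in% names(config$regions)) stop("unknown region: ", region)
  p <- config$regions[[region]]
  m <- pop_median(p, age, sex, height)
  (yeo_johnson(latent_volume, p$skew_lambda) - yeo_johnson(m, p$skew_lambda)) /
    pop_scale(p, m)
}

#' Draw the subject-level frame of a synthetic cohort
#'
#' Ages are uniform within the group's range; sex is Bernoulli with the
#' configured male fraction; height is Gaussian around a sex-specific mean
#' (163/171 cm, SD 7). Consumes RNG state: call under the cohort seed.
#'
#' @param config A [generator_config()].
#' @return Data frame with `subject_id`, `group`, `age`, `sex`, `height`.
#' @export
generate_subjects <- function(config) {
  n <- config$n_nd + config$n_ad
  grp <- rep(c("ND", "AD"), c(config$n_nd, config$n_ad))
  age <- c(stats::runif(config$n_nd, config$age_range_nd[1], config$age_range_nd[2]),
           stats::runif(config$n_ad, config$age_range_ad[1], config$age_range_ad[2]))
  pmale <- ifelse(grp == "ND", config$male_fraction[1], config$male_fraction[2])
  sex <- stats::rbinom(n, 1, pmale)
  height <- stats::rnorm(n, 163 + 8 * sex, 7)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)), group = grp,
             age = age, sex = sex, height = height,
             stringsAsFactors = FALSE)
}

#' Draw latent true volumes for a subject frame
#'
#' One latent volume per subject per configured region: the inverse
#' Yeo-Johnson of a Gaussian with location `psi(m)` and scale
#' `psi'(m) * CV * m` (see [region_params()]); AD subjects' volumes are then
#' multiplied by the region's atrophy factor. Consumes RNG state.
#'
#' @param config A [generator_config()].
#' @param subjects Frame from [generate_subjects()].
#' @return `subjects` with one extra numeric column per region.
#' @export
generate_latent <- function(config, subjects) {
  out <- subjects
  for (r in names(config$regions)) {
    p <- config$regions[[r]]
    m <- pop_median(p, subjects$age, subjects$sex, subjects$height)
    x <- stats::rnorm(nrow(subjects), yeo_johnson(m, p$skew_lambda), pop_scale(p, m))
    v <- yeo_johnson_inverse(x, p$skew_lambda)
    fac <- if (!is.null(config$ad_atrophy) && r %in% names(config$ad_atrophy)) {
      config$ad_atrophy[[r]]
    } else 1
    v <- ifelse(subjects$group == "AD", v * fac, v)
    out[[r]] <- v
  }
  out
}

#' Generate a full synthetic cohort table
#'
#' Applies each configured method's distortion to the latent volumes,
#' injects failures (missing volumes) and gross outliers at the configured
#' rates, splits totals into left/right hemispheres at a fixed 48/52 ratio
#' (so hemisphere merging is exercised deterministically) and, for methods
#' without a pre-merged caudate, splits the caudate+accumbens total into its
#' two source regions. Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A [cohort_table()] whose provenance records the seed and the
#'   injected failure/outlier counts per method.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  subjects <- generate_subjects(config)
  lat <- generate_latent(config, subjects)
  n <- nrow(subjects)
  pieces <- list()
  inj <- list()
  for (meth in names(config$methods)) {
    d <- config$methods[[meth]]
    n_fail <- 0L; n_out <- 0L
    for (r in names(config$regions)) {
      p <- config$regions[[r]]
      obs <- d$scale * lat[[r]] + d$offset + stats::rnorm(n, 0, d$noise_sd)
      is_out <- stats::runif(n) < d$outlier_rate
      if (any(is_out)) {
        sd_pop <- p$coef_variation * p$median_at_ref_age
        sign <- ifelse(stats::runif(sum(is_out)) < 0.5, -1, 1)
        obs[is_out] <- obs[is_out] + sign * d$outlier_magnitude * sd_pop
        n_out <- n_out + sum(is_out)
      }
      obs <- pmax(obs, 1)  # gross negative errors floor at 1 mm^3 (volumes are non-negative)
      is_fail <- stats::runif(n) < d$failure_rate
      obs[is_fail] <- NA_real_
      n_fail <- n_fail + sum(is_fail)
      # emit rows; caudate+accumbens may need splitting into source regions
      if (r == "caudate_accumbens" && !isTRUE(d$premerged_caudate)) {
        emit <- list(caudate_nucleus = obs * config$caudate_fraction,
                     accumbens = obs * (1 - config$caudate_fraction))
      } else {
        emit <- stats::setNames(list(obs), r)
      }
      for (rr in names(emit)) {
        for (h in c("left", "right")) {
          frac <- if (h == "left") 0.48 else 0.52
          pieces[[length(pieces) + 1L]] <- data.frame(
            subject_id = subjects$subject_id, age = subjects$age,
            sex = subjects$sex, height = subjects$height,
            group = subjects$group, method = meth, region = rr,
            hemisphere = h, volume_mm3 = emit[[rr]] * frac,
            stringsAsFactors = FALSE)
        }
      }
    }
    inj[[meth]] <- list(n_failures = n_fail, n_outliers = n_out)
  }
  df <- do.call(rbind, pieces)
  df <- df[order(df$subject_id, df$method, df$region, df$hemisphere), ]
  rownames(df) <- NULL
  cohort_table(df, provenance = list(generator_seed = config$seed,
                                     injected = inj))
}
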
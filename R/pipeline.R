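#' @title End-to-end analysis pipelines
#' @name pipeline
#' @description Scenario 1: the same method produces the normative
#'   distribution and the patient volumes; interchangeability then requires
#'   high correlation of volumes (PCC-v) and high absolute agreement of
#'   patient z-scores (ICC-z), and the z-score's diagnostic value is
#'   measured by the AUC. Scenario 2: different methods produce the two;
#'   this additionally requires absolute agreement on the raw volumes
#'   (ICC-v), since any between-method offset or scaling propagates into
#'   the z-score.
NULL

#' Methods of a generator config that report caudate+accumbens pre-merged
#' @param config A [generator_config()].
#' @return Character vector of method labels.
#' @export
premerged_of <- function(config) {
  names(Filter(function(m) isTRUE(m$premerged_caudate), config$methods))
}

#' Fit normative models for every (method, region)
#'
#' Fits [fit_lms()] on the preprocessed ND records, independently per
#' method and region.
#'
#' @param table Preprocessed [cohort_table()] (merged, failures and
#'   outliers excluded).
#' @param run_config Run configuration list (see [default_run_config()]).
#' @return Nested list `models[[method]][[region]]` of `normative_model`s.
#' @export
fit_all_models <- function(table, run_config = default_run_config()) {
  df <- as.data.frame(table)
  nd <- df[df$group == "ND", , drop = FALSE]
  models <- list()
  for (meth in sort(unique(nd$method))) {
    models[[meth]] <- list()
    for (r in sort(unique(nd$region[nd$method == meth]))) {
      sel <- nd$method == meth & nd$region == r
      d <- nd[sel, , drop = FALSE]
      models[[meth]][[r]] <- fit_lms(
        d$age, d$volume_mm3, d$sex, d$height,
        delta = run_config$delta, ref_height = run_config$ref_height,
        min_n = run_config$min_fit_n, method = meth, region = r)
    }
  }
  models
}

#' Score a cohort against fitted normative models
#'
#' Computes, per record, the z-score under the model fitted by the *same*
#' method for that region (scenario 1 matching).
#'
#' @param table A preprocessed [cohort_table()].
#' @param models Nested list from [fit_all_models()].
#' @param extrapolate Allow ages outside each model's fitted domain
#'   (patients may sit at the domain edge; the training ND cohort spans a
#'   wider age range, so the default `TRUE` here only affects boundary
#'   float error).
#' @return Data frame: `subject_id`, `group`, `age`, `sex`, `height`,
#'   `method`, `region`, `z`.
#' @export
score_cohort <- function(table, models, extrapolate = TRUE) {
  df <- as.data.frame(table)
  out <- df[c("subject_id", "group", "age", "sex", "height", "method", "region")]
  out$z <- NA_real_
  for (meth in names(models)) {
    for (r in names(models[[meth]])) {
      sel <- df$method == meth & df$region == r
      if (any(sel)) {
        out$z[sel] <- z_score(models[[meth]][[r]], df$age[sel], df$sex[sel],
                              df$height[sel], df$volume_mm3[sel],
                              extrapolate = extrapolate)
      }
    }
  }
  out[!is.na(out$z), , drop = FALSE]
}

#' Cross-method z-scores (scenario 2 demonstration)
#'
#' Scores one method's patient volumes against another method's normative
#' model. Diagnostic/demonstration output only: it makes visible how a
#' between-method offset or scaling shifts the patient's apparent position
#' relative to the normative distribution.
#'
#' @param table A preprocessed [cohort_table()].
#' @param models Nested list from [fit_all_models()].
#' @param volume_method Method whose volumes are scored.
#' @param model_method Method whose normative model is used.
#' @param extrapolate Passed to [z_score()].
#' @return Data frame as [score_cohort()] with columns `volume_method` and
#'   `model_method`.
#' @export
cross_method_z <- function(table, models, volume_method, model_method,
                           extrapolate = TRUE) {
  df <- as.data.frame(table)
  df <- df[df$method == volume_method, , drop = FALSE]
  mm <- models[[model_method]]
  if (is.null(mm)) stop("no models for method ", model_method)
  out <- df[c("subject_id", "group", "age", "sex", "height", "region")]
  out$volume_method <- volume_method
  out$model_method <- model_method
  out$z <- NA_real_
  for (r in names(mm)) {
    sel <- df$region == r
    if (any(sel)) {
      out$z[sel] <- z_score(mm[[r]], df$age[sel], df$sex[sel], df$height[sel],
                            df$volume_mm3[sel], extrapolate = extrapolate)
    }
  }
  out[!is.na(out$z), , drop = FALSE]
}

#' Mean (SD) volume summary per method and region
#'
#' Reference-group descriptive table on the post-exclusion ND set.
#'
#' @param table A preprocessed [cohort_table()].
#' @return Data frame with `method`, `region`, `n`, `mean_mm3`, `sd_mm3`.
#' @export
volume_summary <- function(table) {
  df <- as.data.frame(table)
  nd <- df[df$group == "ND", , drop = FALSE]
  agg <- stats::aggregate(nd["volume_mm3"],
                          by = nd[c("method", "region")],
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(method = agg$method, region = agg$region,
                    n = agg$volume_mm3[, "n"],
                    mean_mm3 = agg$volume_mm3[, "mean"],
                    sd_mm3 = agg$volume_mm3[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$region, out$method), ]
}

#' Scenario 1: same-method normative and patient volumes
#'
#' Full pipeline: preprocessing, per-(method, region) normative fits on
#' ND, z-scores of AD patients under the same method's model, pairwise
#' ICC-z per region over patients, and the age-window-restricted AUC with
#' stratified bootstrap CI per method and region. Also emits the ND mean
#' (SD) volume summary.
#'
#' @param cohort A raw [cohort_table()] with ND and AD groups.
#' @param run_config Run configuration (see [default_run_config()]).
#' @param premerged_methods Methods whose caudate+accumbens arrives
#'   pre-merged.
#' @return List: `models`, `zscores` (all groups), `icc_z` (per-region
#'   `agreement_matrix` over AD z-scores), `auc` (data frame per method x
#'   region), `summary` (volume summary), `report` (exclusions).
#' @export
run_scenario1 <- function(cohort, run_config = default_run_config(),
                          premerged_methods = character()) {
  stopifnot(all(c("ND", "AD") %in% unique(cohort$group)))
  prep <- preprocess_cohort(cohort, threshold = run_config$outlier_threshold,
                            premerged_methods = premerged_methods)
  models <- fit_all_models(prep$table, run_config)
  zs <- score_cohort(prep$table, models)

  regions <- sort(unique(zs$region))
  icc_z <- list()
  for (r in regions) {
    ad <- zs[zs$group == "AD" & zs$region == r, , drop = FALSE]
    icc_z[[r]] <- pairwise_agreement(ad, metric = "ICC", value_col = "z")
  }

  zw <- restrict_age_window(zs, run_config$ad_age_window)
  auc_rows <- list()
  i <- 0L
  for (meth in sort(unique(zw$method))) {
    for (r in regions) {
      i <- i + 1L
      znd <- zw$z[zw$group == "ND" & zw$method == meth & zw$region == r]
      zad <- zw$z[zw$group == "AD" & zw$method == meth & zw$region == r]
      if (length(znd) >= 2 && length(zad) >= 2) {
        res <- auc_with_ci(znd, zad, reps = run_config$bootstrap_reps,
                           seed = run_config$seed + i)
        auc_rows[[i]] <- data.frame(
          method = meth, region = r, auc = res$auc, ci_low = res$ci_low,
          ci_high = res$ci_high, n_nd = res$n_nd, n_ad = res$n_ad,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(models = models, zscores = zs, icc_z = icc_z,
       auc = do.call(rbind, auc_rows), summary = volume_summary(prep$table),
       report = prep$report, table = prep$table)
}

#' Scenario 2 assessment: between-method volume agreement
#'
#' Pairwise PCC-v and ICC-v per region on the post-exclusion ND volumes,
#' with conventional ratings. High ICC-v is the requirement for mixing
#' methods between the normative distribution and the patient volumes.
#'
#' @inheritParams run_scenario1
#' @return List: `pcc_v` and `icc_v` (per-region `agreement_matrix`),
#'   `long` (tidy rows with ratings), `anova` (per-region
#'   [compare_method_means()] results), `report`.
#' @export
run_scenario2_assessment <- function(cohort,
                                     run_config = default_run_config(),
                                     premerged_methods = character()) {
  prep <- preprocess_cohort(cohort, threshold = run_config$outlier_threshold,
                            premerged_methods = premerged_methods)
  df <- as.data.frame(prep$table)
  nd <- df[df$group == "ND", , drop = FALSE]
  if (length(unique(nd$method)) < 2) stop("need >= 2 methods")
  pcc_v <- list(); icc_v <- list(); anova <- list(); long <- list()
  for (r in sort(unique(nd$region))) {
    d <- nd[nd$region == r, , drop = FALSE]
    pcc_v[[r]] <- pairwise_agreement(d, metric = "PCC", value_col = "volume_mm3")
    icc_v[[r]] <- pairwise_agreement(d, metric = "ICC", value_col = "volume_mm3")
    anova[[r]] <- compare_method_means(d)
    lr <- rbind(agreement_long(pcc_v[[r]]), agreement_long(icc_v[[r]]))
    lr$region <- r
    long[[r]] <- lr
  }
  list(pcc_v = pcc_v, icc_v = icc_v, long = do.call(rbind, long),
       anova = anova, report = prep$report, table = prep$table)
}

#' Write the AUC results table
#'
#' One row per region, one column per method with `"auc (low, high)"`
#' cells, plus a tidy long CSV alongside if `tidy_path` is given.
#'
#' @param auc Data frame from [run_scenario1()]`$auc`.
#' @param path Output CSV path.
#' @param tidy_path Optional path for the tidy long variant.
#' @export
write_auc_table <- function(auc, path, tidy_path = NULL) {
  auc$cell <- sprintf("%.2f (%.2f, %.2f)", auc$auc, auc$ci_low, auc$ci_high)
  wide <- stats::reshape(auc[c("region", "method", "cell")],
                         idvar = "region", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  if (!is.null(tidy_path)) {
    utils::write.csv(auc[setdiff(names(auc), "cell")], tidy_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Run manifest with content hashes
#'
#' Records the seed, per-stage record counts and an MD5 content hash of
#' every emitted output file, so a re-run with the same configuration and
#' seed can be verified bit-for-bit.
#'
#' @param files Character vector of emitted file paths.
#' @param counts Named list/vector of per-stage record counts.
#' @param seed The master seed of the run.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(files, counts, seed, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    seed = seed,
    version = as.character(utils::packageVersion("normvol")),
    counts = as.list(counts),
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
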
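#' @title Preprocessing: region harmonization, failure and outlier exclusion
#' @name preprocessing
#' @description Harmonizes regions (hemisphere summation, merging of caudate
#'   nucleus and accumbens), removes failed segmentations, and excludes
#'   gross population-z outliers from the reference group before normative
#'   fitting.
NULL

key3 <- function(df) paste(df$subject_id, df$method, df$region, sep = "\r")

#' Sum left and right hemisphere volumes
#'
#' Every output record has `hemisphere = "both"` with
#' `volume = left + right`. Records already merged pass through unchanged. A
#' record with only one hemisphere present (row absent or volume missing)
#' is an incomplete segmentation and becomes a failed record (missing
#' volume).
#'
#' @param table A [cohort_table()].
#' @return A [cohort_table()] with `hemisphere == "both"` everywhere.
#' @export
merge_hemispheres <- function(table) {
  df <- as.data.frame(table)
  if (anyDuplicated(paste(key3(df), df$hemisphere))) {
    stop("duplicate hemisphere rows for the same (subject, method, region)")
  }
  both <- df[df$hemisphere == "both", , drop = FALSE]
  lr <- df[df$hemisphere != "both", , drop = FALSE]
  if (nrow(lr) > 0) {
    if (any(key3(lr) %in% key3(both))) {
      stop("records present both merged and per-hemisphere")
    }
    left <- lr[lr$hemisphere == "left", , drop = FALSE]
    right <- lr[lr$hemisphere == "right", , drop = FALSE]
    keys <- unique(key3(lr))
    vl <- left$volume_mm3[match(keys, key3(left))]    # NA when row absent
    vr <- right$volume_mm3[match(keys, key3(right))]
    src <- lr[match(keys, key3(lr)), , drop = FALSE]
    src$hemisphere <- "both"
    # treat a zero volume as failed too, so the sum does not mask it
    vl[!is.na(vl) & vl == 0] <- NA_real_
    vr[!is.na(vr) & vr == 0] <- NA_real_
    src$volume_mm3 <- vl + vr
    merged <- src
  } else {
    merged <- lr
  }
  out <- rbind(both, merged)
  out <- out[order(out$subject_id, out$method, out$region), ]
  rownames(out) <- NULL
  cohort_table(out, provenance = attr(table, "provenance"))
}

#' Merge caudate nucleus and accumbens into a single region
#'
#' For methods that report the two source regions separately their volumes
#' are summed into a combined region; methods that already report the
#' combined region (pre-merged) keep their value under the combined label.
#' Source regions are removed. If either source volume is missing the
#' combined record is failed.
#'
#' @param table A [cohort_table()] (hemispheres already merged).
#' @param premerged_methods Character vector of method labels that already
#'   report the combined region.
#' @param caudate,accumbens,combined Region labels.
#' @return A [cohort_table()] without the source regions.
#' @export
merge_caudate_accumbens <- function(table, premerged_methods = character(),
                                    caudate = "caudate_nucleus",
                                    accumbens = "accumbens",
                                    combined = "caudate_accumbens") {
  df <- as.data.frame(table)
  is_src <- df$region %in% c(caudate, accumbens)
  rest <- df[!is_src, , drop = FALSE]
  src <- df[is_src, , drop = FALSE]
  if (nrow(src) > 0) {
    if (any(src$method %in% premerged_methods)) {
      stop("pre-merged method supplies source regions: ",
           paste(unique(src$method[src$method %in% premerged_methods]), collapse = ", "))
    }
    cau <- src[src$region == caudate, , drop = FALSE]
    acc <- src[src$region == accumbens, , drop = FALSE]
    k <- function(d) paste(d$subject_id, d$method, sep = "\r")
    keys <- unique(k(src))
    vc <- cau$volume_mm3[match(keys, k(cau))]
    va <- acc$volume_mm3[match(keys, k(acc))]
    out <- src[match(keys, k(src)), , drop = FALSE]
    out$region <- combined
    out$volume_mm3 <- vc + va  # NA when either source missing or failed
    rest <- rbind(rest, out)
  }
  rest <- rest[order(rest$subject_id, rest$method, rest$region), ]
  rownames(rest) <- NULL
  cohort_table(rest, provenance = attr(table, "provenance"))
}

#' Remove failed segmentations
#'
#' A record is failed when its volume is missing or zero (pipelines that
#' abort produce no segmentation; some emit a zero volume).
#'
#' @param table A [cohort_table()].
#' @return List with `table` (failures removed) and `report`, a data frame
#'   of failure counts per (method, region).
#' @export
exclude_failures <- function(table) {
  df <- as.data.frame(table)
  failed <- is.na(df$volume_mm3) | df$volume_mm3 == 0
  rep_df <- if (any(failed)) {
    agg <- stats::aggregate(list(n_failures = failed),
                            by = list(method = df$method, region = df$region),
                            FUN = sum)
    agg[agg$n_failures > 0 | TRUE, , drop = FALSE]
  } else {
    agg <- unique(df[c("method", "region")])
    agg$n_failures <- 0L
    agg
  }
  rep_df <- rep_df[order(rep_df$region, rep_df$method), ]
  rownames(rep_df) <- NULL
  out <- df[!failed, , drop = FALSE]
  rownames(out) <- NULL
  list(table = cohort_table(out, provenance = attr(table, "provenance")),
       report = rep_df)
}

#' Flag gross outliers by population z-score
#'
#' A value is an outlier when its absolute z-score, derived with the mean
#' and (n-1) standard deviation of *all* supplied values (single pass, the
#' candidates included in the statistics), exceeds `threshold`. With zero
#' spread nothing is flagged.
#'
#' @param values Numeric vector, length >= 2.
#' @param threshold Dimensionless z threshold; defaults to 5.
#' @return Logical mask, `TRUE` where the value is an outlier.
#' @export
detect_outliers <- function(values, threshold = 5) {
  if (length(values) < 2) stop("detect_outliers needs at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  abs(values - m) / s > threshold
}

#' Per-region outlier exclusion of reference subjects
#'
#' For each region, outlier detection runs per method on the ND volumes; a
#' subject flagged by *any* method is excluded from that region for *all*
#' methods (union rule — the analyses share a single per-region subject
#' set). AD records are never auto-excluded (patient segmentations are
#' vetted by inspection upstream and enter as failures when rejected).
#' Expects a merged, failure-filtered table.
#'
#' @param table A [cohort_table()] with `hemisphere == "both"` and no failed
#'   records.
#' @param threshold z-score threshold passed to [detect_outliers()].
#' @return List with `table` (excluded ND records removed) and `report`, a
#'   list holding per-(method, region) outlier counts, per-region excluded
#'   subject ids and per-region included counts (subjects with complete
#'   data across all methods).
#' @export
apply_region_exclusion <- function(table, threshold = 5) {
  df <- as.data.frame(table)
  nd <- df[df$group == "ND", , drop = FALSE]
  methods <- sort(unique(df$method))
  regions <- sort(unique(df$region))
  counts <- list()
  excluded <- stats::setNames(vector("list", length(regions)), regions)
  included_n <- stats::setNames(integer(length(regions)), regions)
  drop_mask <- rep(FALSE, nrow(df))
  for (r in regions) {
    flagged <- character(0)
    for (meth in methods) {
      sel <- nd$region == r & nd$method == meth
      if (sum(sel) >= 2) {
        mask <- detect_outliers(nd$volume_mm3[sel], threshold)
        counts[[length(counts) + 1L]] <- data.frame(
          method = meth, region = r, n_outliers = sum(mask),
          stringsAsFactors = FALSE)
        flagged <- union(flagged, nd$subject_id[sel][mask])
      } else {
        counts[[length(counts) + 1L]] <- data.frame(
          method = meth, region = r, n_outliers = 0L,
          stringsAsFactors = FALSE)
      }
    }
    excluded[[r]] <- sort(flagged)
    drop_mask <- drop_mask |
      (df$group == "ND" & df$region == r & df$subject_id %in% flagged)
    # subjects with complete data across all methods for this region
    ndr <- nd[nd$region == r & !nd$subject_id %in% flagged, , drop = FALSE]
    tab <- table(ndr$subject_id)
    included_n[[r]] <- sum(tab == length(methods))
  }
  out <- df[!drop_mask, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(outliers = do.call(rbind, counts),
                 excluded_subjects = excluded,
                 included_n = included_n)
  list(table = cohort_table(out, provenance = attr(table, "provenance")),
       report = report)
}

#' One-call preprocessing pipeline
#'
#' Hemisphere summation, caudate+accumbens merging, failure exclusion and
#' per-region ND outlier exclusion, in that order.
#'
#' @param table A raw [cohort_table()].
#' @param threshold Outlier z threshold.
#' @param premerged_methods Methods whose caudate+accumbens arrives
#'   pre-merged.
#' @return List with `table` and `report` (failures + outliers + included
#'   counts).
#' @export
preprocess_cohort <- function(table, threshold = 5,
                              premerged_methods = character()) {
  merged <- merge_hemispheres(table)
  if (any(merged$region %in% c("caudate_nucleus", "accumbens")) ||
      length(premerged_methods) > 0) {
    merged <- merge_caudate_accumbens(merged, premerged_methods)
  }
  ef <- exclude_failures(merged)
  ex <- apply_region_exclusion(ef$table, threshold)
  list(table = ex$table,
       report = list(failures = ef$report,
                     outliers = ex$report$outliers,
                     excluded_subjects = ex$report$excluded_subjects,
                     included_n = ex$report$included_n))
}

#' Write an exclusion report as a region-by-method table
#'
#' Rows are regions, columns are methods (outlier counts) plus the final
#' included subject count per region.
#'
#' @param report Report list from [preprocess_cohort()] or
#'   [apply_region_exclusion()].
#' @param path Output CSV path.
#' @export
write_exclusion_report <- function(report, path) {
  out <- report$outliers
  wide <- stats::reshape(out, idvar = "region", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^n_outliers\\.", "", names(wide))
  wide$total_n <- report$included_n[wide$region]
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
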
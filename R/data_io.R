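#' @title Cohort volume tables: reading, writing, validation
#' @name data_io
#' @description Long-format volume tables: one row per subject x method x
#'   region x hemisphere, with the demographic covariates used by the
#'   normative fit. Missing or zero volumes mark failed segmentations.
NULL

COHORT_COLUMNS <- c("subject_id", "age", "sex", "height", "group",
                    "method", "region", "hemisphere", "volume_mm3")

#' Construct and validate a cohort table
#'
#' @param df A data frame with columns `subject_id`, `age` (years), `sex`
#'   (0 = female, 1 = male), `height` (cm), `group` (`"ND"` or `"AD"`),
#'   `method`, `region`, `hemisphere` (`"left"`, `"right"` or `"both"`),
#'   `volume_mm3` (mm^3; `NA` for a failed segmentation).
#' @param provenance Free-text metadata (source file, generator seed).
#' @return A `cohort_table`: the validated data frame with a `provenance`
#'   attribute.
#' @export
cohort_table <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[COHORT_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  df$method <- as.character(df$method)
  df$region <- as.character(df$region)
  df$hemisphere <- as.character(df$hemisphere)
  df$group <- as.character(df$group)
  for (col in c("age", "sex", "height", "volume_mm3")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!all(df$group %in% c("ND", "AD"))) {
    stop("group must be 'ND' or 'AD'")
  }
  if (!all(df$hemisphere %in% c("left", "right", "both"))) {
    stop("hemisphere must be 'left', 'right' or 'both'")
  }
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be positive")
  if (any(!is.finite(df$height)) || any(df$height <= 0)) stop("height must be positive")
  if (!all(df$sex %in% c(0, 1))) stop("sex must be coded 0 (female) / 1 (male)")
  v <- df$volume_mm3
  if (any(v[!is.na(v)] < 0)) stop("volume_mm3 must be non-negative when present")
  key <- paste(df$subject_id, df$method, df$region, df$hemisphere, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, method, region, hemisphere) records")
  }
  structure(df, provenance = provenance, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d records, %d subjects, %d methods, %d regions\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(x$method)), length(unique(x$region))))
  NextMethod()
}

delimiter_for_path <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a cohort table from CSV/TSV
#'
#' Rows with unparsable numeric fields are rejected with a per-row diagnostic
#' (a warning naming the row); missing volume cells become failed records.
#' `#loaded + #rejected` always equals the number of input data rows.
#'
#' @param path File path. Delimiter is auto-detected from the extension
#'   (`.tsv` is tab, anything else comma) unless `delimiter` is given.
#' @param delimiter Optional field delimiter overriding auto-detection.
#' @return A [cohort_table()]; the number of rejected rows is recorded in its
#'   provenance.
#' @export
read_cohort_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- delimiter_for_path(path, delimiter)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty file: ", path)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[COHORT_COLUMNS]
  num_cols <- c("age", "sex", "height", "volume_mm3")
  parsed <- lapply(num_cols, function(col) {
    x <- raw[[col]]
    blank <- is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"
    val <- suppressWarnings(as.numeric(x))
    list(value = val, bad = !blank & is.na(val), blank = blank)
  })
  names(parsed) <- num_cols
  # a blank volume is a failed segmentation, not a parse error
  bad_row <- parsed$age$bad | parsed$sex$bad | parsed$height$bad |
    parsed$volume_mm3$bad |
    parsed$age$blank | parsed$sex$blank | parsed$height$blank
  if (any(bad_row)) {
    for (r in which(bad_row)) {
      warning(sprintf("row %d rejected: unparsable or missing numeric field", r),
              call. = FALSE)
    }
  }
  keep <- !bad_row
  df <- raw[keep, , drop = FALSE]
  for (col in num_cols) df[[col]] <- parsed[[col]]$value[keep]
  rownames(df) <- NULL
  cohort_table(df, provenance = list(source = path,
                                     n_input_rows = nrow(raw),
                                     n_rejected = sum(bad_row)))
}

#' Write a cohort table to CSV/TSV
#'
#' Columns are written in the fixed documented order
#' (`subject_id, age, sex, height, group, method, region, hemisphere,
#' volume_mm3`); floats are serialized with full precision so that a
#' write/read round trip is the identity.
#'
#' @param table A [cohort_table()].
#' @param path Output path; delimiter auto-detected from the extension.
#' @param delimiter Optional delimiter override.
#' @export
write_cohort_table <- function(table, path, delimiter = NULL) {
  stopifnot(inherits(table, "cohort_table") || is.data.frame(table))
  sep <- delimiter_for_path(path, delimiter)
  df <- as.data.frame(table)[COHORT_COLUMNS]
  for (col in c("age", "sex", "height", "volume_mm3")) {
    df[[col]] <- formatC(df[[col]], format = "g", digits = 17)
    df[[col]][df[[col]] %in% c("NA", " NA")] <- ""
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

RUN_CONFIG_DEFAULTS <- list(
  outlier_threshold = 5.0,   # |z| above which an ND volume is a gross outlier
  delta = 2,                 # effective degrees of freedom per LMS curve
  bootstrap_reps = 1000L,    # AUC bootstrap resamples
  ad_age_window = c(71, 91), # ND age restriction for the AUC, years
  ref_height = 170,          # cm; reference stratum for displayed curves
  min_fit_n = 50L,           # refuse normative fits below this sample size
  seed = 1L
)

#' Read a run configuration
#'
#' A flat key-value YAML document. Unspecified keys take the defaults:
#' outlier threshold 5.0, curve degrees of freedom `delta` 2, 1,000 bootstrap
#' replicates, AD age window \[71, 91\] years, reference height 170 cm.
#' Unknown keys fail fast with an error listing the valid keys.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- RUN_CONFIG_DEFAULTS
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(names(cfg), collapse = ", "))
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (length(cfg$ad_age_window) != 2 || cfg$ad_age_window[1] >= cfg$ad_age_window[2]) {
    stop("ad_age_window must be an increasing pair of ages")
  }
  cfg
}

#' Default run configuration
#' @return Named list of the default configuration values (see
#'   [read_run_config()]).
#' @export
default_run_config <- function() RUN_CONFIG_DEFAULTS
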
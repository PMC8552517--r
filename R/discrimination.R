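#' @title Diagnostic value of the z-score (AUC with bootstrap CI)
#' @name discrimination
#' @description The AUC here is the probability that a randomly chosen
#'   reference (ND) subject has a higher z-score than a randomly chosen AD
#'   patient - the normalized Mann-Whitney U statistic, with ties counted
#'   as 1/2. Confidence intervals come from a stratified percentile
#'   bootstrap. Because patients are drawn from a narrower age band than
#'   the reference cohort, ND subjects are first restricted to the
#'   patients' age window.
NULL

#' AUC of ND-versus-AD z-scores
#'
#' `auc = (1 / (n_nd * n_ad)) * sum over pairs of [1 if z_nd > z_ad,
#' 1/2 if equal, 0 otherwise]`, computed via midranks (exactly the
#' Mann-Whitney U divided by `n_nd * n_ad`).
#'
#' @param z_nd,z_ad Numeric z-score vectors, both non-empty.
#' @return AUC in \[0, 1\].
#' @export
auc_z <- function(z_nd, z_ad) {
  n1 <- length(z_nd); n2 <- length(z_ad)
  if (n1 == 0 || n2 == 0) stop("auc_z: both groups must be non-empty")
  r <- rank(c(z_nd, z_ad))  # midranks implement the 1/2 tie rule
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Restrict reference subjects to the patients' age window
#'
#' Keeps ND records with `window[1] <= age <= window[2]` (closed
#' interval); AD records pass unfiltered.
#'
#' @param df Data frame with columns `group` and `age`.
#' @param window Length-2 increasing age window in years; default
#'   `c(71, 91)`.
#' @return The filtered data frame.
#' @export
restrict_age_window <- function(df, window = c(71, 91)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- df$group != "ND" | (df$age >= window[1] & df$age <= window[2])
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Draws `reps` resamples with replacement independently within each group
#' (group sizes preserved), recomputes the AUC each time and returns the
#' percentile interval.
#'
#' @param z_nd,z_ad Numeric z-score vectors, both of length >= 2.
#' @param reps Number of bootstrap replicates; default 1,000.
#' @param seed Integer seed for reproducibility (`NULL` = current RNG
#'   state).
#' @param conf Confidence level; default 0.95.
#' @return List with `ci_low`, `ci_high`, `reps`.
#' @export
bootstrap_auc_ci <- function(z_nd, z_ad, reps = 1000, seed = NULL,
                             conf = 0.95) {
  if (length(z_nd) < 2 || length(z_ad) < 2) {
    stop("bootstrap_auc_ci: both groups need >= 2 values")
  }
  if (!is.null(seed)) set.seed(seed)
  stat <- vapply(seq_len(reps), function(i) {
    auc_z(sample(z_nd, replace = TRUE), sample(z_ad, replace = TRUE))
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(stat, c(a, 1 - a), names = FALSE)
  list(ci_low = q[1], ci_high = q[2], reps = reps)
}

#' AUC with bootstrap confidence interval
#'
#' Convenience wrapper bundling [auc_z()] and [bootstrap_auc_ci()].
#'
#' @inheritParams bootstrap_auc_ci
#' @return List of class `auc_result`: `auc`, `ci_low`, `ci_high`, `n_nd`,
#'   `n_ad`, `reps`, `seed`.
#' @export
auc_with_ci <- function(z_nd, z_ad, reps = 1000, seed = NULL, conf = 0.95) {
  a <- auc_z(z_nd, z_ad)
  ci <- bootstrap_auc_ci(z_nd, z_ad, reps = reps, seed = seed, conf = conf)
  structure(list(auc = a, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n_nd = length(z_nd), n_ad = length(z_ad), reps = reps,
                 seed = seed),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f, %.3f); n_nd = %d, n_ad = %d, %d bootstrap reps\n",
              x$auc, x$ci_low, x$ci_high, x$n_nd, x$n_ad, x$reps))
  invisible(x)
}
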
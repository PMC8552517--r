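#' @title Method agreement: Pearson correlation and ICC(A,1)
#' @name agreement
#' @description Pairwise between-method statistics on a subjects-by-methods
#'   measurement matrix: the Pearson correlation (sensitive to ordering,
#'   blind to offsets and scalings) and the single-rater absolute-agreement
#'   intraclass correlation ICC(A,1) from the two-way mean-square
#'   decomposition (penalizes offsets and scalings). Used on raw volumes
#'   (PCC-v, ICC-v) and on patient z-scores (ICC-z).
NULL

#' Two-way mean squares of a measurement matrix
#'
#' For an `n x k` matrix `X` (rows = subjects, columns = methods) with row
#' means `Xi.`, column means `X.j` and grand mean `X..`:
#' `MSR = k * sum_i (Xi. - X..)^2 / (n - 1)`,
#' `MSC = n * sum_j (X.j - X..)^2 / (k - 1)`,
#' `MSE = sum_ij (Xij - Xi. - X.j + X..)^2 / ((n - 1)(k - 1))`.
#'
#' @param X Numeric matrix, `n >= 2` rows and `k >= 2` columns, no missing
#'   cells.
#' @return List with `MSR`, `MSC`, `MSE`, `n`, `k`.
#' @export
mean_squares <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("X must be a complete numeric matrix")
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2) stop("mean_squares needs n >= 2 and k >= 2")
  rm_ <- rowMeans(X)
  cm_ <- colMeans(X)
  gm <- mean(X)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm_ - gm)^2) / (k - 1)
  resid <- X - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  list(MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k)
}

#' Absolute-agreement intraclass correlation ICC(A,1)
#'
#' Single-rater absolute agreement from the two-way model:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k - 1) MSE + (k/n)(MSC - MSE))`.
#' It is 1 exactly when all columns are identical (with non-constant rows)
#' and is invariant under a common affine transform applied to all columns
#' simultaneously. A fully constant matrix has no defined ICC and returns
#' `NA` with a warning.
#'
#' @param X Numeric `n x k` matrix, rows = subjects, columns = methods.
#' @return ICC(A,1) in \[-1, 1\], or `NA` when undefined.
#' @export
icc_a1 <- function(X) {
  ms <- mean_squares(X)
  denom <- ms$MSR + (ms$k - 1) * ms$MSE + (ms$k / ms$n) * (ms$MSC - ms$MSE)
  if (denom == 0) {
    warning("icc_a1 undefined: constant measurement matrix")
    return(NA_real_)
  }
  (ms$MSR - ms$MSE) / denom
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]; constant input has no
#' defined correlation and returns `NA` with a warning rather than a value.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_corr undefined: constant input")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Pairwise agreement matrix over methods
#'
#' Builds, for one region, the k x k symmetric matrix of a pairwise
#' statistic (PCC or ICC(A,1)) over methods. Each cell uses the
#' complete-case subject set for that method *pair* (pairwise deletion);
#' the n used is recorded per cell. Pairs with insufficient overlap are
#' `NA`, never fabricated.
#'
#' @param df Long data frame with columns `subject_id`, `method` and the
#'   value column.
#' @param metric `"PCC"` or `"ICC"`.
#' @param value_col Name of the value column (e.g. `"volume_mm3"` or
#'   `"z"`).
#' @return An `agreement_matrix`: list with `metric`, `methods`, `values`
#'   (k x k, unit diagonal), `n` (k x k pairwise counts).
#' @export
pairwise_agreement <- function(df, metric = c("PCC", "ICC"),
                               value_col = "volume_mm3") {
  metric <- match.arg(metric)
  stopifnot(all(c("subject_id", "method", value_col) %in% names(df)))
  methods <- sort(unique(df$method))
  k <- length(methods)
  if (k < 2) stop("need >= 2 methods")
  wide <- stats::reshape(
    df[c("subject_id", "method", value_col)],
    idvar = "subject_id", timevar = "method", direction = "wide")
  vals <- as.matrix(wide[paste(value_col, methods, sep = ".")])
  colnames(vals) <- methods
  V <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  N <- matrix(0L, k, k, dimnames = list(methods, methods))
  diag(V) <- 1
  diag(N) <- colSums(!is.na(vals))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cc <- stats::complete.cases(vals[, c(i, j)])
      N[i, j] <- N[j, i] <- sum(cc)
      if (sum(cc) >= 2) {
        pair <- vals[cc, c(i, j)]
        v <- if (metric == "PCC") {
          suppressWarnings(pearson_corr(pair[, 1], pair[, 2]))
        } else {
          suppressWarnings(icc_a1(pair))
        }
        V[i, j] <- V[j, i] <- v
      }
    }
  }
  structure(list(metric = metric, methods = methods, values = V, n = N),
            class = "agreement_matrix")
}

#' Rate an agreement value on the conventional scale
#'
#' Poor < 0.5, fair \[0.5, 0.7), good \[0.7, 0.9), excellent >= 0.9
#' (left-closed bands: a boundary value takes the upper label).
#'
#' @param value Numeric vector of agreement values.
#' @return Character vector of labels.
#' @export
rate_agreement <- function(value) {
  as.character(cut(value, breaks = c(-Inf, 0.5, 0.7, 0.9, Inf),
                   labels = c("poor", "fair", "good", "excellent"),
                   right = FALSE))
}

#' One-way ANOVA and Tukey HSD comparison of method means
#'
#' Tests whether the volume distributions differ between methods
#' (fixed-effects one-way ANOVA) and locates the differing pairs with the
#' Tukey honest-significant-difference post hoc test.
#'
#' @param df Data frame with columns `method` and the value column.
#' @param value_col Name of the value column.
#' @return List with `F`, `p` (ANOVA) and `tukey`, a data frame of pairwise
#'   Tukey-adjusted p-values and mean differences.
#' @export
compare_method_means <- function(df, value_col = "volume_mm3") {
  stopifnot(all(c("method", value_col) %in% names(df)))
  g <- factor(df$method)
  if (nlevels(g) < 2) stop("need >= 2 methods")
  if (any(table(g) < 2)) stop("each method needs >= 2 values")
  v <- df[[value_col]]
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], tukey = tukey)
}

#' Write paired agreement matrices as a combined triangle table
#'
#' One CSV per region in the conventional layout: the first metric in the
#' upper-right triangle, the second in the lower-left, blank diagonal.
#'
#' @param upper,lower `agreement_matrix` objects over the same methods
#'   (e.g. PCC-v upper, ICC-v lower).
#' @param path Output CSV path.
#' @param digits Rounding for display; default 2.
#' @export
write_agreement_triangle <- function(upper, lower, path, digits = 2) {
  stopifnot(identical(upper$methods, lower$methods))
  k <- length(upper$methods)
  M <- matrix("", k, k, dimnames = list(upper$methods, upper$methods))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) M[i, j] <- formatC(upper$values[i, j], digits = digits, format = "f")
      if (j < i) M[i, j] <- formatC(lower$values[i, j], digits = digits, format = "f")
    }
  }
  out <- data.frame(method = rownames(M), M, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Tidy long form of an agreement matrix
#' @param x An `agreement_matrix`.
#' @return Data frame with `method1`, `method2`, `metric`, `value`, `n`,
#'   `rating` for each unordered pair.
#' @export
agreement_long <- function(x) {
  stopifnot(inherits(x, "agreement_matrix"))
  k <- length(x$methods)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rows[[length(rows) + 1L]] <- data.frame(
        method1 = x$methods[i], method2 = x$methods[j], metric = x$metric,
        value = x$values[i, j], n = x$n[i, j],
        rating = rate_agreement(x$values[i, j]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("agreement_matrix (%s), %d methods\n", x$metric, length(x$methods)))
  print(round(x$values, 3))
  invisible(x)
}
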
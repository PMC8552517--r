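#' @title Age-dependent normative distributions (LMS / Yeo-Johnson)
#' @name normative
#' @description Fits, per measurement method and region, a normative model
#'   in which the Yeo-Johnson-transformed volume is Gaussian with
#'   age-dependent location and scale and an age-dependent transformation
#'   parameter: `z = (psi_L(t)(y) - mu(t) - b_s*sex - b_h*(height - 170)) /
#'   sigma(t) ~ N(0, 1)`. Each of `L(t)`, `mu(t)` and `log sigma(t)` is a
#'   natural cubic regression spline in age with `delta` effective degrees
#'   of freedom; sex and height act additively on the transformed-scale
#'   location. The model is fitted by maximum likelihood including the
#'   Jacobian of the transformation. The fitted median and iso-z-score
#'   curves follow by inverting the transform.
NULL

# natural cubic spline basis spec with exactly `delta` df, plus intercept
ns_spec <- function(age, delta) {
  if (delta < 1) stop("delta must be >= 1")
  b <- splines::ns(age, df = delta)
  list(df = delta, knots = as.numeric(attr(b, "knots")),
       boundary = as.numeric(attr(b, "Boundary.knots")))
}

eval_basis <- function(spec, age) {
  b <- splines::ns(age, knots = spec$knots, Boundary.knots = spec$boundary)
  cbind(1, unclass(b))
}

# smooth bound keeping the transformation parameter in (-3, 3)
bound_lambda <- function(u) 3 * tanh(u / 3)
unbound_lambda <- function(l) 3 * atanh(l / 3)

#' Fit an LMS normative model
#'
#' Maximizes the log-likelihood of the transformed-Gaussian model described
#' in [normative] over the spline coefficients of `L`, `mu` and
#' `log sigma` and the covariate coefficients for sex and centered height,
#' by quasi-Newton (BFGS) iteration. Volumes are internally rescaled by
#' their sample median before transformation for numerical conditioning;
#' the scale is stored in the model and applied transparently by
#' [z_score()] and [iso_curve()]. Ages outside the training range are
#' refused at evaluation time unless extrapolation is explicitly allowed.
#'
#' @param age Ages in years.
#' @param volume Volumes in mm^3 (positive; failures must be excluded
#'   upstream).
#' @param sex 0 = female, 1 = male.
#' @param height Heights in cm.
#' @param delta Effective degrees of freedom per curve (smoothness);
#'   default 2.
#' @param ref_height Reference height (cm) at which curves are displayed
#'   and around which height is centered; default 170.
#' @param min_n Minimum number of observations; default 50.
#' @param method,region Labels stored in the model.
#' @param max_iter,reltol Optimizer budget and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `normative_model`: basis definition,
#'   coefficient vectors for the three curves, covariate coefficients,
#'   internal volume scale, age domain, and fit diagnostics (convergence
#'   flag, log-likelihood, n, training z mean/SD).
#' @export
fit_lms <- function(age, volume, sex, height, delta = 2, ref_height = 170,
                    min_n = 50, method = "unknown", region = "unknown",
                    max_iter = 500, reltol = 1e-8) {
  n <- length(age)
  stopifnot(length(volume) == n, length(sex) == n, length(height) == n)
  ok <- is.finite(age) & is.finite(volume) & is.finite(sex) & is.finite(height)
  if (!all(ok)) stop("fit_lms: non-finite inputs")
  if (n < min_n) stop(sprintf("fit_lms: %d observations, need >= %d", n, min_n))
  if (any(volume <= 0)) stop("fit_lms: volumes must be positive (exclude failures first)")
  if (stats::sd(volume) == 0) stop("fit_lms: degenerate volume variance")

  vscale <- stats::median(volume)
  ys <- volume / vscale
  spec <- ns_spec(age, delta)
  B <- eval_basis(spec, age)
  p <- ncol(B)
  hc <- height - ref_height
  ly <- log1p(ys)

  idx <- list(aL = 1:p, aM = p + 1:p, aS = 2 * p + 1:p,
              bs = 3 * p + 1L, bh = 3 * p + 2L)
  nll <- function(par) {
    L <- bound_lambda(B %*% par[idx$aL])
    mu <- B %*% par[idx$aM] + par[idx$bs] * sex + par[idx$bh] * hc
    lsig <- pmin(pmax(B %*% par[idx$aS], -20), 20)
    x <- yeo_johnson(ys, L)
    z <- (x - mu) / exp(lsig)
    val <- sum(lsig + 0.5 * z^2) - sum((L - 1) * ly)
    if (!is.finite(val)) 1e10 else val
  }

  # init: identity transform (L = 1), least-squares location, log residual SD
  par0 <- numeric(3 * p + 2)
  par0[idx$aL] <- c(unbound_lambda(1), rep(0, p - 1))
  ls <- stats::lm.fit(cbind(B, sex, hc), ys)
  par0[idx$aM] <- ls$coefficients[1:p]
  par0[idx$bs] <- ls$coefficients[p + 1]
  par0[idx$bh] <- ls$coefficients[p + 2]
  par0[idx$aS] <- c(log(stats::sd(ls$residuals)), rep(0, p - 1))
  par0[!is.finite(par0)] <- 0

  fit <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = max_iter, reltol = reltol))
  if (fit$convergence != 0) {
    stop(sprintf(paste0("fit_lms did not converge for (%s, %s): optim code %d, ",
                        "nll %.6g after budget of %d iterations"),
                 method, region, fit$convergence, fit$value, max_iter))
  }
  par <- fit$par
  model <- structure(list(
    method = method, region = region, delta = delta,
    basis = spec, vscale = vscale, ref_height = ref_height,
    coef = list(aL = par[idx$aL], aM = par[idx$aM], aS = par[idx$aS],
                beta_sex = par[idx$bs], beta_height = par[idx$bh]),
    age_domain = range(age),
    diagnostics = list(converged = TRUE, loglik = -fit$value, n = n)
  ), class = "normative_model")
  ztr <- z_score(model, age, sex, height, volume)
  model$diagnostics$z_mean <- mean(ztr)
  model$diagnostics$z_sd <- stats::sd(ztr)
  model
}

# evaluate L(t), mu_ref(t) (reference covariates excluded), log sigma(t)
model_curves <- function(model, age) {
  B <- eval_basis(model$basis, age)
  list(L = as.numeric(bound_lambda(B %*% model$coef$aL)),
       mu = as.numeric(B %*% model$coef$aM),
       sigma = as.numeric(exp(pmin(pmax(B %*% model$coef$aS, -20), 20))))
}

check_domain <- function(model, age, extrapolate) {
  lo <- model$age_domain[1]; hi <- model$age_domain[2]
  if (!extrapolate && any(age < lo | age > hi)) {
    bad <- age[age < lo | age > hi][1]
    stop(sprintf("age %.2f outside the fitted domain [%.2f, %.2f]; set extrapolate = TRUE to override",
                 bad, lo, hi))
  }
}

#' z-score of a volume under a normative model
#'
#' `z = (psi_L(age)(v) - mu(age) - b_s*sex - b_h*(height - ref)) /
#' sigma(age)`, strictly increasing in the volume at fixed covariates.
#'
#' @param model A `normative_model` from [fit_lms()].
#' @param age,sex,height Covariates (vectors recycled to a common length).
#' @param volume Volume in mm^3.
#' @param extrapolate Allow ages outside the fitted domain (default
#'   `FALSE`: extrapolation error).
#' @return Numeric z-scores.
#' @export
z_score <- function(model, age, sex, height, volume, extrapolate = FALSE) {
  stopifnot(inherits(model, "normative_model"))
  n <- max(length(age), length(sex), length(height), length(volume))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  height <- rep_len(height, n); volume <- rep_len(volume, n)
  check_domain(model, age, extrapolate)
  cv <- model_curves(model, age)
  ys <- volume / model$vscale
  x <- yeo_johnson(ys, cv$L)
  mu <- cv$mu + model$coef$beta_sex * sex +
    model$coef$beta_height * (height - model$ref_height)
  as.numeric((x - mu) / cv$sigma)
}

#' Iso-z-score curve
#'
#' The volume-versus-age curve along which the z-score is constant:
#' `y(t) = psi^{-1}_L(t)(mu(t) + b_s*sex + b_h*(height - ref) +
#' z * sigma(t))`. With `z = 0` this is the covariate-adjusted median
#' curve. Curves for increasing `z` never cross (the inverse transform is
#' strictly increasing).
#'
#' @param model A `normative_model`.
#' @param z The constant z-score of the curve.
#' @param age_grid Ages (years) at which to evaluate.
#' @param sex,height Covariate values of the displayed stratum (defaults:
#'   male, reference height).
#' @param extrapolate Allow ages outside the fitted domain.
#' @return Numeric volumes (mm^3) on the grid.
#' @export
iso_curve <- function(model, z, age_grid, sex = 1, height = NULL,
                      extrapolate = FALSE) {
  stopifnot(inherits(model, "normative_model"))
  if (is.null(height)) height <- model$ref_height
  check_domain(model, age_grid, extrapolate)
  cv <- model_curves(model, age_grid)
  x <- cv$mu + model$coef$beta_sex * sex +
    model$coef$beta_height * (height - model$ref_height) + z * cv$sigma
  y <- tryCatch(yeo_johnson_inverse(x, cv$L), error = function(e) {
    stop(sprintf("iso_curve: z = %g leaves the transform domain within ages [%g, %g]: %s",
                 z, min(age_grid), max(age_grid), conditionMessage(e)))
  })
  y * model$vscale
}

#' Fitted median volume curve
#'
#' Convenience wrapper: [iso_curve()] at `z = 0`.
#'
#' @inheritParams iso_curve
#' @return Numeric volumes (mm^3) on the grid.
#' @export
median_curve <- function(model, age_grid, sex = 1, height = NULL,
                         extrapolate = FALSE) {
  iso_curve(model, 0, age_grid, sex = sex, height = height,
            extrapolate = extrapolate)
}

#' Serialize a normative model to a portable text file
#'
#' JSON with the spline knots and coefficients, covariate coefficients,
#' internal volume scale, age domain, `delta` and diagnostics, so models
#' round-trip between runs.
#'
#' @param model A `normative_model`.
#' @param path Output path.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized normative model
#' @param path Path written by [write_normative_model()].
#' @return A `normative_model`.
#' @export
read_normative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$age_domain <- as.numeric(obj$age_domain)
  obj$basis$knots <- as.numeric(obj$basis$knots)
  obj$basis$boundary <- as.numeric(obj$basis$boundary)
  structure(obj, class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("normative_model (%s, %s): n = %d, delta = %g, ages [%.1f, %.1f]\n",
              x$method, x$region, x$diagnostics$n, x$delta,
              x$age_domain[1], x$age_domain[2]))
  cat(sprintf("  training z: mean %.3f, sd %.3f; loglik %.2f\n",
              x$diagnostics$z_mean, x$diagnostics$z_sd, x$diagnostics$loglik))
  invisible(x)
}
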
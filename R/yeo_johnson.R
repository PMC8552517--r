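#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson transformation is a power-family transformation defined on
#' the whole real line, used here to Gaussianize regional brain volume
#' distributions before fitting normative reference curves. For `y >= 0` it is
#' `((y + 1)^lambda - 1) / lambda` (or `log(y + 1)` when `lambda = 0`); for
#' `y < 0` it is `-(((1 - y)^(2 - lambda) - 1) / (2 - lambda))` (or
#' `-log(1 - y)` when `lambda = 2`). The transform is continuous in `lambda`
#' and strictly increasing in `y`.
#'
#' @param y Numeric vector of values to transform.
#' @param lambda Numeric vector of transformation parameters, recycled
#'   against `y`.
#' @return Numeric vector of transformed values.
#' @examples
#' yeo_johnson(3, 2)          # 7.5
#' yeo_johnson(exp(1) - 1, 0) # 1
#' @export
yeo_johnson <- function(y, lambda) {
  stopifnot(is.numeric(y), is.numeric(lambda))
  if (any(!is.finite(y))) stop("yeo_johnson: 'y' must be finite")
  n <- max(length(y), length(lambda))
  y <- rep_len(as.numeric(y), n)
  lam <- rep_len(as.numeric(lambda), n)
  out <- numeric(n)
  eps <- 1e-8
  pos <- y >= 0
  # positive branch: ((1+y)^lam - 1)/lam, limit log1p(y) as lam -> 0
  i <- pos & abs(lam) > eps
  out[i] <- expm1(lam[i] * log1p(y[i])) / lam[i]
  i <- pos & abs(lam) <= eps
  out[i] <- log1p(y[i])
  # negative branch: -(((1-y)^(2-lam) - 1)/(2-lam)), limit -log1p(-y) as lam -> 2
  i <- !pos & abs(lam - 2) > eps
  out[i] <- -expm1((2 - lam[i]) * log1p(-y[i])) / (2 - lam[i])
  i <- !pos & abs(lam - 2) <= eps
  out[i] <- -log1p(-y[i])
  out
}

#' Inverse Yeo-Johnson transformation
#'
#' Inverts [yeo_johnson()]: `yeo_johnson(yeo_johnson_inverse(x, lambda),
#' lambda)` recovers `x`. Values outside the image of the transform for the
#' given `lambda` (e.g. `x <= -1/lambda` for `lambda > 0`) have no preimage
#' and raise a domain error.
#'
#' @param x Numeric vector of transformed values.
#' @param lambda Numeric vector of transformation parameters, recycled.
#' @return Numeric vector `y` with `yeo_johnson(y, lambda) == x`.
#' @examples
#' yeo_johnson_inverse(7.5, 2) # 3
#' @export
yeo_johnson_inverse <- function(x, lambda) {
  stopifnot(is.numeric(x), is.numeric(lambda))
  if (any(!is.finite(x))) stop("yeo_johnson_inverse: 'x' must be finite")
  n <- max(length(x), length(lambda))
  x <- rep_len(as.numeric(x), n)
  lam <- rep_len(as.numeric(lambda), n)
  out <- numeric(n)
  eps <- 1e-8
  pos <- x >= 0
  # positive branch inverse: y = (lam*x + 1)^(1/lam) - 1
  i <- pos & abs(lam) > eps
  if (any(bad <- i & lam * x + 1 <= 0)) {
    stop(sprintf("yeo_johnson_inverse: x = %g outside the transform image for lambda = %g",
                 x[which(bad)[1]], lam[which(bad)[1]]))
  }
  out[i] <- expm1(log1p(lam[i] * x[i]) / lam[i])
  i <- pos & abs(lam) <= eps
  out[i] <- expm1(x[i])
  # negative branch inverse: y = 1 - (1 - (2-lam)*x)^(1/(2-lam))
  i <- !pos & abs(lam - 2) > eps
  if (any(bad <- i & 1 - (2 - lam) * x <= 0)) {
    stop(sprintf("yeo_johnson_inverse: x = %g outside the transform image for lambda = %g",
                 x[which(bad)[1]], lam[which(bad)[1]]))
  }
  out[i] <- -expm1(log1p(-(2 - lam[i]) * x[i]) / (2 - lam[i]))
  i <- !pos & abs(lam - 2) <= eps
  out[i] <- -expm1(-x[i])
  out
}

# d psi_lambda(y) / dy; needed for the Jacobian term of the LMS likelihood
yeo_johnson_deriv <- function(y, lambda) {
  n <- max(length(y), length(lambda))
  y <- rep_len(as.numeric(y), n)
  lam <- rep_len(as.numeric(lambda), n)
  out <- numeric(n)
  pos <- y >= 0
  out[pos] <- exp((lam[pos] - 1) * log1p(y[pos]))
  out[!pos] <- exp((1 - lam[!pos]) * log1p(-y[!pos]))
  out
}
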
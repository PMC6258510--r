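## Log densities used throughout. All quadratic forms go through a Cholesky
## factor so profiles of dimension up to a few dozen fractions never leave
## log space.

chol_pd <- function(S, what = "covariance") {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("degenerate ", what, " matrix: not symmetric", call. = FALSE)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R))
    stop("degenerate ", what, " matrix: not positive definite", call. = FALSE)
  R
}

## rows of x against one (mean, chol factor R); returns N-vector of
## -0.5 * mahalanobis^2 along with the log determinant handled by caller
mahal_sq <- function(x, mean, R) {
  z <- backsolve(R, t(x) - mean, transpose = TRUE)
  colSums(z^2)
}

as_row_matrix <- function(x, D) {
  if (is.null(dim(x))) {
    if (length(x) %% D != 0L) stop("`x` length incompatible with dimension D")
    matrix(x, ncol = D, byrow = TRUE)
  } else as.matrix(x)
}

#' Multivariate normal log-density
#'
#' Density of the multivariate normal distribution used for the annotated
#' niche components, evaluated in log space via a Cholesky factorisation.
#'
#' @param x A numeric vector of length `D`, or an `N x D` matrix of row
#'   vectors.
#' @param mean Mean vector of length `D`.
#' @param cov Positive-definite `D x D` covariance matrix.
#' @return A numeric vector of log-density values, one per row of `x`.
#' @examples
#' mvnorm_logpdf(0, 0, 1)          # -0.5 * log(2 * pi)
#' @export
mvnorm_logpdf <- function(x, mean, cov) {
  mean <- as.numeric(mean)
  D <- length(mean)
  x <- as_row_matrix(x, D)
  if (ncol(x) != D) stop("`x` and `mean` dimensions differ")
  R <- chol_pd(cov)
  logdet <- 2 * sum(log(diag(R)))
  q <- mahal_sq(x, mean, R)
  as.numeric(-0.5 * (D * log(2 * pi) + logdet + q))
}

#' Multivariate Student-t log-density
#'
#' Density of the heavy-tailed multivariate t distribution used for the
#' outlier component, with degrees of freedom `df`, location `mu` and scale
#' matrix `sigma`.
#'
#' @param x Numeric vector of length `D` or an `N x D` matrix.
#' @param df Degrees of freedom (positive).
#' @param mu Location vector of length `D`.
#' @param sigma Positive-definite `D x D` scale matrix.
#' @return A numeric vector of log-density values.
#' @examples
#' mvt_logpdf(0, 4, 0, 1)          # log(3/8)
#' @export
mvt_logpdf <- function(x, df, mu, sigma) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0)
    stop("`df` must be a positive scalar")
  mu <- as.numeric(mu)
  D <- length(mu)
  x <- as_row_matrix(x, D)
  if (ncol(x) != D) stop("`x` and `mu` dimensions differ")
  R <- chol_pd(sigma, "scale")
  logdet <- 2 * sum(log(diag(R)))
  q <- mahal_sq(x, mu, R)
  as.numeric(lgamma((df + D) / 2) - lgamma(df / 2) -
    0.5 * D * log(df * pi) - 0.5 * logdet -
    0.5 * (df + D) * log1p(q / df))
}

## log multivariate gamma
lmvgamma <- function(a, D) {
  (D * (D - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))
}

## inverse-Wishart log density of Sigma given (nu, S)
liwish <- function(Sigma, nu, S) {
  D <- nrow(S)
  Rs <- chol_pd(S, "scale")
  Rg <- chol_pd(Sigma)
  ldS <- 2 * sum(log(diag(Rs)))
  ldG <- 2 * sum(log(diag(Rg)))
  tr <- sum(backsolve(Rg, backsolve(Rg, S, transpose = TRUE)) * diag(D)) # tr(S Sigma^-1)
  0.5 * nu * ldS - 0.5 * nu * D * log(2) - lmvgamma(nu / 2, D) -
    0.5 * (nu + D + 1) * ldG - 0.5 * tr
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
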
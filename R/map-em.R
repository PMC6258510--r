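## MAP inference by expectation-maximisation (TAGM-MAP).
##
## Latent structure per protein i: a niche label z_i in 1..K and an outlier
## indicator phi_i (phi_i = 1: drawn from the Gaussian of niche z_i;
## phi_i = 0: drawn from the shared Student-t outlier component). The
## E-step computes joint responsibilities
##   a_ik = p(z_i = k, phi_i = 1 | x_i)   (Gaussian route)
##   b_ik = p(z_i = k, phi_i = 0 | x_i)   (outlier route)
## and the M-step maximises the expected log-posterior exactly, using the
## conjugate normal-inverse-Wishart joint mode for each niche.

## densities of all rows of X under each component and under the outlier t
component_logdens <- function(X, params, hyper) {
  K <- nrow(params$means)
  logf <- vapply(seq_len(K), function(k)
    mvnorm_logpdf(X, params$means[k, ], params$covariances[[k]]),
    numeric(nrow(X)))
  logf <- matrix(logf, nrow = nrow(X))
  logg <- mvt_logpdf(X, hyper$kappa, hyper$M, hyper$V)
  list(logf = logf, logg = logg)
}

#' E-step of the TAGM EM algorithm
#'
#' Computes, for every protein, the joint responsibilities of belonging to
#' each niche via the Gaussian route (`a`) and via the outlier route (`b`),
#' normalised jointly over all `2K` outcomes with a log-sum-exp guard.
#' Marker proteins are clamped to their annotated class with `a = 1`.
#'
#' @param X Quantitation matrix.
#' @param markers A [marker_annotation()].
#' @param params Current [component_params()].
#' @param hyper A `tagm_hyper` object.
#' @return A list of class `tagm_em_state` with responsibility matrices `a`,
#'   `b`, `w = a + b`, per-class totals `ak`, `bk`, `rk`, grand totals and
#'   the observed-data log-likelihood contribution `loglik`.
#' @export
tagm_e_step <- function(X, markers, params, hyper) {
  X <- quantitation_matrix(X)
  midx <- check_markers(X, markers)
  N <- nrow(X); K <- length(markers$classes)
  dens <- component_logdens(X, params, hyper)
  lpi <- log(params$weights)
  eps <- params$epsilon
  la <- sweep(dens$logf, 2L, lpi + log1p(-eps), "+")
  lb <- outer(dens$logg, lpi + log(eps), "+")
  joint <- cbind(la, lb)
  lse <- logsumexp_rows(joint)
  if (any(!is.finite(lse))) {
    bad <- rownames(X)[!is.finite(lse)][1L]
    stop("all 2K responsibility terms underflowed for protein ", bad)
  }
  p <- exp(joint - lse)
  a <- p[, seq_len(K), drop = FALSE]
  b <- p[, K + seq_len(K), drop = FALSE]

  unl <- setdiff(seq_len(N), midx)
  loglik <- sum(lse[unl])
  if (length(midx)) {
    mk <- match(markers$labels, markers$classes)
    a[midx, ] <- 0; b[midx, ] <- 0
    a[cbind(midx, mk)] <- 1
    loglik <- loglik + sum(la[cbind(midx, mk)])
  }
  dimnames(a) <- dimnames(b) <- list(rownames(X), markers$classes)
  w <- a + b
  structure(list(a = a, b = b, w = w,
                 ak = colSums(a), bk = colSums(b), rk = colSums(w),
                 a_tot = sum(a), b_tot = sum(b), loglik = loglik),
            class = "tagm_em_state")
}

## NIW posterior-mode update for one class given soft counts
niw_mode_update <- function(X, aik, hyper) {
  D <- ncol(X)
  ak <- sum(aik)
  if (ak <= 0) {
    lambda_k <- hyper$lambda0; nu_k <- hyper$nu0
    m_k <- hyper$mu0; S_k <- hyper$S0
  } else {
    xbar <- colSums(aik * X) / ak
    lambda_k <- hyper$lambda0 + ak
    nu_k <- hyper$nu0 + ak
    m_k <- (ak * xbar + hyper$lambda0 * hyper$mu0) / lambda_k
    cX <- sweep(X, 2L, xbar)
    scatter <- crossprod(sqrt(aik) * cX)
    d <- xbar - hyper$mu0
    S_k <- hyper$S0 + scatter + (hyper$lambda0 * ak / lambda_k) * tcrossprod(d)
  }
  list(lambda = lambda_k, nu = nu_k, m = m_k, S = S_k,
       mu_hat = m_k, sigma_hat = S_k / (nu_k + D + 2))
}

#' M-step of the TAGM EM algorithm
#'
#' Exact maximiser of the expected log-posterior: posterior-mode updates for
#' the outlier weight (Beta), the mixture weights (Dirichlet) and each
#' niche's mean and covariance (joint normal-inverse-Wishart mode).
#'
#' @param state A `tagm_em_state` from [tagm_e_step()].
#' @param X,markers,hyper As in [tagm_e_step()].
#' @return A list with elements `params` (updated [component_params()]) and
#'   `niw` (per-class posterior quantities `lambda`, `nu`, `m`, `S`).
#' @export
tagm_m_step <- function(state, X, markers, hyper) {
  X <- quantitation_matrix(X)
  N <- nrow(X); K <- length(markers$classes); D <- ncol(X)
  eps <- (hyper$u + state$b_tot - 1) / (N + hyper$u + hyper$v - 2)
  eps <- min(max(eps, 0), 1)
  wts <- (state$rk + hyper$beta - 1) / (N + sum(hyper$beta) - K)
  if (any(wts < 0))
    stop("negative mixture weight in M-step (beta < 1 with empty component)")
  wts <- wts / sum(wts)
  niw <- lapply(seq_len(K), function(k) niw_mode_update(X, state$a[, k], hyper))
  params <- component_params(
    means = do.call(rbind, lapply(niw, `[[`, "mu_hat")),
    covariances = lapply(niw, `[[`, "sigma_hat"),
    weights = wts, epsilon = eps)
  rownames(params$means) <- markers$classes
  list(params = params, niw = niw)
}

## log prior density of (pi, eps, {mu_k, Sigma_k}); constants included so the
## posterior trace is an actual log density up to the data normalisation
log_prior <- function(params, hyper) {
  K <- length(params$weights)
  lp <- lgamma(sum(hyper$beta)) - sum(lgamma(hyper$beta)) +
    sum((hyper$beta - 1) * log(params$weights))
  lp <- lp - lbeta(hyper$u, hyper$v) +
    (hyper$u - 1) * log(params$epsilon) +
    (hyper$v - 1) * log1p(-params$epsilon)
  for (k in seq_len(K)) {
    Sk <- params$covariances[[k]]
    lp <- lp + mvnorm_logpdf(params$means[k, ], hyper$mu0, Sk / hyper$lambda0) +
      liwish(Sk, hyper$nu0, hyper$S0)
  }
  lp
}

## deterministic initialisation: prior-mean weights, marker-moment NIW modes
init_params <- function(X, markers, hyper) {
  K <- length(markers$classes)
  midx <- check_markers(X, markers)
  a0 <- matrix(0, nrow(X), K)
  a0[cbind(midx, match(markers$labels, markers$classes))] <- 1
  niw <- lapply(seq_len(K), function(k) niw_mode_update(X, a0[, k], hyper))
  params <- component_params(
    means = do.call(rbind, lapply(niw, `[[`, "mu_hat")),
    covariances = lapply(niw, `[[`, "sigma_hat"),
    weights = hyper$beta / sum(hyper$beta),
    epsilon = hyper$u / (hyper$u + hyper$v))
  rownames(params$means) <- markers$classes
  params
}

#' Fit the TAGM model by MAP expectation-maximisation
#'
#' Alternates E- and M-steps until the observed-data log-posterior changes
#' by less than `tol` between successive iterations, or `max_iter`
#' iterations have been performed. Initialisation is deterministic: mixture
#' and outlier weights start at their prior means and each niche's mean and
#' covariance at the NIW posterior mode given its markers only.
#'
#' @param X Quantitation matrix (`N x D`).
#' @param markers A [marker_annotation()]; every class needs at least one
#'   marker.
#' @param hyper Optional `tagm_hyper`; defaults to
#'   [default_hyperparameters()].
#' @param tol Convergence tolerance on the absolute change of the
#'   log-posterior (default `1e-6`).
#' @param max_iter Maximum number of EM iterations (default 200).
#' @return An object of class `tagm_map` with MAP parameter estimates,
#'   per-class NIW posterior quantities, the log-posterior trace (which is
#'   non-decreasing), the `N x K` localisation probability matrix
#'   (marker rows are clamped to probability 1) and the per-protein outlier
#'   probability.
#' @examples
#' sim <- generate_tagm_dataset(n = 120, means = rbind(c(-4, 0), c(4, 0)),
#'                              seed = 1)
#' mk <- make_marker_annotation(sim, marker_fraction = 0.3, seed = 2)
#' fit <- fit_tagm_map(sim$expression, mk)
#' head(fit$localisation)
#' @export
fit_tagm_map <- function(X, markers, hyper = NULL, tol = 1e-6, max_iter = 200L) {
  stopifnot(tol > 0, max_iter >= 1L)
  X <- quantitation_matrix(X)
  if (is.null(hyper)) hyper <- default_hyperparameters(X, markers)
  validate_hyper(hyper)
  if (length(hyper$beta) != length(markers$classes))
    stop("length of beta must equal the number of classes")
  if (!length(markers$labels)) stop("fitting requires at least one marker per class")
  cnt <- table(factor(markers$labels, levels = markers$classes))
  if (any(cnt == 0))
    stop("class without markers: ", paste(names(cnt)[cnt == 0], collapse = ", "))

  params <- init_params(X, markers, hyper)
  niw <- NULL
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- tagm_e_step(X, markers, params, hyper)
    Q <- st$loglik + log_prior(params, hyper)
    if (!is.finite(Q)) stop("non-finite log-posterior at iteration ", it)
    trace <- c(trace, Q)
    if (it >= 2L && abs(Q - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    ms <- tagm_m_step(st, X, markers, hyper)
    params <- ms$params; niw <- ms$niw
    n_iter <- it
  }
  ## prediction uses the final parameter estimates (one extra E-step when
  ## the iteration budget, not the tolerance, stopped the loop)
  if (!converged) st <- tagm_e_step(X, markers, params, hyper)
  structure(list(params = params, niw = niw, converged = converged,
                 n_iterations = n_iter, posterior_trace = trace,
                 localisation = st$a, outlier_prob = rowSums(st$b),
                 classes = markers$classes, markers = markers, hyper = hyper,
                 fraction_ids = colnames(X), protein_ids = rownames(X)),
            class = "tagm_map")
}

#' @export
print.tagm_map <- function(x, ...) {
  cat("TAGM-MAP fit:", length(x$protein_ids), "proteins,",
      length(x$classes), "niches\n")
  cat("  iterations:", x$n_iterations, if (x$converged) "(converged)" else
      "(not converged)", "\n")
  cat("  epsilon-hat:", format(x$params$epsilon, digits = 4), "\n")
  invisible(x)
}

#' Predict localisation probabilities from a MAP fit
#'
#' Plugs the MAP parameter estimates into the allocation formulas to obtain,
#' for each protein, the posterior probability of belonging to each niche
#' (jointly with not being an outlier) and the posterior outlier
#' probability. Proteins annotated as markers are reported with probability
#' 1 for their annotated class.
#'
#' @param object A `tagm_map` fit.
#' @param newdata Optional quantitation matrix with the same fractions as
#'   the training data; defaults to reporting the training allocation.
#' @param ... Unused.
#' @return A list with `localisation` (`N x K` matrix) and `outlier_prob`
#'   (length-`N` vector); each row of `localisation` plus its outlier
#'   probability sums to 1.
#' @export
predict.tagm_map <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(list(localisation = object$localisation,
                outlier_prob = object$outlier_prob))
  X <- quantitation_matrix(newdata)
  if (!identical(colnames(X), object$fraction_ids))
    stop("fraction names of `newdata` do not match the training data")
  known <- intersect(rownames(X), names(object$markers$labels))
  mk <- marker_annotation(object$markers$labels[known],
                          classes = object$classes)
  st <- tagm_e_step(X, mk, object$params, object$hyper)
  list(localisation = st$a, outlier_prob = rowSums(st$b))
}
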
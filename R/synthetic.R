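## Synthetic datasets drawn from the TAGM generative model with known
## ground truth. These stand in for LOPIT/hyperLOPIT quantitation data in
## tests and simulation studies: per protein a niche label z_i ~
## Categorical(pi), an indicator phi_i ~ Bernoulli(1 - epsilon), then a
## profile from N(mu_z, Sigma_z) when phi_i = 1 or from the heavy-tailed
## t(kappa, M, V) outlier component when phi_i = 0.

rmvnorm_chol <- function(n, mean, R) {
  D <- length(mean)
  z <- matrix(rnorm(n * D), n, D)
  sweep(z %*% R, 2L, mean, "+")
}

#' Generate a synthetic TAGM dataset
#'
#' @param n Number of proteins.
#' @param means `K x D` matrix of niche means.
#' @param covariances List of `K` positive-definite covariance matrices;
#'   defaults to identity.
#' @param weights Mixture weights (default uniform).
#' @param epsilon Prior outlier probability (default 0).
#' @param kappa,M,V Outlier t parameters; `M` defaults to the column mean of
#'   `means` and `V` to half the global covariance implied by the niche
#'   spread plus the average within-niche covariance.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A list of class `tagm_sim` with `expression` (quantitation
#'   matrix with protein/fraction IDs) and `truth` (a list with the class
#'   indices `z`, outlier indicators `phi`, the generating
#'   [component_params()], the outlier parameters and the seed).
#' @export
generate_tagm_dataset <- function(n, means, covariances = NULL,
                                  weights = NULL, epsilon = 0,
                                  kappa = 4, M = NULL, V = NULL,
                                  seed = NULL) {
  means <- as.matrix(means)
  K <- nrow(means); D <- ncol(means)
  if (is.null(covariances)) covariances <- rep(list(diag(D)), K)
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (abs(sum(weights) - 1) > 1e-10 || any(weights < 0))
    stop("`weights` must be a probability vector over K classes")
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must lie in [0, 1]")
  if (is.null(M)) M <- colMeans(means)
  if (is.null(V)) {
    spread <- if (K > 1) cov(means) else diag(0, D)
    V <- 0.5 * (spread + Reduce(`+`, covariances) / K)
  }
  Rv <- chol_pd(V, "outlier scale V")
  Rk <- lapply(covariances, chol_pd)
  params <- component_params(means, covariances, weights, epsilon)

  with_seed(seed, {
    z <- sample.int(K, n, replace = TRUE, prob = weights)
    phi <- rbinom(n, 1L, 1 - epsilon)
    X <- matrix(NA_real_, n, D)
    for (k in seq_len(K)) {
      idx <- which(z == k & phi == 1L)
      if (length(idx))
        X[idx, ] <- rmvnorm_chol(length(idx), means[k, ], Rk[[k]])
    }
    out <- which(phi == 0L)
    if (length(out)) {
      g <- rmvnorm_chol(length(out), rep(0, D), Rv)
      s <- sqrt(rchisq(length(out), df = kappa) / kappa)
      X[out, ] <- sweep(g / s, 2L, M, "+")
    }
    rownames(X) <- sprintf("protein_%04d", seq_len(n))
    colnames(X) <- sprintf("fraction_%d", seq_len(D))
    structure(list(expression = X,
                   truth = list(z = z, phi = phi, params = params,
                                kappa = kappa, M = M, V = V, seed = seed)),
              class = "tagm_sim")
  })
}

#' Well-separated niche means
#'
#' Draws `K` mean vectors in `D` dimensions whose pairwise Euclidean
#' distances are all at least `separation * base_scale`, by rejection
#' sampling in a hypercube that is widened on failure.
#'
#' @param K,D Number of niches and fractions.
#' @param separation Minimum pairwise distance in units of `base_scale`.
#' @param base_scale Length scale (typically the within-niche standard
#'   deviation; default 1).
#' @param seed Integer seed.
#' @return A `K x D` matrix of means.
#' @export
separated_means <- function(K, D, separation, base_scale = 1, seed = NULL) {
  stopifnot(K >= 1L, D >= 1L, separation >= 0, base_scale > 0)
  min_d <- separation * base_scale
  with_seed(seed, {
    half <- max(min_d, 1) * max(1, ceiling(K^(1 / D)))
    for (try in seq_len(200L)) {
      m <- matrix(runif(K * D, -half, half), K, D)
      if (K == 1L || min(dist(m)) >= min_d) return(m)
      half <- half * 1.3
    }
    stop("could not place ", K, " means at separation ", min_d,
         " after 200 attempts")
  })
}

#' Marker annotation from a synthetic truth
#'
#' Selects, per niche, a seeded sample of `round(marker_fraction * n_c)` of
#' its non-outlier proteins (at least one) as markers labelled with their
#' generating class. Outlier proteins (`phi = 0`) are never markers, since
#' markers represent curated, unambiguous single-niche annotations.
#'
#' @param sim A `tagm_sim` from [generate_tagm_dataset()].
#' @param marker_fraction Fraction in `(0, 1]` of each niche's non-outlier
#'   proteins to annotate.
#' @param seed Integer seed.
#' @return A [marker_annotation()].
#' @export
make_marker_annotation <- function(sim, marker_fraction, seed = NULL) {
  stopifnot(inherits(sim, "tagm_sim"),
            marker_fraction > 0, marker_fraction <= 1)
  z <- sim$truth$z; phi <- sim$truth$phi
  K <- nrow(sim$truth$params$means)
  ids <- rownames(sim$expression)
  classes <- paste0("class_", seq_len(K))
  with_seed(seed, {
    lab <- character(0)
    for (k in seq_len(K)) {
      pool <- which(z == k & phi == 1L)
      if (!length(pool))
        stop("class ", k, " has no non-outlier protein to use as marker")
      m <- max(1L, round(marker_fraction * length(pool)))
      pick <- pool[sample.int(length(pool), m)]
      lab <- c(lab, setNames(rep(classes[k], m), ids[pick]))
    }
    marker_annotation(lab, classes = classes)
  })
}
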
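## Fully Bayesian inference (TAGM-MCMC): a collapsed Gibbs sampler over the
## allocation variables (z_i, phi_i) of the unlabelled proteins. Mixture
## weights are marginalised to Dirichlet-multinomial counts, each niche's
## (mu_k, Sigma_k) to its normal-inverse-Wishart posterior predictive, and
## the outlier weight epsilon is resampled from its conjugate Beta full
## conditional. Marker allocations are clamped and never resampled.

#' Per-class sufficient statistics
#'
#' Running count, sum and sum of outer products of the profiles currently
#' assigned to a niche (markers plus non-outlier unlabelled members), from
#' which the NIW posterior predictive is computed.
#'
#' @param X Optional matrix of member rows; an empty statistic of dimension
#'   `D` is returned when only `D` is given.
#' @param D Profile dimension (required when `X` is missing).
#' @return A list with elements `n`, `xsum`, `xx`.
#' @export
class_suffstats <- function(X = NULL, D = NULL) {
  if (is.null(X)) {
    stopifnot(!is.null(D))
    return(list(n = 0, xsum = rep(0, D), xx = matrix(0, D, D)))
  }
  X <- as.matrix(X)
  list(n = nrow(X), xsum = colSums(X), xx = crossprod(X))
}

#' @rdname class_suffstats
#' @param ss A sufficient-statistics list.
#' @param x A single profile (length-`D` vector) to add or remove.
#' @export
suffstats_add <- function(ss, x) {
  x <- as.numeric(x)
  list(n = ss$n + 1, xsum = ss$xsum + x, xx = ss$xx + tcrossprod(x))
}

#' @rdname class_suffstats
#' @export
suffstats_remove <- function(ss, x) {
  if (ss$n < 1) stop("cannot remove from an empty sufficient statistic")
  x <- as.numeric(x)
  list(n = ss$n - 1, xsum = ss$xsum - x, xx = ss$xx - tcrossprod(x))
}

## NIW posterior given a class's members
niw_posterior <- function(ss, hyper) {
  n <- ss$n
  lambda_n <- hyper$lambda0 + n
  nu_n <- hyper$nu0 + n
  if (n > 0) {
    xbar <- ss$xsum / n
    d <- xbar - hyper$mu0
    S_n <- hyper$S0 + (ss$xx - n * tcrossprod(xbar)) +
      (hyper$lambda0 * n / lambda_n) * tcrossprod(d)
    m_n <- (hyper$lambda0 * hyper$mu0 + ss$xsum) / lambda_n
  } else {
    S_n <- hyper$S0
    m_n <- hyper$mu0
  }
  list(lambda = lambda_n, nu = nu_n, m = m_n, S = S_n)
}

#' NIW posterior-predictive log-density
#'
#' Log-density of a profile under the normal-inverse-Wishart posterior
#' predictive of a niche given its current members: a multivariate
#' Student-t with `nu_n - D + 1` degrees of freedom, location `m_n` and
#' scale `S_n (lambda_n + 1) / (lambda_n (nu_n - D + 1))`. With zero
#' members this is the prior predictive.
#'
#' @param x Profile vector of length `D`.
#' @param ss Sufficient statistics from [class_suffstats()].
#' @param hyper A `tagm_hyper` object.
#' @return Scalar log-density.
#' @export
niw_predictive_logpdf <- function(x, ss, hyper) {
  D <- length(hyper$mu0)
  po <- niw_posterior(ss, hyper)
  df <- po$nu - D + 1
  if (df <= 0) stop("posterior predictive degrees of freedom must be positive")
  scale <- po$S * ((po$lambda + 1) / (po$lambda * df))
  mvt_logpdf(x, df, po$m, scale)
}

#' MCMC settings
#'
#' @param n_chains Number of independent chains (default 6).
#' @param n_iter Total Gibbs sweeps per chain (default 15000).
#' @param burn_in Sweeps discarded as burn-in (default 4000).
#' @param thin Retain every `thin`-th post-burn-in sweep (default 10).
#' @param seed Integer seed from which per-chain sub-seeds are derived.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 6L, n_iter = 15000L, burn_in = 4000L,
                          thin = 10L, seed = 1L) {
  s <- structure(list(n_chains = as.integer(n_chains),
                      n_iter = as.integer(n_iter),
                      burn_in = as.integer(burn_in),
                      thin = as.integer(thin), seed = as.integer(seed)),
                 class = "mcmc_settings")
  if (s$n_chains < 1L) stop("need at least one chain")
  if (s$burn_in < 0L || s$n_iter <= s$burn_in)
    stop("`n_iter` must exceed `burn_in` (burn_in >= 0)")
  if (s$thin < 1L) stop("`thin` must be at least 1")
  s
}

#' Number of retained samples per chain
#'
#' Retention keeps every `thin`-th sweep after burn-in, so
#' `floor((n_iter - burn_in) / thin)` samples are retained: with 15000
#' sweeps, 4000 burn-in and thinning by 10, 1100 samples per chain.
#'
#' @param settings An [mcmc_settings()] object.
#' @return Integer count of retained samples.
#' @export
retained_samples <- function(settings) {
  (settings$n_iter - settings$burn_in) %/% settings$thin
}

## initial sampler state for the reference R sweep
gibbs_init <- function(X, markers, hyper, z = NULL, phi = NULL,
                       epsilon = NULL) {
  X <- quantitation_matrix(X)
  midx <- check_markers(X, markers)
  K <- length(markers$classes)
  unl <- setdiff(seq_len(nrow(X)), midx)
  Xu <- X[unl, , drop = FALSE]
  if (is.null(z)) z <- sample.int(K, length(unl), replace = TRUE)
  if (is.null(phi)) phi <- rep(1L, length(unl))
  if (is.null(epsilon)) epsilon <- hyper$u / (hyper$u + hyper$v)
  mcls <- match(markers$labels, markers$classes)
  stats <- lapply(seq_len(K), function(k) {
    rows <- c(midx[mcls == k], unl[z == k & phi == 1L])
    if (length(rows)) class_suffstats(X[rows, , drop = FALSE])
    else class_suffstats(D = ncol(X))
  })
  nz <- tabulate(mcls, K) + tabulate(z, K)
  list(z = as.integer(z), phi = as.integer(phi), epsilon = epsilon,
       stats = stats, nz = nz, Xu = Xu, unlabelled = rownames(X)[unl],
       logg = mvt_logpdf(Xu, hyper$kappa, hyper$M, hyper$V),
       prob = matrix(NA_real_, length(unl), K),
       prob_out = rep(NA_real_, length(unl)))
}

#' One collapsed Gibbs sweep (reference implementation)
#'
#' Visits each unlabelled protein in turn: removes it from its niche's
#' statistics, computes the `2K` conditional weights — `(k, phi = 1)`
#' proportional to `(n_k + beta_k)(1 - epsilon)` times the niche's NIW
#' posterior predictive, `(k, phi = 0)` proportional to
#' `(n_k + beta_k) epsilon` times the outlier t density — normalises with a
#' log-sum-exp guard, samples an outcome and reinserts the protein. The
#' outlier weight is then resampled from `Beta(u + #phi=0, v + #phi=1)`
#' over the unlabelled proteins, unless fixed. The conditional (Rao-
#' Blackwellised) niche probabilities are recorded in `state$prob`.
#'
#' This pure-R sweep is the reference for the compiled kernel used by
#' [run_tagm_chains()]; both draw from R's global RNG stream.
#'
#' @param state Sampler state from a previous sweep or internal
#'   initialisation.
#' @param X,markers,hyper As in [fit_tagm_map()].
#' @param fix_epsilon Optional fixed outlier weight (skips the Beta draw).
#' @return The updated state.
#' @export
collapsed_gibbs_sweep <- function(state, X, markers, hyper,
                                  fix_epsilon = NULL) {
  K <- length(markers$classes)
  beta <- hyper$beta
  eps <- if (is.null(fix_epsilon)) state$epsilon else fix_epsilon
  leps <- log(eps); l1meps <- log1p(-eps)
  for (i in seq_along(state$z)) {
    x <- state$Xu[i, ]
    k_cur <- state$z[i]
    state$nz[k_cur] <- state$nz[k_cur] - 1
    if (state$phi[i] == 1L)
      state$stats[[k_cur]] <- suffstats_remove(state$stats[[k_cur]], x)
    logw <- numeric(2L * K)
    for (k in seq_len(K)) {
      lp <- niw_predictive_logpdf(x, state$stats[[k]], hyper)
      lnk <- log(state$nz[k] + beta[k])
      logw[k] <- lnk + l1meps + lp
      logw[K + k] <- lnk + leps + state$logg[i]
    }
    m <- max(logw)
    w <- exp(logw - m)
    p <- w / sum(w)
    u <- runif(1)
    j <- which(cumsum(p) >= u)[1L]
    if (is.na(j)) j <- 2L * K
    state$z[i] <- ((j - 1L) %% K) + 1L
    state$phi[i] <- if (j <= K) 1L else 0L
    state$nz[state$z[i]] <- state$nz[state$z[i]] + 1
    if (state$phi[i] == 1L)
      state$stats[[state$z[i]]] <- suffstats_add(state$stats[[state$z[i]]], x)
    state$prob[i, ] <- p[seq_len(K)]
    state$prob_out[i] <- sum(p[K + seq_len(K)])
  }
  if (is.null(fix_epsilon)) {
    n_out <- sum(state$phi == 0L)
    state$epsilon <- rbeta(1, hyper$u + n_out,
                           hyper$v + length(state$phi) - n_out)
  } else state$epsilon <- fix_epsilon
  state
}

#' Run multiple collapsed Gibbs chains
#'
#' Runs `settings$n_chains` independent chains with distinct sub-seeds
#' derived deterministically from `settings$seed`. Each chain starts from a
#' random allocation of the unlabelled proteins (all initially non-outlier)
#' and uses a compiled kernel for the sweeps. Burn-in sweeps are discarded
#' and every `thin`-th retained.
#'
#' @param X Quantitation matrix.
#' @param markers A [marker_annotation()].
#' @param hyper Optional `tagm_hyper`; defaults to
#'   [default_hyperparameters()].
#' @param settings An [mcmc_settings()] object.
#' @param fix_epsilon Optional fixed outlier weight (mainly for validation
#'   against exact enumeration).
#' @return A list of class `tagm_chains`; each element is a `tagm_chain`
#'   with retained allocation samples (`T' x N_U`), outlier-indicator
#'   samples, an `N_U x K x T'` array of conditional localisation
#'   probabilities, outlier probabilities, epsilon samples and the
#'   per-sweep count of non-outlier allocations (`phi_trace`, all sweeps).
#' @examples
#' sim <- generate_tagm_dataset(n = 60, means = rbind(c(-4, 0), c(4, 0)),
#'                              seed = 1)
#' mk <- make_marker_annotation(sim, 0.3, seed = 2)
#' ch <- run_tagm_chains(sim$expression, mk,
#'                       settings = mcmc_settings(n_chains = 2, n_iter = 200,
#'                                                burn_in = 50, thin = 5,
#'                                                seed = 7))
#' summ <- summarize_posterior(pool_chains(ch))
#' @export
run_tagm_chains <- function(X, markers, hyper = NULL,
                            settings = mcmc_settings(),
                            fix_epsilon = NULL) {
  X <- quantitation_matrix(X)
  if (is.null(hyper)) hyper <- default_hyperparameters(X, markers)
  validate_hyper(hyper)
  midx <- check_markers(X, markers)
  K <- length(markers$classes)
  unl <- setdiff(seq_len(nrow(X)), midx)
  if (!length(unl)) stop("no unlabelled proteins to sample")
  Xu <- X[unl, , drop = FALSE]
  logg <- mvt_logpdf(Xu, hyper$kappa, hyper$M, hyper$V)
  mcls <- match(markers$labels, markers$classes)
  marker_n <- as.numeric(tabulate(mcls, K))
  D <- ncol(X)
  marker_xsum <- matrix(0, D, K)
  marker_xx <- array(0, c(D, D, K))
  for (k in seq_len(K)) {
    rows <- midx[mcls == k]
    if (length(rows)) {
      ss <- class_suffstats(X[rows, , drop = FALSE])
      marker_xsum[, k] <- ss$xsum
      marker_xx[, , k] <- ss$xx
    }
  }
  chains <- with_seed(settings$seed, {
    subs <- sample.int(.Machine$integer.max - 1L, settings$n_chains)
    lapply(seq_len(settings$n_chains), function(ci) {
      with_seed(subs[ci], {
        z0 <- sample.int(K, length(unl), replace = TRUE)
        phi0 <- rep(1L, length(unl))
        eps0 <- if (is.null(fix_epsilon)) hyper$u / (hyper$u + hyper$v)
                else fix_epsilon
        res <- gibbs_kernel(Xu, z0 - 1L, phi0, marker_xsum, marker_xx,
                            marker_n, hyper$beta, hyper$mu0, hyper$lambda0,
                            hyper$nu0, hyper$S0, hyper$u, hyper$v, logg,
                            eps0, !is.null(fix_epsilon),
                            settings$n_iter, settings$burn_in, settings$thin)
        dimnames(res$z) <- list(NULL, rownames(Xu))
        dimnames(res$phi) <- list(NULL, rownames(Xu))
        dimnames(res$prob) <- list(rownames(Xu), markers$classes, NULL)
        structure(list(allocation_samples = res$z + 1L,
                       outlier_samples = res$phi,
                       prob_samples = res$prob,
                       prob_out_samples = res$prob_out,
                       epsilon_samples = as.numeric(res$eps),
                       phi_trace = as.numeric(res$phi_trace),
                       settings = settings, sub_seed = subs[ci],
                       classes = markers$classes,
                       protein_ids = rownames(Xu)),
                  class = "tagm_chain")
      })
    })
  })
  structure(chains, class = "tagm_chains")
}

#' @export
print.tagm_chains <- function(x, ...) {
  s <- x[[1L]]$settings
  cat("TAGM-MCMC:", length(x), "chains x", s$n_iter, "sweeps (burn-in",
      s$burn_in, ", thin", s$thin, ") ->", nrow(x[[1L]]$allocation_samples),
      "retained samples each for", length(x[[1L]]$protein_ids),
      "unlabelled proteins\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from the between- and within-chain variances of a monitored
#' scalar; values near 1 indicate the chains sample the same distribution.
#' The conventional monitored scalar for this model is the per-sweep count
#' of proteins allocated to the known niches (`phi_trace`).
#'
#' @param traces A list of at least two equal-length numeric vectors.
#' @return The scalar potential scale reduction factor; 1 when every chain
#'   is constant and equal (degenerate convention).
#' @export
gelman_rubin <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 2L)
  n <- unique(vapply(traces, length, integer(1)))
  if (length(n) != 1L || n < 2L) stop("chains must share a common length >= 2")
  means <- vapply(traces, mean, numeric(1))
  vars <- vapply(traces, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Chain convergence diagnostics
#'
#' Computes the Gelman-Rubin statistic on the post-burn-in traces of the
#' monitored scalar across all chains, plus a per-chain statistic of each
#' chain against the pooled others to flag non-convergent chains. Chains
#' are never dropped automatically; pass the chains to keep to
#' [pool_chains()].
#'
#' @param chains A `tagm_chains` object.
#' @param threshold Flagging threshold on the per-chain statistic
#'   (default 1.1).
#' @return A list with `rhat` (all chains) and a data frame `per_chain`.
#' @export
tagm_diagnostics <- function(chains, threshold = 1.1) {
  stopifnot(inherits(chains, "tagm_chains"))
  s <- chains[[1L]]$settings
  post <- lapply(chains, function(ch)
    ch$phi_trace[(s$burn_in + 1L):s$n_iter])
  rhat <- if (length(post) >= 2L) gelman_rubin(post) else NA_real_
  per <- vapply(seq_along(post), function(i) {
    if (length(post) < 2L) return(NA_real_)
    rest <- unlist(post[-i])
    m <- min(length(rest), length(post[[i]]))
    gelman_rubin(list(post[[i]][seq_len(m)], rest[seq_len(m)]))
  }, numeric(1))
  list(rhat = rhat,
       per_chain = data.frame(chain = seq_along(post), rhat_vs_rest = per,
                              flagged = !is.na(per) & per > threshold))
}

#' Pool retained samples across chains
#'
#' Concatenates the retained samples of the kept chains after discarding a
#' further `extra_discard` retained samples from the start of each.
#'
#' @param chains A `tagm_chains` object.
#' @param extra_discard Additional retained samples to drop per chain.
#' @param keep Indices of chains to pool (default all).
#' @return A single pooled `tagm_chain`.
#' @export
pool_chains <- function(chains, extra_discard = 0L, keep = seq_along(chains)) {
  stopifnot(inherits(chains, "tagm_chains"))
  if (!length(keep)) stop("`keep` must select at least one chain")
  Tp <- nrow(chains[[1L]]$allocation_samples)
  if (extra_discard >= Tp)
    stop("`extra_discard` (", extra_discard,
         ") leaves no retained samples (T' = ", Tp, ")")
  sel <- (extra_discard + 1L):Tp
  kept <- chains[keep]
  pooled <- list(
    allocation_samples = do.call(rbind, lapply(kept, function(ch)
      ch$allocation_samples[sel, , drop = FALSE])),
    outlier_samples = do.call(rbind, lapply(kept, function(ch)
      ch$outlier_samples[sel, , drop = FALSE])),
    prob_samples = array_cat3(lapply(kept, function(ch)
      ch$prob_samples[, , sel, drop = FALSE])),
    prob_out_samples = do.call(rbind, lapply(kept, function(ch)
      ch$prob_out_samples[sel, , drop = FALSE])),
    epsilon_samples = unlist(lapply(kept, function(ch)
      ch$epsilon_samples[sel])),
    settings = chains[[1L]]$settings,
    classes = chains[[1L]]$classes,
    protein_ids = chains[[1L]]$protein_ids)
  class(pooled) <- "tagm_chain"
  pooled
}

## concatenate a list of N x K x T arrays along the third dimension
array_cat3 <- function(arrs) {
  d <- dim(arrs[[1L]])
  Ts <- vapply(arrs, function(a) dim(a)[3L], integer(1))
  out <- array(NA_real_, c(d[1L], d[2L], sum(Ts)),
               dimnames = c(dimnames(arrs[[1L]])[1:2], list(NULL)))
  at <- 0L
  for (a in arrs) {
    out[, , at + seq_len(dim(a)[3L])] <- a
    at <- at + dim(a)[3L]
  }
  out
}

#' Posterior summary of a pooled chain
#'
#' Monte-Carlo means of the localisation probabilities, the outlier
#' probability, 95% equi-tailed intervals (empirical 0.025/0.975 quantiles,
#' linear-interpolation definition) and the Monte-Carlo averaged Shannon
#' entropy per protein.
#'
#' @param pooled A `tagm_chain`, usually from [pool_chains()].
#' @return An object of class `tagm_summary`.
#' @export
summarize_posterior <- function(pooled) {
  stopifnot(inherits(pooled, "tagm_chain"))
  p <- pooled$prob_samples
  Tn <- dim(p)[3L]
  if (!Tn) stop("empty chain")
  mean_loc <- rowMeans(p, dims = 2L)
  qs <- apply(p, c(1L, 2L), quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  xlx <- p * log(p)
  xlx[p == 0] <- 0
  H <- apply(-xlx, c(1L, 3L), sum)     # N_U x T entropy per sample
  structure(list(mean_localisation = mean_loc,
                 outlier_prob = colMeans(pooled$prob_out_samples),
                 lower95 = qs[1L, , ], upper95 = qs[2L, , ],
                 shannon = rowMeans(H), n_samples = Tn,
                 classes = pooled$classes,
                 protein_ids = pooled$protein_ids),
            class = "tagm_summary")
}

#' @export
print.tagm_summary <- function(x, ...) {
  cat("TAGM posterior summary:", length(x$protein_ids),
      "unlabelled proteins,", length(x$classes), "niches,",
      x$n_samples, "samples\n")
  invisible(x)
}

#' Shannon entropy of an allocation distribution
#'
#' `H = -sum_k p_k log p_k` with the `0 log 0 = 0` convention. For a matrix
#' of sampled probability rows the Monte-Carlo averaged entropy (mean of
#' per-sample entropies) is returned.
#'
#' @param p A probability vector over niches (entries nonnegative, summing
#'   to at most 1) or a samples-by-niches matrix.
#' @return Scalar entropy in `[0, log K]`.
#' @export
shannon_entropy <- function(p) {
  ent <- function(row) {
    if (any(row < 0)) stop("negative probabilities")
    if (sum(row) > 1 + 1e-10) stop("probabilities sum to more than 1")
    nz <- row > 0
    -sum(row[nz] * log(row[nz]))
  }
  if (is.matrix(p)) mean(apply(p, 1L, ent)) else ent(as.numeric(p))
}

#' Classify proteins from posterior probabilities
#'
#' Assigns each protein to the most probable outcome among the `K` niches
#' and the outlier component, reporting it only when its probability
#' exceeds `threshold`; otherwise the protein is left `"unassigned"`. With
#' `threshold = 0` every protein receives its most probable label.
#'
#' @param x A localisation probability matrix, a `tagm_summary` or a
#'   `tagm_map` fit.
#' @param ... Passed to methods.
#' @return A factor with levels `classes`, `"outlier"`, `"unassigned"`,
#'   named by protein.
#' @export
tagm_classify <- function(x, ...) UseMethod("tagm_classify")

#' @rdname tagm_classify
#' @param outlier_prob Outlier probabilities aligned with the rows of `x`.
#' @param threshold Reporting threshold in `[0, 1]` (default 0.95).
#' @export
tagm_classify.default <- function(x, outlier_prob, threshold = 0.95, ...) {
  stopifnot(threshold >= 0, threshold <= 1)
  x <- as.matrix(x)
  classes <- colnames(x)
  full <- cbind(x, .outlier = outlier_prob)
  win <- apply(full, 1L, which.max)
  pw <- full[cbind(seq_len(nrow(full)), win)]
  lab <- c(classes, "outlier")[win]
  lab[pw <= threshold & threshold > 0] <- "unassigned"
  factor(setNames(lab, rownames(x)),
         levels = c(classes, "outlier", "unassigned"))
}

#' @rdname tagm_classify
#' @export
tagm_classify.tagm_summary <- function(x, threshold = 0.95, ...) {
  tagm_classify.default(x$mean_localisation, x$outlier_prob, threshold)
}

#' @rdname tagm_classify
#' @export
tagm_classify.tagm_map <- function(x, threshold = 0.95, ...) {
  tagm_classify.default(x$localisation, x$outlier_prob, threshold)
}
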
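hy1d <- function(K = 2, lambda0 = 1, nu0 = 3, mu0 = 0, S0 = 1)
  hyperparameters(beta = rep(1, K), mu0 = mu0, lambda0 = lambda0, nu0 = nu0,
                  S0 = S0, u = 2, v = 10, kappa = 4, M = 0, V = 2)

test_that("NIW posterior predictive: prior case, update/downdate, quadrature oracle", {
  hy <- hy1d()
  ss0 <- class_suffstats(D = 1)
  # zero members: the prior predictive t with dof nu0 - D + 1
  df <- hy$nu0 - 1 + 1
  expect_equal(niw_predictive_logpdf(0.3, ss0, hy),
               mvt_logpdf(0.3, df, hy$mu0,
                          hy$S0 * (hy$lambda0 + 1) / (hy$lambda0 * df)),
               tolerance = 1e-12)

  # add then remove restores the value
  ss <- class_suffstats(matrix(c(0, 1), 2, 1))
  before <- niw_predictive_logpdf(0.5, ss, hy)
  ss2 <- suffstats_remove(suffstats_add(ss, 2.7), 2.7)
  expect_equal(niw_predictive_logpdf(0.5, ss2, hy), before,
               tolerance = 1e-12)
  expect_error(suffstats_remove(ss0, 1), "empty")

  # numerical integration over (mu, sigma^2) of likelihood x NIW prior
  members <- c(0, 1); x <- 0.5
  niw_prior_dens <- function(mu, s2)
    dnorm(mu, hy$mu0, sqrt(s2 / hy$lambda0)) *
      (hy$S0 / 2)^(hy$nu0 / 2) / gamma(hy$nu0 / 2) *
      s2^(-(hy$nu0 / 2 + 1)) * exp(-hy$S0 / (2 * s2))
  joint <- function(extra) {
    f_outer <- function(s2v) vapply(s2v, function(s2) {
      f_inner <- function(muv) vapply(muv, function(mu)
        prod(dnorm(c(members, extra), mu, sqrt(s2))) *
          niw_prior_dens(mu, s2), numeric(1))
      integrate(f_inner, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
    integrate(f_outer, 0, Inf, rel.tol = 1e-10)$value
  }
  oracle <- log(joint(x)) - log(joint(numeric(0)))
  expect_equal(niw_predictive_logpdf(x, class_suffstats(matrix(members)), hy),
               oracle, tolerance = 1e-6)

  # and against the closed-form marginal-likelihood ratio
  expect_equal(niw_predictive_logpdf(x, class_suffstats(matrix(members)), hy),
               oracle_niw_marginal(matrix(c(members, x)), hy$mu0, hy$lambda0,
                                   hy$nu0, hy$S0) -
                 oracle_niw_marginal(matrix(members), hy$mu0, hy$lambda0,
                                     hy$nu0, hy$S0),
               tolerance = 1e-10)
})

test_that("reference sweep conditionals normalise and match the compiled kernel", {
  fx <- make_fixture(K = 3, D = 2, n = 40, separation = 6, seed = 5)
  X <- fx$sim$expression; mk <- fx$markers
  hy <- default_hyperparameters(X, mk)
  K <- 3
  midx <- match(names(mk$labels), rownames(X))
  unl <- setdiff(seq_len(nrow(X)), midx)

  set.seed(99)
  z0 <- sample.int(K, length(unl), replace = TRUE)
  st <- tagmix:::gibbs_init(X, mk, hy, z = z0, phi = rep(1L, length(unl)))
  nsw <- 50
  zs <- matrix(NA_integer_, nsw, length(unl))
  ps <- array(NA_real_, c(length(unl), K, nsw))
  for (t in seq_len(nsw)) {
    st <- collapsed_gibbs_sweep(st, X, mk, hy)
    zs[t, ] <- st$z; ps[, , t] <- st$prob
    expect_equal(unname(rowSums(st$prob) + st$prob_out),
                 rep(1, length(unl)), tolerance = 1e-10)
  }

  # identical RNG stream through the compiled kernel
  set.seed(99)
  z0b <- sample.int(K, length(unl), replace = TRUE)
  Xu <- X[unl, , drop = FALSE]
  logg <- mvt_logpdf(Xu, hy$kappa, hy$M, hy$V)
  mcls <- match(mk$labels, mk$classes)
  D <- ncol(X)
  mxsum <- matrix(0, D, K); mxx <- array(0, c(D, D, K))
  mn <- as.numeric(tabulate(mcls, K))
  for (k in 1:K) {
    rows <- midx[mcls == k]
    if (length(rows)) {
      ss <- class_suffstats(X[rows, , drop = FALSE])
      mxsum[, k] <- ss$xsum; mxx[, , k] <- ss$xx
    }
  }
  res <- tagmix:::gibbs_kernel(Xu, z0b - 1L, rep(1L, length(unl)), mxsum,
                               mxx, mn, hy$beta, hy$mu0, hy$lambda0, hy$nu0,
                               hy$S0, hy$u, hy$v, logg,
                               hy$u / (hy$u + hy$v), FALSE, nsw, 0L, 1L)
  expect_identical(unname(res$z + 1L), unname(zs))
  expect_lt(max(abs(res$prob - ps)), 1e-10)
})

test_that("no markers and a symmetric prior allocate a lone protein uniformly", {
  X <- matrix(0.3, 1, 1, dimnames = list("p1", "f1"))
  mk <- marker_annotation(character(0), classes = c("c1", "c2"))
  hy <- hy1d()
  ch <- run_tagm_chains(X, mk, hy,
                        settings = mcmc_settings(n_chains = 1,
                                                 n_iter = 10000,
                                                 burn_in = 0, thin = 1,
                                                 seed = 4),
                        fix_epsilon = 0)
  z <- ch[[1]]$allocation_samples[, 1]
  freq <- mean(z == 1)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / length(z)))
  # epsilon fixed at zero: never an outlier
  expect_true(all(ch[[1]]$outlier_samples == 1))
})

test_that("tiny-instance allocation frequencies match exhaustive enumeration", {
  # N_U = 2, K = 2, D = 1, two markers per class, epsilon fixed
  ids <- c("m1", "m2", "m3", "m4", "u1", "u2")
  X <- matrix(c(-2, -1.5, 2, 1.5, -0.5, 0.8), ncol = 1,
              dimnames = list(ids, "f1"))
  mk <- marker_annotation(setNames(c("c1", "c1", "c2", "c2"), ids[1:4]))
  hy <- hy1d()
  eps <- 0.2
  ch <- run_tagm_chains(X, mk, hy,
                        settings = mcmc_settings(n_chains = 1,
                                                 n_iter = 10100,
                                                 burn_in = 100, thin = 1,
                                                 seed = 21),
                        fix_epsilon = eps)[[1]]
  cfg <- oracle_enumerate_two(X[c("u1", "u2"), 1],
                              list(X[c("m1", "m2"), , drop = FALSE],
                                   X[c("m3", "m4"), , drop = FALSE]),
                              hy, eps)
  z <- ch$allocation_samples; phi <- ch$outlier_samples
  for (j in seq_len(nrow(cfg))) {
    ind <- z[, 1] == cfg$z1[j] & phi[, 1] == cfg$phi1[j] &
      z[, 2] == cfg$z2[j] & phi[, 2] == cfg$phi2[j]
    se <- max(batch_se(ind), 1e-6)
    expect_lt(abs(mean(ind) - cfg$prob[j]), 3 * se + 1e-3)
  }
})

test_that("chain protocol: retention arithmetic, determinism, independence", {
  expect_equal(retained_samples(mcmc_settings(n_iter = 15000,
                                              burn_in = 4000, thin = 10)),
               1100)
  expect_error(mcmc_settings(n_iter = 100, burn_in = 100), "exceed")

  fx <- make_fixture(K = 2, D = 2, n = 30, seed = 23)
  st <- mcmc_settings(n_chains = 2, n_iter = 60, burn_in = 20, thin = 4,
                      seed = 77)
  ch1 <- run_tagm_chains(fx$sim$expression, fx$markers, settings = st)
  ch2 <- run_tagm_chains(fx$sim$expression, fx$markers, settings = st)
  expect_identical(ch1[[1]]$allocation_samples, ch2[[1]]$allocation_samples)
  expect_identical(ch1[[2]]$prob_samples, ch2[[2]]$prob_samples)
  # distinct sub-seeds give distinct chains
  expect_false(identical(ch1[[1]]$allocation_samples,
                         ch1[[2]]$allocation_samples))
  expect_equal(nrow(ch1[[1]]$allocation_samples), 10)
  # markers are clamped: only unlabelled proteins are sampled
  expect_false(any(names(fx$markers$labels) %in%
                     colnames(ch1[[1]]$allocation_samples)))
})

test_that("pooling drops extra samples per kept chain and concatenates", {
  fx <- make_fixture(K = 2, D = 2, n = 30, seed = 29)
  st <- mcmc_settings(n_chains = 3, n_iter = 50, burn_in = 10, thin = 2,
                      seed = 5)
  ch <- run_tagm_chains(fx$sim$expression, fx$markers, settings = st)
  Tp <- retained_samples(st)
  pooled <- pool_chains(ch, extra_discard = 5, keep = c(1, 3))
  expect_equal(nrow(pooled$allocation_samples), 2 * (Tp - 5))
  expect_equal(dim(pooled$prob_samples)[3], 2 * (Tp - 5))
  expect_error(pool_chains(ch, extra_discard = Tp), "no retained")
  expect_error(pool_chains(ch, keep = integer(0)), "at least one")
})

test_that("Gelman-Rubin statistic separates converged from shifted chains", {
  set.seed(31)
  iid <- replicate(5, rnorm(600), simplify = FALSE)
  expect_lt(gelman_rubin(iid), 1.1)
  shifted <- iid
  shifted[[3]] <- shifted[[3]] + 10
  expect_gt(gelman_rubin(shifted), 1.1)
  expect_equal(gelman_rubin(list(rep(2, 10), rep(2, 10))), 1)
  expect_error(gelman_rubin(list(rnorm(5))))
})

test_that("posterior summaries: constant chain, alternating samples, linearity", {
  # hand-built pooled chain with one protein, two classes
  p <- array(NA_real_, c(1, 2, 1000))
  p[1, 1, ] <- rep(c(0.2, 0.8), 500)
  p[1, 2, ] <- 1 - p[1, 1, ] - 0.05
  pooled <- structure(list(
    prob_samples = p,
    prob_out_samples = matrix(0.05, 1000, 1),
    allocation_samples = matrix(1L, 1000, 1),
    outlier_samples = matrix(1L, 1000, 1),
    epsilon_samples = rep(0.05, 1000),
    classes = c("c1", "c2"), protein_ids = "p1"), class = "tagm_chain")
  su <- summarize_posterior(pooled)
  expect_equal(unname(su$mean_localisation[1, 1]), 0.5)
  expect_equal(unname(su$lower95[1]), 0.2)
  expect_equal(unname(su$upper95[1]), 0.8)
  expect_equal(unname(rowSums(su$mean_localisation) + su$outlier_prob), 1,
               tolerance = 1e-10)

  # constant samples: zero-width intervals, mean equals the sample
  pc <- p; pc[1, 1, ] <- 0.7; pc[1, 2, ] <- 0.25
  pooled$prob_samples <- pc
  suc <- summarize_posterior(pooled)
  expect_equal(unname(suc$mean_localisation[1, ]), c(0.7, 0.25))
  expect_equal(unname(suc$upper95 - suc$lower95), c(0, 0))
  expect_equal(suc$shannon,
               -(0.7 * log(0.7) + 0.25 * log(0.25)), tolerance = 1e-12)
})

test_that("Shannon entropy closed forms and classification thresholds", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 14, 14)), log(14), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  # Monte-Carlo average over sampled rows
  expect_equal(shannon_entropy(rbind(c(1, 0), c(0.5, 0.5))), log(2) / 2,
               tolerance = 1e-12)

  loc <- rbind(a = c(0.96, 0.02), b = c(0.6, 0.3), c = c(0.02, 0.02))
  colnames(loc) <- c("c1", "c2")
  out <- c(0.02, 0.1, 0.96)
  cl <- tagm_classify(loc, out, threshold = 0.95)
  expect_equal(as.character(cl), c("c1", "unassigned", "outlier"))
  # vacuous threshold: everything gets its argmax (outlier when maximal)
  cl0 <- tagm_classify(loc, out, threshold = 0)
  expect_equal(as.character(cl0), c("c1", "c1", "outlier"))
})
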
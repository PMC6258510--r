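# Independent oracles used to validate the package's computations. These
# deliberately re-derive every formula with direct linear algebra
# (solve/det) or numerical integration rather than calling package paths.

# multivariate normal log-density by the direct formula
oracle_mvnorm <- function(x, mean, cov) {
  D <- length(mean)
  d <- as.numeric(x - mean)
  -0.5 * (D * log(2 * pi) + log(det(as.matrix(cov))) +
            drop(t(d) %*% solve(cov, d)))
}

oracle_lmvgamma <- function(a, D) {
  (D * (D - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))
}

# closed-form NIW marginal likelihood of rows Y under (mu0, lambda0, nu0, S0)
oracle_niw_marginal <- function(Y, mu0, lambda0, nu0, S0) {
  Y <- as.matrix(Y)
  n <- nrow(Y); D <- ncol(Y)
  if (n == 0) return(0)
  ybar <- colMeans(Y)
  lambda_n <- lambda0 + n
  nu_n <- nu0 + n
  C <- crossprod(sweep(Y, 2, ybar))
  d <- ybar - mu0
  S_n <- S0 + C + (lambda0 * n / lambda_n) * tcrossprod(d)
  -0.5 * n * D * log(pi) + 0.5 * D * (log(lambda0) - log(lambda_n)) +
    0.5 * nu0 * log(det(as.matrix(S0))) - 0.5 * nu_n * log(det(S_n)) +
    oracle_lmvgamma(nu_n / 2, D) - oracle_lmvgamma(nu0 / 2, D)
}

# univariate Student-t density with location/scale, via stats::dt
oracle_t_density <- function(x, df, m, scale) {
  stats::dt((x - m) / sqrt(scale), df = df) / sqrt(scale)
}

# exact joint posterior over the 16 (z1, phi1, z2, phi2) configurations of
# two unlabelled 1-D proteins with fixed epsilon, classes with given marker
# rows, flat-ish Dirichlet beta over z of ALL proteins
oracle_enumerate_two <- function(x_unl, marker_rows, hyper, eps) {
  K <- length(marker_rows)
  cfg <- expand.grid(z1 = 1:K, phi1 = 0:1, z2 = 1:K, phi2 = 0:1)
  logg <- vapply(x_unl, function(x)
    mvt_logpdf(x, hyper$kappa, hyper$M, hyper$V), numeric(1))
  logp <- apply(cfg, 1, function(row) {
    z <- c(row[["z1"]], row[["z2"]]); phi <- c(row[["phi1"]], row[["phi2"]])
    nz <- vapply(seq_len(K), function(k)
      nrow(marker_rows[[k]]) + sum(z == k), numeric(1))
    lp <- sum(lgamma(nz + hyper$beta)) +
      sum(phi == 0) * log(eps) + sum(phi == 1) * log(1 - eps)
    for (k in seq_len(K)) {
      members <- rbind(marker_rows[[k]],
                       matrix(x_unl[z == k & phi == 1], ncol = 1))
      lp <- lp + oracle_niw_marginal(members, hyper$mu0, hyper$lambda0,
                                     hyper$nu0, hyper$S0)
    }
    lp + sum(logg[phi == 0])
  })
  p <- exp(logp - max(logp))
  cfg$prob <- p / sum(p)
  cfg
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) 0/1 indicator series
batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  b <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# small well-separated simulation used across tests
make_fixture <- function(K = 3, D = 4, n = 300, separation = 8,
                         epsilon = 0.05, marker_fraction = 0.3,
                         seed = 42) {
  mu <- separated_means(K, D, separation, seed = seed)
  sim <- generate_tagm_dataset(n = n, means = mu, epsilon = epsilon,
                               seed = seed + 1)
  mk <- make_marker_annotation(sim, marker_fraction, seed = seed + 2)
  list(sim = sim, markers = mk, means = mu)
}

# recovery rate of generating labels among non-outlier unlabelled proteins
recovery_rate <- function(prob_matrix, protein_ids, sim) {
  idx <- match(protein_ids, rownames(sim$expression))
  keep <- sim$truth$phi[idx] == 1
  pred <- max.col(prob_matrix)
  mean(pred[keep] == sim$truth$z[idx][keep])
}
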
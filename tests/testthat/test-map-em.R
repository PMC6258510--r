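mk_of <- function(labels) marker_annotation(labels)

test_that("E-step responsibilities: single component, symmetry, hand-normalised oracle", {
  # K = 1, epsilon = 0: every unlabelled protein has a = 1
  X <- matrix(c(0, 1, 2, 3), 4, 1,
              dimnames = list(paste0("p", 1:4), "f1"))
  mk <- mk_of(c(p1 = "c1"))
  hy <- hyperparameters(beta = 1, mu0 = 0, lambda0 = 0.01, nu0 = 3, S0 = 1,
                        u = 2, v = 10, kappa = 4, M = 0, V = 2)
  pp <- component_params(matrix(0, 1, 1), list(matrix(1)), 1, epsilon = 0)
  st <- tagm_e_step(X, mk, pp, hy)
  expect_equal(unname(st$a[, 1]), rep(1, 4))
  expect_equal(unname(st$b[, 1]), rep(0, 4))

  # two identical components, equidistant point: a split 0.5/0.5
  X2 <- matrix(c(2, 0), 1, 2, dimnames = list("q1", c("f1", "f2")))
  mk2 <- marker_annotation(setNames(c("c1", "c2"), c("m1", "m2")),
                           classes = c("c1", "c2"))
  # markers must exist in the matrix for validation; add them
  X2 <- rbind(X2, m1 = c(0, 0), m2 = c(4, 0))
  hy2 <- hyperparameters(beta = c(1, 1), mu0 = c(2, 0), lambda0 = 0.01,
                         nu0 = 4, S0 = diag(2), u = 2, v = 10, kappa = 4,
                         M = c(2, 0), V = 2 * diag(2))
  pp2 <- component_params(rbind(c(0, 0), c(4, 0)),
                          list(diag(2), diag(2)), c(0.5, 0.5), epsilon = 0)
  st2 <- tagm_e_step(X2, mk2, pp2, hy2)
  expect_equal(unname(st2$a["q1", ]), c(0.5, 0.5), tolerance = 1e-12)

  # D = 1 joint-normalisation oracle with an outlier term
  X3 <- matrix(c(0, -1, 5), 3, 1,
               dimnames = list(c("u1", "m1", "m2"), "f1"))
  mk3 <- marker_annotation(setNames(c("c1", "c2"), c("m1", "m2")))
  hy3 <- hyperparameters(beta = c(1, 1), mu0 = 0, lambda0 = 0.01, nu0 = 3,
                         S0 = 1, u = 2, v = 10, kappa = 4, M = 2, V = 2)
  pp3 <- component_params(matrix(c(0, 4), 2, 1), list(matrix(1), matrix(1)),
                          c(0.5, 0.5), epsilon = 0.1)
  st3 <- tagm_e_step(X3, mk3, pp3, hy3)
  ta <- c(0.5 * 0.9 * dnorm(0, 0, 1), 0.5 * 0.9 * dnorm(0, 4, 1))
  g0 <- oracle_t_density(0, 4, 2, 2)
  tb <- c(0.5 * 0.1 * g0, 0.5 * 0.1 * g0)
  Z <- sum(ta) + sum(tb)
  expect_equal(unname(st3$a["u1", ]), ta / Z, tolerance = 1e-10)
  expect_equal(unname(st3$b["u1", ]), tb / Z, tolerance = 1e-10)
  # joint normalisation per protein
  expect_equal(unname(rowSums(st3$a) + rowSums(st3$b)), rep(1, 3),
               tolerance = 1e-10)
})

test_that("M-step posterior-mode updates match the printed formulas", {
  # boundary: no outlier mass and a flat Beta prior give epsilon = 0
  X <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("p", 1:3), "f1"))
  mk <- mk_of(c(p1 = "c1", p2 = "c1", p3 = "c1"))
  hy <- hyperparameters(beta = 1, mu0 = 0, lambda0 = 0.01, nu0 = 3, S0 = 1,
                        u = 1, v = 1, kappa = 4, M = 0, V = 2)
  pp <- component_params(matrix(1, 1, 1), list(matrix(1)), 1, epsilon = 0.2)
  st <- tagm_e_step(X, mk, pp, hy)
  ms <- tagm_m_step(st, X, mk, hy)
  expect_equal(ms$params$epsilon, 0)

  # single class, three labelled 1-D points {0, 1, 2}
  expect_equal(st$ak, c(c1 = 3))
  expect_equal(ms$niw[[1]]$lambda, 3.01)
  expect_equal(ms$niw[[1]]$nu, 6)
  expect_equal(unname(ms$niw[[1]]$m), 3 / 3.01, tolerance = 1e-12)
  expect_equal(unname(ms$params$means[1, 1]), 3 / 3.01, tolerance = 1e-12)

  # symmetric responsibilities give uniform weights under beta = 1
  set.seed(3)
  X4 <- matrix(rnorm(16), 8, 2,
               dimnames = list(paste0("p", 1:8), c("f1", "f2")))
  mk4 <- marker_annotation(setNames(rep(c("c1", "c2"), 4), paste0("p", 1:8)))
  hy4 <- hyperparameters(beta = c(1, 1), mu0 = c(0, 0), lambda0 = 0.01,
                         nu0 = 4, S0 = diag(2), u = 2, v = 10, kappa = 4,
                         M = c(0, 0), V = diag(2))
  pp4 <- component_params(rbind(c(0, 0), c(1, 1)), list(diag(2), diag(2)),
                          c(0.5, 0.5), epsilon = 0.05)
  st4 <- tagm_e_step(X4, mk4, pp4, hy4)
  ms4 <- tagm_m_step(st4, X4, mk4, hy4)
  expect_equal(ms4$params$weights, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("EM fit converges monotonically and stops on the tolerance rule", {
  fx <- make_fixture(K = 3, D = 4, n = 200, seed = 11)
  fit <- fit_tagm_map(fx$sim$expression, fx$markers)
  expect_true(fit$converged)
  expect_gte(min(diff(fit$posterior_trace)), -1e-8)
  # each localisation row plus its outlier probability sums to one
  expect_equal(unname(rowSums(fit$localisation) + fit$outlier_prob),
               rep(1, nrow(fit$localisation)), tolerance = 1e-10)

  # vacuous criterion: infinite tolerance stops after one iteration
  fit1 <- fit_tagm_map(fx$sim$expression, fx$markers, tol = Inf)
  expect_true(fit1$converged)
  expect_equal(fit1$n_iterations, 1L)
})

test_that("well-separated synthetic data is recovered almost perfectly", {
  fx <- make_fixture(K = 3, D = 4, n = 300, separation = 8,
                     epsilon = 0.05, marker_fraction = 0.3, seed = 42)
  fit <- fit_tagm_map(fx$sim$expression, fx$markers)
  unl <- setdiff(rownames(fx$sim$expression), names(fx$markers$labels))
  rate <- recovery_rate(fit$localisation[unl, ], unl, fx$sim)
  expect_gte(rate, 0.99)
})

test_that("class-order permutation permutes outputs without changing them", {
  fx <- make_fixture(K = 3, D = 4, n = 150, seed = 13)
  mk <- fx$markers
  mk_rev <- marker_annotation(mk$labels, classes = rev(mk$classes))
  f1 <- fit_tagm_map(fx$sim$expression, mk)
  f2 <- fit_tagm_map(fx$sim$expression, mk_rev)
  expect_equal(f1$localisation, f2$localisation[, colnames(f1$localisation)],
               tolerance = 1e-9)
  expect_equal(f1$outlier_prob, f2$outlier_prob, tolerance = 1e-9)
})

test_that("prediction clamps markers and reduces to Gaussian responsibilities at epsilon = 0", {
  fx <- make_fixture(K = 2, D = 3, n = 80, seed = 17)
  fit <- fit_tagm_map(fx$sim$expression, fx$markers)
  pr <- predict(fit, newdata = fx$sim$expression)
  mids <- names(fx$markers$labels)
  cls <- match(fx$markers$labels, fx$markers$classes)
  expect_equal(unname(pr$localisation[cbind(mids, fx$markers$classes[cls])]),
               rep(1, length(mids)))
  expect_equal(unname(rowSums(pr$localisation) + pr$outlier_prob),
               rep(1, nrow(pr$localisation)), tolerance = 1e-10)
  expect_error(predict(fit, newdata = matrix(0, 1, 3,
    dimnames = list("z", c("a", "b", "c")))), "fraction")

  # epsilon = 0 reduction: plain mixture responsibilities from direct formula
  p0 <- component_params(fit$params$means, fit$params$covariances,
                         fit$params$weights, epsilon = 0)
  st <- tagm_e_step(fx$sim$expression, fx$markers, p0, fit$hyper)
  unl <- setdiff(rownames(fx$sim$expression), names(fx$markers$labels))
  for (id in head(unl, 5)) {
    x <- fx$sim$expression[id, ]
    lw <- vapply(1:2, function(k)
      log(fit$params$weights[k]) +
        oracle_mvnorm(x, fit$params$means[k, ], fit$params$covariances[[k]]),
      numeric(1))
    expect_equal(unname(st$a[id, ]), exp(lw) / sum(exp(lw)),
                 tolerance = 1e-10)
  }
})
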
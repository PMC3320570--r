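test_that("K = 1 fit on complete data matches the eigendecomposition solution", {
  sim <- simulate_orientations(n_per = 200, angles_deg = 30, noise_sd = 0.3,
                               seed = 3)
  fit <- mppca(sim$x, K = 1, seed = 4, max_iter = 20000, tol = 1e-15)
  S <- crossprod(sim$x) / nrow(sim$x)
  e <- eigen(S, symmetric = TRUE)
  s2_oracle <- mean(e$values[2:3])
  u_oracle <- e$vectors[, 1]
  u_hat <- fit$W[, 1] / sqrt(sum(fit$W[, 1]^2))
  expect_lt(acos(pmin(1, abs(sum(u_hat * u_oracle)))), 1e-6)
  expect_equal(fit$sigma2[1], s2_oracle, tolerance = 1e-8)
  expect_equal(sqrt(sum(fit$W^2)), sqrt(e$values[1] - s2_oracle),
               tolerance = 1e-6)
})

test_that("responsibilities normalize, and K = 1 gives probability 1", {
  sim <- simulate_orientations(n_per = 20, angles_deg = c(0, 90),
                               noise_sd = 0.2, seed = 5)
  fit <- suppressWarnings(mppca(sim$x, K = 2, seed = 6))
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-12))
  fit1 <- mppca(sim$x, K = 1, seed = 6)
  expect_true(all(fit1$responsibilities == 1))
})

test_that("EM log-likelihood trace is monotone and exceeds the initialization", {
  sim <- simulate_orientations(n_per = 30, angles_deg = c(0, 60, 120),
                               noise_sd = 0.3, seed = 7)
  fit <- suppressWarnings(mppca(sim$x, K = 3, seed = 8))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  expect_gte(fit$logLik, tr[1])
})

test_that("negating a loading vector changes nothing observable", {
  sim <- simulate_orientations(n_per = 15, angles_deg = c(20, 110),
                               noise_sd = 0.2, seed = 9)
  W <- cbind(c(1, 0.5, 0), c(-0.3, 1, 0.2))
  m1 <- make_mppca_model(W, c(0.05, 0.08), c(0.6, 0.4))
  m2 <- make_mppca_model(W %*% diag(c(-1, 1)), c(0.05, 0.08), c(0.6, 0.4))
  expect_equal(responsibilities(m1, sim$x), responsibilities(m2, sim$x),
               tolerance = 1e-12)
  expect_equal(mppca_loglik(m1, sim$x), mppca_loglik(m2, sim$x),
               tolerance = 1e-12)
})

test_that("marginal likelihood at the origin follows pi / sqrt(det C)", {
  W <- cbind(c(1, 0.4, -0.2), c(0.1, -0.8, 0.5))
  s2 <- c(0.05, 0.12)
  piw <- c(0.3, 0.7)
  m <- make_mppca_model(W, s2, piw)
  q <- responsibilities(m, matrix(0, 1, 3))
  dets <- vapply(1:2, function(k) det(tcrossprod(W[, k]) + diag(s2[k], 3)),
                 numeric(1))
  expected <- piw / sqrt(dets)
  expect_equal(as.vector(q), expected / sum(expected), tolerance = 1e-12)
})

test_that("a far point on one orientation is assigned there with near certainty", {
  W <- cbind(c(1, 0, 0), c(0, 1, 0))
  m <- make_mppca_model(W, c(0.05, 0.05), c(0.5, 0.5))
  q <- responsibilities(m, matrix(c(3, 0, 0), 1))
  expect_gt(q[1, 1], 0.99)
})

test_that("missing-data marginal equals the complete-data likelihood when all variables are observed", {
  sim <- simulate_orientations(n_per = 25, angles_deg = c(10, 100),
                               noise_sd = 0.25, seed = 10)
  fit <- suppressWarnings(mppca(sim$x, K = 2, seed = 11))
  x_masked <- sim$x
  attr(x_masked, "dummy") <- NULL
  expect_equal(responsibilities(fit, x_masked), fit$responsibilities,
               tolerance = 1e-12)
  # pattern-grouped EM evaluation agrees with the per-row Cholesky evaluation
  expect_equal(mppca_loglik(fit, sim$x), fit$logLik, tolerance = 1e-10)
  # likelihood additivity: duplicating one vector adds exactly its term
  l_all <- mppca_loglik(fit, sim$x)
  l_dup <- mppca_loglik(fit, rbind(sim$x, sim$x[1, , drop = FALSE]))
  l_one <- mppca_loglik(fit, sim$x[1, , drop = FALSE])
  expect_equal(l_dup, l_all + l_one, tolerance = 1e-10)
})

test_that("single-point log-likelihood matches a quadrature oracle over the latent", {
  w <- c(0.8, -0.5, 0.3)
  s2 <- 0.07
  m <- make_mppca_model(matrix(w, 3), s2, 1)
  x <- c(0.9, -0.2, 0.5)
  # integrate N(x; w t, s2 I) phi(t) dt over the 1-D latent
  integrand <- function(t) {
    vapply(t, function(ti) {
      exp(sum(stats::dnorm(x, w * ti, sqrt(s2), log = TRUE)) +
            stats::dnorm(ti, log = TRUE))
    }, numeric(1))
  }
  oracle <- log(stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value)
  expect_equal(mppca_loglik(m, matrix(x, 1)), oracle, tolerance = 1e-9)
})

test_that("identical vectors receive identical responsibilities", {
  x <- matrix(rep(c(1, 0.5, -0.2), each = 10), 10)
  fit <- suppressWarnings(mppca(x, K = 2, seed = 12))
  q <- fit$responsibilities
  expect_true(all(abs(sweep(q, 2, q[1, ], "-")) < 1e-10))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
})

test_that("permuting input rows permutes responsibilities identically", {
  sim <- simulate_orientations(n_per = 20, angles_deg = c(0, 75),
                               noise_sd = 0.2, seed = 13)
  fit <- suppressWarnings(mppca(sim$x, K = 2, seed = 14))
  perm <- sample(nrow(sim$x))
  q_perm <- responsibilities(fit, sim$x[perm, ])
  expect_equal(unname(q_perm), unname(fit$responsibilities[perm, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("parameter-recovery: 3 orientations 60 degrees apart are found from 10 restarts", {
  sim <- simulate_orientations(n_per = 50, angles_deg = c(0, 60, 120),
                               noise_sd = 0.1, seed = 1)
  fit <- suppressWarnings(mppca(sim$x, K = 3, seed = 2, nstart = 10))
  # match each true orientation to the closest fitted one
  U_hat <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), "/")
  ang_err <- apply(abs(t(sim$orientations) %*% U_hat), 1,
                   function(r) acos(pmin(1, max(r))) * 180 / pi)
  expect_true(all(ang_err < 5))
  agree <- table(sim$cluster, fit$labels)
  expect_gte(sum(apply(agree, 1, max)) / nrow(sim$x), 0.95)
})

test_that("invalid inputs raise typed errors", {
  x <- matrix(rnorm(9), 3)
  expect_error(mppca(x, K = 3, seed = 1), class = "synclust_parameter_error")
  x_bad <- x
  x_bad[1, ] <- NA
  expect_error(mppca(x_bad, K = 1, seed = 1, min_observed = 1),
               class = "synclust_validation_error")
  fit <- mppca(matrix(rnorm(60), 20), K = 1, seed = 1)
  expect_error(responsibilities(fit, matrix(rnorm(8), 2)),
               class = "synclust_validation_error")
})

test_that("vectors below the observation threshold are scored but not fitted", {
  sim <- simulate_orientations(n_per = 30, angles_deg = c(0, 90),
                               noise_sd = 0.15, seed = 15)
  x <- sim$x
  x[1, 2:3] <- NA   # only 1 observed evoked variable
  fit <- suppressWarnings(mppca(x, K = 2, seed = 16))
  expect_false(1L %in% fit$fitted_rows)
  expect_equal(nrow(fit$responsibilities), nrow(x))
  expect_equal(sum(fit$responsibilities[1, ]), 1, tolerance = 1e-12)
})

test_that("model JSON serialization round-trips", {
  sim <- simulate_orientations(n_per = 20, angles_deg = 45, noise_sd = 0.2,
                               seed = 17)
  fit <- mppca(sim$x, K = 1, seed = 18)
  f <- withr::local_tempfile(fileext = ".json")
  write_mppca_json(fit, f)
  back <- read_mppca_json(f)
  expect_equal(back$W, unname(fit$W), tolerance = 1e-12)
  expect_equal(back$sigma2, fit$sigma2)
  expect_equal(back$pi, fit$pi)
})

test_that("simulate() reproduces the generating second-moment structure", {
  w <- c(1.2, -0.6, 0.4)
  m <- make_mppca_model(matrix(w, 3), 0.04, 1)
  x <- simulate(m, nsim = 4000, seed = 19)
  S <- crossprod(x) / nrow(x)
  expect_equal(S, tcrossprod(w) + diag(0.04, 3), tolerance = 0.1)
})
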
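test_that("the release-model circle lies on the unit sphere and the constraint plane", {
  th <- seq(0, 2 * pi, length.out = 37)
  pts <- release_circle(th)
  expect_true(all(abs(rowSums(pts^2) - 1) < 1e-12))
  # x_A = x_RRP + x_Pv in the (RRP, Pv, A) axis order
  expect_true(all(abs(pts[, "A"] - pts[, "RRP"] - pts[, "Pv"]) < 1e-12))
  # closure: any (a, b, a+b) direction normalizes onto the circle
  for (trial in 1:10) {
    v <- stats::rnorm(2)
    u <- c(v[1], v[2], sum(v))
    u <- u / sqrt(sum(u^2))
    pr <- project_to_release_circle(u)
    expect_equal(unname(pr), unname(u), tolerance = 1e-12)
  }
})

test_that("circle projection matches a dense grid oracle and is idempotent", {
  w <- c(0, 0, 1)   # pure amplitude direction, off the plane
  pr <- project_to_release_circle(w)
  grid <- release_circle(seq(0, 2 * pi, length.out = 2e5))
  d2 <- colSums((t(grid) - w)^2)
  oracle <- grid[which.min(d2), ]
  expect_equal(unname(pr), unname(oracle), tolerance = 1e-4)
  expect_equal(project_to_release_circle(pr), pr, tolerance = 1e-12)
  # a direction already on the circle projects to itself
  on_circle <- c(1, 0, 1) / sqrt(2)
  expect_equal(unname(project_to_release_circle(on_circle)), on_circle,
               tolerance = 1e-12)
})

test_that("cluster unit vectors are sign-fixed unit length with circle projections", {
  W <- cbind(c(-1, -1, 0), c(0, 0.2, 2))
  m <- make_mppca_model(W, c(0.1, 0.1), c(0.5, 0.5))
  uv <- cluster_unit_vectors(m)
  expect_equal(colSums(uv$unit_vectors^2), c(1, 1), tolerance = 1e-12)
  # largest-magnitude coordinate positive
  expect_true(all(apply(uv$unit_vectors, 2, function(u) u[which.max(abs(u))]) > 0))
  expect_true(all(abs(uv$projections[3, ] -
                        uv$projections[1, ] - uv$projections[2, ]) < 1e-12))
  expect_error(cluster_unit_vectors(make_mppca_model(cbind(c(0, 0, 0)), 0.1, 1)),
               class = "synclust_degenerate_error")
})

test_that("weighted orthogonal errors match analytic cases", {
  # points on the 45-degree line have zero error there
  pts <- cbind(c(-2, 1, 3), c(-2, 1, 3))
  expect_equal(weighted_orthogonal_error(pts, c(0.2, 0.5, 1), 45)$error, 0)
  # single point (1, 0): distance to the 45-degree line is 1/sqrt(2)
  e <- weighted_orthogonal_error(cbind(1, 0), 1, 45)
  expect_equal(e$error, 0.5, tolerance = 1e-12)
  expect_equal(e$corrected, 0.5, tolerance = 1e-12)
  # and to the vertical line it is 1
  expect_equal(weighted_orthogonal_error(cbind(1, 0), 1, 90)$error, 1,
               tolerance = 1e-12)
  expect_error(weighted_orthogonal_error(matrix(0, 0, 2), NULL, 0),
               class = "synclust_undefined_error")
})

test_that("orthogonal error is rotation-consistent and equals a rotate-then-residual oracle", {
  set.seed(51)
  pts <- matrix(rnorm(40), 20)
  w <- runif(20)
  for (a in c(0, 45, 90, 135, 17.3)) {
    th <- a * pi / 180
    R <- rbind(c(cos(-th), -sin(-th)), c(sin(-th), cos(-th)))
    rotated <- pts %*% t(R)
    e1 <- weighted_orthogonal_error(pts, w, a)$error
    e0 <- weighted_orthogonal_error(rotated, w, 0)$error
    expect_equal(e1, e0, tolerance = 1e-10)
    # independent oracle: residuals of the y-coordinate after rotation
    expect_equal(e1, sum(w * rotated[, 2]^2), tolerance = 1e-10)
  }
})

test_that("best-orientation selection finds generating angles and breaks ties toward proportionality", {
  set.seed(52)
  t <- rnorm(50, sd = 2)
  anti <- cbind(t, -t) + matrix(rnorm(100, sd = 0.1), 50)
  expect_equal(fit_best_orientation(anti)$best_angle, 135)
  prop <- cbind(t, t) + matrix(rnorm(100, sd = 0.1), 50)
  expect_equal(fit_best_orientation(prop)$best_angle, 45)
  # a single point at the origin ties all four angles -> 45 wins
  expect_equal(fit_best_orientation(cbind(0, 0))$best_angle, 45)
})

test_that("error reduction is 0 for identical fits and 1 for perfectly split clusters", {
  # two orthogonal noise-free clusters
  t <- seq(0.5, 2, length.out = 10)
  pv <- data.frame(
    perturbation_id = sprintf("p%02d", 1:20), gene_symbol = "g",
    x_A = c(t, rep(0, 10)), x_RRP = c(t, t), x_Pv = rep(0, 20),
    x_F = NA_real_)
  class(pv) <- c("synclust_perturbations", "data.frame")
  q <- cbind(rep(c(1, 0), each = 10), rep(c(0, 1), each = 10))
  fits <- orientation_fit(pv, q, projections = list(c("A", "RRP")))
  expect_equal(error_reduction(fits), 1, tolerance = 1e-12)
  # one cluster with all probability 1 reproduces the pooled fit exactly
  fits1 <- orientation_fit(pv, matrix(1, 20, 1),
                           projections = list(c("A", "RRP")))
  expect_equal(error_reduction(fits1), 0, tolerance = 1e-12)
})

test_that("error reduction equals an independent re-implementation on a 10-point fixture", {
  set.seed(53)
  pv <- data.frame(
    perturbation_id = sprintf("p%02d", 1:10), gene_symbol = "g",
    x_A = rnorm(10), x_RRP = rnorm(10), x_Pv = rnorm(10), x_F = NA_real_)
  class(pv) <- c("synclust_perturbations", "data.frame")
  q <- matrix(runif(20), 10)
  q <- q / rowSums(q)
  projections <- list(c("RRP", "Pv"), c("A", "RRP"), c("A", "Pv"))
  fits <- orientation_fit(pv, q, projections = projections)
  # independent: explicit double loop with direct distance formulas
  angle_err <- function(x, y, w, a) {
    th <- a * pi / 180
    sum(w * (y * cos(th) - x * sin(th))^2)
  }
  num <- 0
  den <- 0
  X <- as.data.frame(pv)
  for (pr in projections) {
    xx <- X[[paste0("x_", pr[1])]]
    yy <- X[[paste0("x_", pr[2])]]
    for (k in 1:2) num <- num +
        min(vapply(c(0, 45, 90, 135), function(a) angle_err(xx, yy, q[, k], a),
                   numeric(1)))
    den <- den +
      min(vapply(c(0, 45, 90, 135), function(a) angle_err(xx, yy, rep(1, 10), a),
                 numeric(1)))
  }
  expect_equal(error_reduction(fits), 1 - num / den, tolerance = 1e-12)
})

test_that("permutation p-values hit the documented boundaries", {
  # strongly proportional data: observed error below every permuted error
  set.seed(54)
  t <- rnorm(40, sd = 2)
  x <- cbind(RRP = t, Pv = t + rnorm(40, sd = 0.01), A = NA_real_)
  pn <- permutation_null(x, n_perm = 1000, seed = 55,
                         projections = list(c("RRP", "Pv")))
  expect_equal(pn$p_value, 1 / 1001, tolerance = 1e-12)
  # n_perm = 1 with a less-structured observation gives p = 1 when the
  # single permuted error is smaller
  x2 <- cbind(RRP = c(1, -1, 2, -2), Pv = c(-1, 1, -2, 2), A = NA_real_)
  pn2 <- permutation_null(x2, n_perm = 1, seed = 56,
                          projections = list(c("RRP", "Pv")))
  expect_true(pn2$p_value %in% c(0.5, 1))
  expect_equal(pn2$p_value, (1 + sum(pn2$null <= pn2$observed)) / 2)
})

test_that("within-column permutation preserves each column's missingness pattern and values", {
  x <- cbind(RRP = c(1, 2, NA, 4, 5), Pv = c(NA, 1, 2, 3, NA),
             A = c(1, NA, 3, 4, 5))
  pn <- permutation_null(x, n_perm = 5, seed = 57)
  expect_length(pn$null, 5)
  # statistic definition check: pooled mean squared distance to the 45 line
  e <- 0; n <- 0
  for (pr in list(c("RRP", "Pv"), c("A", "RRP"), c("A", "Pv"))) {
    ok <- stats::complete.cases(x[, pr])
    d <- (x[ok, pr[2]] - x[ok, pr[1]])^2 / 2
    e <- e + sum(d); n <- n + sum(ok)
  }
  expect_equal(pn$observed, e / n, tolerance = 1e-12)
})
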
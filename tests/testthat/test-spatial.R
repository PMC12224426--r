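test_that("exponential SACF evaluates exp(-phi d) with unit diagonal", {
  D <- rbind(c(0, 10), c(10, 0))
  expect_equal(exponential_sacf(D, 0.1)[1, 2], exp(-1))
  expect_equal(diag(exponential_sacf(D, 2)), c(1, 1))
  expect_lt(exponential_sacf(D, 5)[1, 2], exponential_sacf(D, 0.5)[1, 2])
  expect_error(exponential_sacf(D, 0), "positive")
  expect_error(exponential_sacf(D, -1), "positive")
})

test_that("shared-projector OLS residuals equal per-vertex regressions", {
  set.seed(21)
  N <- 12
  X <- cbind(1, rnorm(N), rbinom(N, 1, 0.5))
  Y <- matrix(rnorm(N * 7), N, 7)
  E <- ols_residuals(Y, X)
  for (v in seq_len(ncol(Y)))
    expect_equal(E[, v], unname(resid(lm(Y[, v] ~ X - 1))), tolerance = 1e-10)
  # intercept-only reduces to column centering
  expect_equal(ols_residuals(Y), sweep(Y, 2, colMeans(Y)), tolerance = 1e-12)
  # data in the covariate span leaves nothing
  expect_equal(ols_residuals(X %*% matrix(rnorm(3 * 5), 3, 5), X),
               matrix(0, N, 5), tolerance = 1e-10)
  expect_error(ols_residuals(Y, cbind(X, X[, 2])), "rank deficient")
})

test_that("covariance regression recovers an exactly representable target", {
  geom <- geodesic_distances(make_synthetic_mesh("grid", 6))
  D <- geom$D
  V <- nrow(D)
  M <- 2 * exponential_sacf(D, 0.2) + diag(V)
  E <- chol(M)  # crossprod(E)/V = M / ... scaled below
  E <- sqrt(V) * E  # now crossprod(E)/nrow(E) = M exactly
  fit <- fit_covariance_regression(E, D, phi_grid = c(0.05, 0.1, 0.2, 0.4))
  expect_equal(fit$sigma2, 2, tolerance = 1e-8)
  expect_equal(fit$tau2, 1, tolerance = 1e-8)
  expect_equal(fit$phi, 0.2)
  expect_lt(fit$objective, 1e-16 * sum(M^2))
})

test_that("pure white noise yields a near-zero spatial variance", {
  geom <- geodesic_distances(make_synthetic_mesh("grid", 6))
  set.seed(5)
  E <- matrix(rnorm(400 * 36), 400, 36)
  fit <- fit_covariance_regression(E, geom$D)
  expect_lt(fit$sigma2, 0.08)
  expect_equal(fit$tau2 + fit$sigma2, 1, tolerance = 0.1)
})

test_that("the returned fit minimizes the Frobenius objective over the grid", {
  geom <- geodesic_distances(make_synthetic_mesh("grid", 5))
  D <- geom$D
  set.seed(9)
  E <- matrix(rnorm(60 * 25), 60, 25) %*% chol(exponential_sacf(D, 0.3) + diag(25))
  grid <- c(0.05, 0.15, 0.3, 0.6, 1.2)
  fit <- fit_covariance_regression(E, D, phi_grid = grid)
  M <- crossprod(E) / nrow(E)
  frob <- function(s, t, phi) sum((M - s * exponential_sacf(D, phi) - t * diag(25))^2)
  # reported objective matches a direct evaluation
  expect_equal(fit$objective, frob(fit$sigma2, fit$tau2, fit$phi),
               tolerance = 1e-8)
  expect_equal(fit$objective, min(fit$objective_grid))
  # no random nonnegative parameter choice on the grid beats it
  set.seed(10)
  for (i in 1:25) {
    phi <- sample(grid, 1)
    expect_gte(frob(runif(1, 0, 3), runif(1, 0.01, 3), phi),
               fit$objective - 1e-10)
  }
})

test_that("spatial BLUP matches the dense conditional-expectation oracle", {
  D <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  params <- structure(list(sigma2 = 1.5, tau2 = 0.7, phi = 0.4),
                      class = "cleanv_noise")
  set.seed(3)
  E <- matrix(rnorm(5 * 3), 5, 3)
  bl <- blup_spatial(E, params, D)
  Sigma <- 1.5 * exponential_sacf(D, 0.4) + 0.7 * diag(3)
  for (i in 1:5)
    expect_equal(bl$Bhat[i, ],
                 drop(1.5 * exponential_sacf(D, 0.4) %*% solve(Sigma, E[i, ])),
                 tolerance = 1e-10)
  expect_equal(bl$E, bl$Bhat + bl$Delta, tolerance = 1e-12)
})

test_that("the BLUP is a contraction in the precision norm", {
  geom <- geodesic_distances(make_synthetic_mesh("grid", 5))
  params <- structure(list(sigma2 = 2, tau2 = 0.5, phi = 0.2),
                      class = "cleanv_noise")
  Sigma <- 2 * exponential_sacf(geom$D, 0.2) + 0.5 * diag(25)
  set.seed(8)
  E <- matrix(rnorm(10 * 25), 10, 25)
  bl <- blup_spatial(E, params, geom$D)
  for (i in 1:10) {
    nb <- drop(bl$Bhat[i, ] %*% solve(Sigma, bl$Bhat[i, ]))
    ne <- drop(E[i, ] %*% solve(Sigma, E[i, ]))
    expect_lte(nb, ne + 1e-10)
  }
})

test_that("zero spatial variance passes residuals through unchanged", {
  params <- structure(list(sigma2 = 0, tau2 = 2, phi = 1),
                      class = "cleanv_noise")
  E <- matrix(1:6, 2, 3)
  bl <- blup_spatial(E, params, matrix(0, 3, 3) + 1 - diag(3))
  expect_equal(bl$Bhat, matrix(0, 2, 3))
  expect_equal(bl$Delta, E)
  expect_equal(apply_precision(params, diag(0, 3), c(2, 4, 6)), c(1, 2, 3))
})

test_that("NNGP precision agrees with the exact solve", {
  set.seed(14)
  pts <- matrix(runif(50 * 2, 0, 10), 50, 2)
  D <- as.matrix(dist(pts))
  params <- structure(list(sigma2 = 1, tau2 = 0.3, phi = 0.5),
                      class = "cleanv_noise")
  x <- matrix(rnorm(50 * 3), 50, 3)
  exact <- apply_precision(params, D, x, method = "exact")
  # full conditioning sets reproduce the exact factorization
  ngp <- apply_precision(params, D, x, method = "nngp", m = 49,
                         ord = order(pts[, 1]))
  expect_lt(max(abs(ngp - exact)), 1e-10)
  expect_warning(apply_precision(params, D, x, method = "nngp", m = 50),
                 "falling back")

  # truncated conditioning sets stay within a few percent at V = 200
  pts <- matrix(runif(200 * 2, 0, 14), 200, 2)
  D <- as.matrix(dist(pts))
  Sigma <- params$sigma2 * exponential_sacf(D, params$phi) +
    params$tau2 * diag(200)
  x <- rnorm(200)
  approx_inv <- apply_precision(params, D, x, method = "nngp", m = 30,
                                ord = order(pts[, 1]))
  expect_lt(sqrt(sum((Sigma %*% approx_inv - x)^2)) / sqrt(sum(x^2)), 0.05)
})

test_that("the default decay grid brackets weak and strong autocorrelation", {
  geom <- geodesic_distances(make_synthetic_mesh("grid", 6))
  g <- default_phi_grid(geom$D)
  d <- geom$D[upper.tri(geom$D)]
  dmed <- median(d[d > 0])
  expect_equal(exp(-g[1] * dmed), 0.95, tolerance = 1e-10)
  expect_equal(exp(-g[length(g)] * dmed), 0.01, tolerance = 1e-10)
  expect_equal(length(g), 20L)
})
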
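# Full pipeline orchestration: permutation scheme, FWER threshold,
# localization, and the ablated variants.

#' Deterministic stream of image-index permutations
#'
#' @param N number of images.
#' @param B number of permutations.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return B x N integer matrix, one uniform permutation per row.
#' @export
permutation_stream <- function(N, B, seed) {
  stopifnot(N >= 2L, B >= 1L)
  P <- matrix(0L, B, N)
  .with_seed(seed, {
    for (b in seq_len(B)) P[b, ] <- sample.int(N)
  })
  P
}

#' Permutation null for the score statistics and their neighborhood sums
#'
#' Shuffling images under the null is equivalent to shuffling the whitened
#' residual rows, so no per-permutation refitting of the mean model or the
#' covariance model is needed: each permutation is one quadratic form plus
#' sparse neighborhood sums.
#'
#' @param Delta N x n matrix of (whitened) residuals over active vertices.
#' @param K N x N relatedness matrix.
#' @param nbhd neighborhood index (its active set must match `Delta`'s
#'   columns).
#' @param B number of permutations.
#' @param seed RNG seed.
#' @param perms optional precomputed permutation matrix (overrides B, seed).
#' @return list with `U` (observed statistics), `S_obs`, `S_perm` (stacked
#'   radius-major as in `.nbhd_sums`), and `perms`.
#' @export
permutation_null <- function(Delta, K, nbhd, B = 1000L, seed = 1L,
                             perms = NULL) {
  Delta <- as.matrix(Delta)
  N <- nrow(Delta)
  if (ncol(Delta) != length(nbhd$active))
    stop("`Delta` must have one column per active vertex")
  if (is.null(perms)) perms <- permutation_stream(N, B, seed)
  B <- nrow(perms)
  if (B < 50L)
    warning("fewer than 50 permutations; the threshold quantile is unstable")
  U <- as.numeric(score_statistics(Delta, K))
  Uperm <- matrix(0, ncol(Delta), B)
  for (b in seq_len(B)) {
    Dp <- Delta[perms[b, ], , drop = FALSE]
    Uperm[, b] <- colSums(Dp * (K %*% Dp))
  }
  list(U = U,
       S_obs = drop(.nbhd_sums(matrix(U, ncol = 1L), nbhd)),
       S_perm = .nbhd_sums(Uperm, nbhd),
       perms = perms)
}

#' Permutation FWER threshold
#'
#' The (1 - alpha) empirical quantile of the permuted global maxima, taken as
#' the `ceiling((1 - alpha) * (B + 1))`-th ascending order statistic (capped
#' at B). Counting the observed statistic as the (B + 1)-th exchangeable
#' draw, rejecting when `T > t_alpha` then has probability at most alpha
#' under the null for any B: the rule coincides with the standard permutation
#' p-value test `(1 + #\{T_perm >= T\}) / (B + 1) <= alpha`. The alternative
#' rank `ceiling((1 - alpha) * B)` exceeds alpha by about `1/(B + 1)`, which
#' is material at small B.
#'
#' @param T_perm permuted global maxima.
#' @param alpha target family-wise error rate in (0, 1).
#' @return the threshold t_alpha.
#' @export
fwer_threshold <- function(T_perm, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  B <- length(T_perm)
  if (B < 1L) stop("no permuted maxima")
  if (B < 1 / alpha)
    warning("fewer than 1/alpha permutations; threshold is coarse")
  sort(T_perm)[min(B, ceiling((1 - alpha) * (B + 1)))]
}

#' Run the full spatial-extent variance-component test
#'
#' Orchestrates the pipeline: vertex-wise OLS residuals, covariance
#' regression for the spatial noise model, BLUP whitening, score statistics,
#' cluster enhancement with permutation standardization, adaptive and global
#' maxima, and the permutation FWER threshold with vertex localization.
#'
#' Variants ablate the two modeling components:
#' \describe{
#'   \item{`full`}{spatially adjusted statistics with cluster enhancement.}
#'   \item{`no_spatial`}{non-spatial statistics (no covariance regression or
#'     whitening) with the same cluster enhancement and neighborhoods.}
#'   \item{`no_enhance`}{spatially adjusted statistics, radius 0 only.}
#'   \item{`massive`}{non-spatial statistics, radius 0 only (the
#'     massive-univariate / MEGHA-style analysis).}
#' }
#' All variants share the identical permutation machinery, and with the same
#' seed the same permutations.
#'
#' @param Y N x V data matrix, one row per image.
#' @param X N x p nuisance covariates; `NULL` means intercept only.
#' @param geometry a `cleanv_surface`, or a V x V distance matrix.
#' @param K N x N relatedness matrix (see [kinship_test_retest()],
#'   [kinship_twins()], [load_custom_kinship()]).
#' @param radii neighborhood radii in mm (default 0:20).
#' @param B number of permutations (default 5000).
#' @param alpha FWER level (default 0.05).
#' @param seed RNG seed for the permutation stream.
#' @param variant one of `"full"`, `"no_spatial"`, `"no_enhance"`,
#'   `"massive"`.
#' @param phi_grid optional decay-rate grid for the covariance regression.
#' @param nngp_m NNGP neighbor count for large meshes.
#' @param exact_threshold vertex count above which the precision solve
#'   switches to NNGP.
#' @param moments moment convention for [standardize_sums()]; the default
#'   `"pooled"` keeps the observed and permuted maxima exactly exchangeable
#'   at any B.
#' @param nbhd optional precomputed neighborhood index (reused across calls
#'   on the same mesh, e.g., in simulation studies).
#' @return an object of class `cleanv_result`; see Details.
#' @details The result contains per-vertex `U`, `Tv`, `argmax_radius`
#'   (NA at masked vertices), the observed global maximum `T` and its vertex,
#'   permuted maxima `T_perm`, threshold `t_alpha`, the significant vertex
#'   set `{v : Tv(v) > t_alpha}`, the permutation p-value
#'   `(1 + #\{T_perm >= T\}) / (B + 1)`, the fitted noise parameters (when the
#'   variant is spatial), and a config echo.
#' @export
run_cleanv <- function(Y, X = NULL, geometry, K, radii = 0:20, B = 5000L,
                       alpha = 0.05, seed = 1L,
                       variant = c("full", "no_spatial", "no_enhance",
                                   "massive"),
                       phi_grid = NULL, nngp_m = 50L, exact_threshold = 2000L,
                       moments = c("pooled", "permuted"), nbhd = NULL) {
  moments <- match.arg(moments)
  variant <- match.arg(variant)
  Y <- as.matrix(Y)
  K <- as.matrix(K)
  N <- nrow(Y)
  if (nrow(K) != N || ncol(K) != N)
    stop("`K` must be ", N, " x ", N, " to match the rows of `Y`")
  if (!is.null(X) && nrow(as.matrix(X)) != N)
    stop("`X` must have one row per image")
  if (is.matrix(geometry) && !inherits(geometry, "cleanv_surface"))
    geometry <- surface_from_distances(geometry)
  stopifnot(inherits(geometry, "cleanv_surface"))
  if (ncol(Y) != nrow(geometry$coords))
    stop("`Y` has ", ncol(Y), " columns but the geometry has ",
         nrow(geometry$coords), " vertices")
  if (variant %in% c("no_enhance", "massive")) radii <- 0
  geometry <- geodesic_distances(geometry)
  if (is.null(nbhd)) {
    nbhd <- build_neighborhoods(geometry, radii)
  } else {
    stopifnot(inherits(nbhd, "cleanv_nbhd"))
    nbhd <- .subset_nbhd(nbhd, radii)
  }
  active <- nbhd$active
  n <- length(active)

  E <- ols_residuals(Y, X)
  Ea <- E[, active, drop = FALSE]
  spatial <- variant %in% c("full", "no_enhance")
  params <- NULL
  if (spatial) {
    Dact <- geometry$D[active, active, drop = FALSE]
    params <- fit_covariance_regression(Ea, Dact, phi_grid = phi_grid)
    Delta <- blup_spatial(Ea, params, Dact, m = nngp_m,
                          exact_threshold = exact_threshold,
                          ord = order(geometry$coords[active, 1L]))$Delta
  } else {
    Delta <- Ea
  }

  pn <- permutation_null(Delta, K, nbhd, B = B, seed = seed)
  st <- standardize_sums(pn$S_obs, pn$S_perm, moments = moments)
  R <- length(nbhd$radii)
  TrM <- matrix(st$T_obs, n, R)          # columns are radii
  am <- adaptive_max(t(TrM), nbhd$radii)
  T_perm <- apply(st$T_perm, 2L, max)
  Tv_full <- rep(NA_real_, nbhd$V); Tv_full[active] <- am$Tv
  Tg <- global_max(Tv_full, NULL)
  t_alpha <- fwer_threshold(T_perm, alpha)
  U_full <- rep(NA_real_, nbhd$V); U_full[active] <- pn$U
  rad_full <- rep(NA_real_, nbhd$V); rad_full[active] <- am$radius
  TrFull <- matrix(NA_real_, R, nbhd$V,
                   dimnames = list(paste0("r", nbhd$radii), NULL))
  TrFull[, active] <- t(TrM)

  structure(list(
    U = U_full, Tr = TrFull, Tv = Tv_full, argmax_radius = rad_full,
    T = as.numeric(Tg), T_vertex = attr(Tg, "vertex"),
    T_perm = T_perm, t_alpha = t_alpha,
    significant = active[am$Tv > t_alpha],
    p_global = (1 + sum(T_perm >= as.numeric(Tg))) / (length(T_perm) + 1),
    params = params,
    config = list(radii = nbhd$radii, B = length(T_perm), alpha = alpha,
                  seed = seed, variant = variant, moments = moments, N = N,
                  V = nbhd$V, n_active = n,
                  nngp_m = nngp_m, exact_threshold = exact_threshold)),
    class = "cleanv_result")
}

#' @export
print.cleanv_result <- function(x, ...) {
  cfg <- x$config
  cat("Spatial-extent variance-component test (variant: ", cfg$variant,
      ")\n", sep = "")
  cat(sprintf("  N = %d images, V = %d vertices (%d active), B = %d permutations\n",
              cfg$N, cfg$V, cfg$n_active, cfg$B))
  if (!is.null(x$params))
    cat(sprintf("  noise fit: sigma2 = %.4g, tau2 = %.4g, phi = %.4g\n",
                x$params$sigma2, x$params$tau2, x$params$phi))
  cat(sprintf("  T = %.4f at vertex %d; t_%.2g = %.4f; p = %.4g\n",
              x$T, x$T_vertex, cfg$alpha, x$t_alpha, x$p_global))
  cat(sprintf("  %d significant vertices at %.2g FWER\n",
              length(x$significant), cfg$alpha))
  invisible(x)
}

#' Method-of-moments effect sizes per vertex
#'
#' Descriptive per-vertex estimates of the variance ratio
#' `theta2(v) / (theta2(v) + tau2(v))` (test-retest ICC, or narrow-sense
#' heritability for twin kernels) from the non-spatial vertex-level model:
#' `theta2` is the least-squares projection of the residual cross-products
#' onto the off-diagonal kernel pattern,
#' `theta2(v) = sum_{i != j} K_ij e_i(v) e_j(v) / sum_{i != j} K_ij^2`,
#' and the total variance is the mean squared residual. The ratio is clipped
#' to [0, 1]. These estimates are descriptive companions to the test, not
#' part of it.
#'
#' @inheritParams run_cleanv
#' @return list with per-vertex `theta2`, `tau2`, and `ratio`.
#' @export
estimate_effect_size <- function(Y, X = NULL, K) {
  Y <- as.matrix(Y)
  K <- as.matrix(K)
  K0 <- K; diag(K0) <- 0
  den <- sum(K0^2)
  if (den == 0)
    stop("design has no related image pairs; the effect size is undefined")
  E <- ols_residuals(Y, X)
  theta2 <- colSums(E * (K0 %*% E)) / den
  s2 <- colMeans(E^2)
  ratio <- ifelse(s2 > 0, pmin(pmax(theta2 / s2, 0), 1), 0)
  list(theta2 = theta2, tau2 = pmax(s2 - theta2, 0), ratio = ratio)
}
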
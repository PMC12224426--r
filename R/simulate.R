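# Generative simulator: y(v) = X beta(v) + r(v) + b + delta with
# r(v) ~ N(0, theta2(v) K), b_i ~ N(0, sigma2 Phi(phi, D)),
# delta_i ~ N(0, tau2 I). Provides built-in meshes and null/signal scenarios
# for calibration, power, and reproducibility studies.

#' Built-in synthetic surface meshes
#'
#' `"grid"` builds a planar triangulated lattice with unit (1 mm) spacing and
#' `size^2` vertices; `"sphere"` builds an icosphere with `size` subdivision
#' levels (size 0 is the icosahedron, V = 12) scaled to the given radius.
#' Both carry a full (all-inclusive) mask.
#'
#' @param kind `"grid"` or `"sphere"`.
#' @param size vertices per side (grid) or subdivision level (sphere).
#' @param radius sphere radius in mm; 50 mm is a hemisphere-like scale.
#' @return a `cleanv_surface` (distances not yet computed).
#' @export
make_synthetic_mesh <- function(kind = c("grid", "sphere"), size = 10L,
                                radius = 50) {
  kind <- match.arg(kind)
  if (kind == "grid") {
    n <- as.integer(size)
    if (n < 1L) stop("grid size must be >= 1")
    g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
    coords <- cbind(g$x, g$y, 0)
    faces <- NULL
    if (n >= 2L) {
      id <- function(i, j) (j - 1L) * n + i
      i <- rep(seq_len(n - 1L), n - 1L)
      j <- rep(seq_len(n - 1L), each = n - 1L)
      v00 <- id(i, j); v10 <- id(i + 1L, j)
      v01 <- id(i, j + 1L); v11 <- id(i + 1L, j + 1L)
      faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
    }
    surface_geometry(coords, faces)
  } else {
    if (size < 0L) stop("subdivision level must be >= 0")
    ms <- .icosahedron()
    for (s in seq_len(size)) ms <- .subdivide(ms)
    len <- sqrt(rowSums(ms$verts^2))
    surface_geometry(ms$verts / len * radius, ms$faces)
  }
}

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(verts = verts, faces = faces)
}

.subdivide <- function(ms) {
  verts <- ms$verts
  midpoint <- new.env(parent = emptyenv())
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    idx <- midpoint[[key]]
    if (is.null(idx)) {
      verts <<- rbind(verts, (ms$verts[a, ] + ms$verts[b, ]) / 2)
      idx <- nrow(verts)
      midpoint[[key]] <- idx
    }
    idx
  }
  faces <- matrix(0L, 4L * nrow(ms$faces), 3L)
  for (f in seq_len(nrow(ms$faces))) {
    v <- ms$faces[f, ]
    ab <- get_mid(v[1L], v[2L]); bc <- get_mid(v[2L], v[3L])
    ca <- get_mid(v[3L], v[1L])
    faces[4L * f - 3L:0L, ] <- rbind(c(v[1L], ab, ca), c(v[2L], bc, ab),
                                     c(v[3L], ca, bc), c(ab, bc, ca))
  }
  list(verts = verts, faces = faces)
}

#' Simulation scenario for reliability and heritability designs
#'
#' Packages a mesh, a study design, and generative-model parameters into a
#' scenario object. The null mode generates pseudo test-retest pairs: the
#' relatedness matrix handed to the analysis labels images as pairs, but the
#' generating truth has no between-image dependence, mirroring null designs
#' built from independent images. Signal modes place `theta2` on a contiguous
#' geodesic disc covering roughly `signal_frac` of the vertices (cluster
#' enhancement is designed for spatially contiguous signal); `prop_true`
#' controls the fraction of pairs that truly carry the dependence, the rest
#' being pseudo-pairs, which moves the signal-to-noise ratio the way varying
#' the number of true pairs does.
#'
#' @param mode `"null"`, `"test_retest"`, or `"twin"`.
#' @param n_units number of pairs; defaults to 20 (test-retest and null,
#'   N = 40 images) or 60 (twin, N = 120 images).
#' @param prop_true fraction of pairs generated as truly related (ignored in
#'   null mode).
#' @param theta2 between-image variance on the signal region; the implied
#'   effect size is `theta2 / (theta2 + tau2)`.
#' @param sigma2,tau2 spatial and white-noise variances of the within-image
#'   residual.
#' @param phi SACF decay rate; defaults so the correlation at the median
#'   pairwise geodesic distance is 0.3.
#' @param mesh optional `cleanv_surface`; default a planar grid.
#' @param mesh_kind,mesh_size passed to [make_synthetic_mesh()] when `mesh`
#'   is absent.
#' @param signal_frac fraction of vertices in the signal disc.
#' @param mz_frac fraction of MZ pairs in twin mode.
#' @return an object of class `cleanv_scenario`.
#' @export
simulation_scenario <- function(mode = c("test_retest", "twin", "null"),
                                n_units = NULL, prop_true = 1, theta2 = 1,
                                sigma2 = 1, tau2 = 1, phi = NULL,
                                mesh = NULL, mesh_kind = "grid",
                                mesh_size = 12L, signal_frac = 0.1,
                                mz_frac = 0.6) {
  mode <- match.arg(mode)
  if (!is.null(prop_true) && (prop_true < 0 || prop_true > 1))
    stop("`prop_true` must be in [0, 1]")
  if (theta2 < 0 || sigma2 < 0 || tau2 <= 0)
    stop("need theta2 >= 0, sigma2 >= 0, tau2 > 0")
  if (is.null(n_units)) n_units <- if (mode == "twin") 60L else 20L
  if (mode == "null") prop_true <- 0
  if (is.null(mesh)) mesh <- make_synthetic_mesh(mesh_kind, mesh_size)
  mesh <- geodesic_distances(mesh)
  active <- which(mesh$mask)
  if (is.null(phi)) {
    d <- mesh$D[active, active]
    d <- d[upper.tri(d)]
    phi <- -log(0.3) / stats::median(d[is.finite(d) & d > 0])
  }
  N <- 2L * n_units
  unit <- rep(seq_len(n_units), each = 2L)
  if (mode == "twin") {
    n_mz <- round(mz_frac * n_units)
    zy <- rep(c("MZ", "DZ"), times = c(n_mz, n_units - n_mz))
    K_design <- kinship_twins(paste0("p", unit), zy[unit])
  } else {
    K_design <- kinship_test_retest(paste0("s", unit))
  }
  n_true <- round(prop_true * n_units)
  K_truth <- diag(N)
  if (n_true > 0) {
    in_true <- unit <= n_true
    K_truth[in_true, in_true] <- K_design[in_true, in_true]
  }
  V <- nrow(mesh$coords)
  theta2_map <- numeric(V)
  if (theta2 > 0 && n_true > 0 && mode != "null") {
    centroid <- colMeans(mesh$coords[active, , drop = FALSE])
    center <- active[which.min(colSums((t(mesh$coords[active, , drop = FALSE])
                                        - centroid)^2))]
    k <- max(1L, ceiling(signal_frac * length(active)))
    disc <- active[order(mesh$D[center, active])[seq_len(k)]]
    theta2_map[disc] <- theta2
  }
  structure(list(mode = mode, n_units = n_units, n_images = N,
                 prop_true = prop_true, theta2 = theta2,
                 theta2_map = theta2_map, sigma2 = sigma2, tau2 = tau2,
                 phi = phi, geometry = mesh, K_design = K_design,
                 K_truth = K_truth, X = matrix(1, N, 1L), beta = NULL),
            class = "cleanv_scenario")
}

#' @export
print.cleanv_scenario <- function(x, ...) {
  cat("Simulation scenario (", x$mode, "): ", x$n_images, " images, ",
      nrow(x$geometry$coords), " vertices\n", sep = "")
  cat(sprintf("  theta2 = %g on %d vertices; sigma2 = %g, tau2 = %g, phi = %.4g\n",
              x$theta2, sum(x$theta2_map > 0), x$sigma2, x$tau2, x$phi))
  invisible(x)
}

#' Draw a dataset from a simulation scenario
#'
#' Samples the three variance components independently: the between-image
#' effect `r(v) ~ N(0, theta2(v) * K_truth)` independently across vertices,
#' the within-image spatial noise `b_i ~ N(0, sigma2 * Phi(phi, D))`, and
#' white noise `delta_i ~ N(0, tau2 * I)`, then assembles
#' `Y = X beta + r + b + delta`. Deterministic given the seed.
#'
#' @param scenario a `cleanv_scenario`.
#' @param seed RNG seed.
#' @return list with `Y` (N x V), `X`, `K` (the design relatedness matrix
#'   handed to analysis), and `geometry`.
#' @export
simulate_dataset <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "cleanv_scenario"))
  geom <- scenario$geometry
  V <- nrow(geom$coords)
  N <- scenario$n_images
  .check_psd(scenario$K_truth)
  Y <- .with_seed(seed, {
    Ym <- matrix(stats::rnorm(N * V, sd = sqrt(scenario$tau2)), N, V)
    if (scenario$sigma2 > 0) {
      Phi <- exp(-scenario$phi * geom$D)
      # graph geodesics are not exactly Euclidean, so guard the factorization
      Rchol <- tryCatch(chol(Phi), error = function(e) {
        diag(Phi) <- diag(Phi) + 1e-8
        chol(Phi)
      })
      Ym <- Ym + sqrt(scenario$sigma2) *
        (matrix(stats::rnorm(N * V), N, V) %*% Rchol)
    }
    if (any(scenario$theta2_map > 0)) {
      ek <- eigen(scenario$K_truth, symmetric = TRUE)
      L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), N)
      Rm <- L %*% matrix(stats::rnorm(N * V), N, V)
      Ym <- Ym + sweep(Rm, 2L, sqrt(scenario$theta2_map), "*")
    }
    if (!is.null(scenario$beta)) Ym <- Ym + scenario$X %*% scenario$beta
    Ym
  })
  list(Y = Y, X = scenario$X, K = scenario$K_design, geometry = geom)
}
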
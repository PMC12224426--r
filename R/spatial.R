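# Within-image spatial noise model: Sigma = sigma2 * Phi(phi, D) + tau2 * I,
# with exponential SACF Phi(phi, D) = exp(-phi * D).

#' Exponential spatial autocorrelation function
#'
#' Entrywise `exp(-phi * D)`: unit diagonal, symmetric, entries in (0, 1]
#' (0 across disconnected components where distances are infinite).
#'
#' @param D geodesic distance matrix (mm).
#' @param phi decay rate (> 0, in 1/mm).
#' @return the correlation matrix Phi(phi, D).
#' @export
exponential_sacf <- function(D, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi <= 0)
    stop("`phi` must be a positive scalar")
  exp(-phi * as.matrix(D))
}

#' Vertex-wise ordinary least squares residuals
#'
#' Removes the nuisance mean X beta(v) from every vertex at once through one
#' shared projector (a single QR of X), which is identical to running a
#' separate least-squares fit per vertex.
#'
#' @param Y N x V data matrix, one row per image.
#' @param X N x p nuisance covariate matrix; `NULL` means intercept only.
#' @return N x V matrix of residuals.
#' @export
ols_residuals <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (is.null(X)) X <- matrix(1, N, 1L)
  X <- as.matrix(X)
  if (nrow(X) != N)
    stop("`X` has ", nrow(X), " rows but `Y` has ", N)
  if (N <= ncol(X)) stop("need more images than covariates")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    lab <- if (is.null(colnames(X))) paste0("column ", drop_idx)
           else colnames(X)[drop_idx]
    stop("covariate matrix is rank deficient; redundant: ",
         paste(lab, collapse = ", "))
  }
  qr.resid(qx, Y)
}

#' Default decay-rate search grid
#'
#' Log-spaced `phi` values chosen so the exponential SACF at the median
#' pairwise distance spans 0.95 (near-flat autocorrelation) down to 0.01
#' (essentially local), adapting the grid to the mesh scale.
#'
#' @param D distance matrix.
#' @param n grid size.
#' @return numeric vector of candidate decay rates.
#' @export
default_phi_grid <- function(D, n = 20L) {
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) stop("no positive finite distances in D")
  dmed <- stats::median(d)
  exp(seq(log(-log(0.95) / dmed), log(-log(0.01) / dmed), length.out = n))
}

#' Covariance regression for the spatial noise parameters
#'
#' Minimizes the Frobenius objective
#' `sum_i || e_i e_i' - sigma2 * Phi(phi, D) - tau2 * I ||_F^2`
#' over (sigma2, tau2, phi). The objective depends on the residuals only
#' through the mean outer product `M = crossprod(E) / N`, so that matrix is
#' fitted directly. For each candidate `phi` the (sigma2, tau2) profile is a
#' two-parameter least-squares problem solved in closed form through the Gram
#' system of Frobenius inner products, with nonnegativity enforced by an
#' active-set step; the grid value with the lowest objective wins. `tau2` is
#' floored at a small positive multiple of the residual variance so the
#' fitted covariance stays positive definite.
#'
#' @param E N x V matrix of null-model residuals (rows are images).
#' @param D V x V geodesic distance matrix.
#' @param phi_grid candidate decay rates; defaults to [default_phi_grid()].
#' @param tau2_floor lower bound for `tau2`; default `1e-8 * mean(E^2)`.
#' @return an object of class `cleanv_noise` with elements `sigma2`, `tau2`,
#'   `phi`, `phi_grid`, `objective` (at the optimum, on the mean-outer-product
#'   scale), and `objective_grid` (per grid value).
#' @export
fit_covariance_regression <- function(E, D, phi_grid = NULL,
                                      tau2_floor = NULL) {
  E <- as.matrix(E)
  N <- nrow(E); V <- ncol(E)
  if (N < 2L) stop("need at least two images")
  if (ncol(D) != V) stop("`D` must be ", V, " x ", V)
  if (all(E == 0)) stop("residuals are identically zero; no noise to model")
  if (is.null(phi_grid)) phi_grid <- default_phi_grid(D)
  phi_grid <- sort(unique(as.numeric(phi_grid)))
  if (any(phi_grid <= 0)) stop("phi grid values must be positive")
  if (is.null(tau2_floor)) tau2_floor <- 1e-8 * mean(E^2)

  M <- crossprod(E) / N
  trM <- sum(diag(M))
  normM2 <- sum(M * M)
  obj_grid <- numeric(length(phi_grid))
  fit <- list(objective = Inf)
  for (k in seq_along(phi_grid)) {
    Phi <- exp(-phi_grid[k] * D)
    a <- sum(Phi * Phi)          # <Phi, Phi>_F
    cP <- sum(M * Phi)           # <M, Phi>_F
    # <Phi, I>_F = trace(Phi) = V and <I, I>_F = V
    obj <- function(s, t)
      normM2 + s^2 * a + 2 * s * t * V + t^2 * V - 2 * (s * cP + t * trM)
    cand <- list(
      c(0, max(trM / V, tau2_floor)),
      c(max((cP - tau2_floor * V) / a, 0), tau2_floor))
    det2 <- V * (a - V)
    if (det2 > .Machine$double.eps * V * a) {
      s_u <- (cP - trM) / (a - V)
      t_u <- (a * trM - V * cP) / det2
      if (s_u >= 0 && t_u >= tau2_floor) cand <- c(list(c(s_u, t_u)), cand)
    }
    vals <- vapply(cand, function(p) obj(p[1L], p[2L]), numeric(1L))
    best <- cand[[which.min(vals)]]
    obj_grid[k] <- min(vals)
    if (obj_grid[k] < fit$objective)
      fit <- list(sigma2 = best[1L], tau2 = best[2L], phi = phi_grid[k],
                  objective = obj_grid[k])
  }
  structure(list(sigma2 = fit$sigma2, tau2 = fit$tau2, phi = fit$phi,
                 phi_grid = phi_grid, objective = fit$objective,
                 objective_grid = obj_grid),
            class = "cleanv_noise")
}

#' @export
print.cleanv_noise <- function(x, ...) {
  cat(sprintf(
    "Spatial noise fit: sigma2 = %.4g, tau2 = %.4g, phi = %.4g (1/mm)\n",
    x$sigma2, x$tau2, x$phi))
  invisible(x)
}

#' Spatial BLUP and whitened residuals
#'
#' Under the fitted null model the conditional expectation of the spatial
#' component of image i is `bhat_i = sigma2 * Phi %*% solve(Sigma, e_i)`,
#' computed per image independently (the residual images are i.i.d. under
#' the model). The whitened residual `delta_i = e_i - bhat_i` feeds the
#' spatially adjusted score statistic.
#'
#' @param E N x V residual matrix.
#' @param params a `cleanv_noise` fit.
#' @param D distance matrix matching `E`'s columns.
#' @param method `"auto"` (exact below `exact_threshold` vertices, NNGP
#'   above), `"exact"`, or `"nngp"`.
#' @param m NNGP neighbor count.
#' @param exact_threshold vertex count above which `"auto"` switches to NNGP.
#' @param ord optional vertex ordering for the NNGP factorization; defaults
#'   to the natural order (callers with coordinates pass an ordering by the
#'   first spatial coordinate).
#' @return list with `E`, `Bhat` (spatial components), and `Delta = E - Bhat`.
#' @export
blup_spatial <- function(E, params, D, method = c("auto", "exact", "nngp"),
                         m = 50L, exact_threshold = 2000L, ord = NULL) {
  method <- match.arg(method)
  E <- as.matrix(E)
  V <- ncol(E)
  stopifnot(inherits(params, "cleanv_noise"))
  if (params$sigma2 <= 0) {
    Z <- matrix(0, nrow(E), V)
    return(list(E = E, Bhat = Z, Delta = E))
  }
  SinvEt <- apply_precision(params, D, t(E), method = method, m = m,
                            exact_threshold = exact_threshold, ord = ord)
  Phi <- exp(-params$phi * D)
  Bhat <- t(params$sigma2 * (Phi %*% SinvEt))
  list(E = E, Bhat = Bhat, Delta = E - Bhat)
}

#' Apply the inverse of the fitted spatial covariance
#'
#' Returns `solve(Sigma, x)` for `Sigma = sigma2 * Phi(phi, D) + tau2 * I`,
#' either by dense Cholesky ("exact") or by a Vecchia-type nearest-neighbor
#' Gaussian process factorization ("nngp") in which each vertex conditions on
#' its `m` nearest previously-ordered vertices, giving a sparse approximate
#' precision usable at large V.
#'
#' @inheritParams blup_spatial
#' @param x numeric vector of length V or V x k matrix of column vectors.
#' @return object shaped like `x` holding (approximately) `Sigma^{-1} x`.
#' @export
apply_precision <- function(params, D, x, method = c("auto", "exact", "nngp"),
                            m = 50L, exact_threshold = 2000L, ord = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(params, "cleanv_noise"))
  was_vec <- is.null(dim(x))
  x <- as.matrix(x)
  V <- nrow(x)
  if (ncol(D) != V) stop("`D` must be ", V, " x ", V)
  if (params$tau2 <= 0) stop("tau2 must be positive")
  if (params$sigma2 <= 0) {
    out <- x / params$tau2
    return(if (was_vec) drop(out) else out)
  }
  if (method == "auto") method <- if (V <= exact_threshold) "exact" else "nngp"
  if (method == "nngp" && m >= V) {
    warning("NNGP neighbor count m >= V; falling back to the exact solve")
    method <- "exact"
  }
  if (method == "exact") {
    S <- params$sigma2 * exp(-params$phi * D)
    diag(S) <- diag(S) + params$tau2
    cs <- tryCatch(chol(S),
                   error = function(e) stop("fitted covariance is not ",
                                            "positive definite: ",
                                            conditionMessage(e)))
    out <- backsolve(cs, backsolve(cs, x, transpose = TRUE))
  } else {
    if (is.null(ord)) ord <- seq_len(V)
    fac <- .nngp_factors(params, D, m = m, ord = ord)
    xo <- x[ord, , drop = FALSE]
    u <- as.matrix(xo - fac$A %*% xo) / fac$d
    ro <- as.matrix(u - Matrix::crossprod(fac$A, u))
    out <- matrix(0, V, ncol(x))
    out[ord, ] <- ro
  }
  if (was_vec) drop(out) else out
}

# Vecchia factorization Sigma^{-1} ~ (I - A)' diag(1/d) (I - A) in the given
# ordering; A is strictly lower triangular with at most m nonzeros per row.
.nngp_factors <- function(params, D, m, ord) {
  V <- nrow(D)
  s2 <- params$sigma2; t2 <- params$tau2; phi <- params$phi
  cov_block <- function(I, J) {
    S <- s2 * exp(-phi * D[I, J, drop = FALSE])
    S + t2 * outer(I, J, "==")
  }
  d <- numeric(V)
  d[1L] <- s2 + t2
  ii <- jj <- vector("list", V)
  aa <- vector("list", V)
  for (k in 2:V) {
    v <- ord[k]
    prev <- ord[seq_len(k - 1L)]
    nb <- prev[order(D[v, prev])][seq_len(min(m, k - 1L))]
    Cnn <- cov_block(nb, nb)
    cvn <- drop(cov_block(nb, v))
    a <- solve(Cnn, cvn)
    d[k] <- s2 + t2 - sum(cvn * a)
    ii[[k]] <- rep.int(k, length(nb))
    jj[[k]] <- match(nb, ord)
    aa[[k]] <- a
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(aa),
                            dims = c(V, V))
  list(A = A, d = d)
}
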
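# Vertex-wise variance-component score statistics (SKAT-type quadratic forms)
# and the analytic mixture-chi-square null used for validation.

#' Variance-component score statistics
#'
#' Computes `U(v) = d(v)' K d(v)` for every vertex, where `d(v)` is the v-th
#' column of the residual matrix: whitened residuals for the spatially
#' adjusted statistic, plain OLS residuals for the non-spatial one. The
#' statistic is the (unscaled) score test of a zero variance component with
#' kernel K; all downstream use goes through permutation standardization,
#' which is scale invariant.
#'
#' @param resid N x V matrix of per-image residuals (whitened or not).
#' @param K N x N relatedness matrix.
#' @param variant label stored on the result (`"spatial"` or `"nonspatial"`).
#' @return numeric vector of length V with attribute `variant`.
#' @export
score_statistics <- function(resid, K, variant = c("spatial", "nonspatial")) {
  variant <- match.arg(variant)
  resid <- as.matrix(resid)
  K <- as.matrix(K)
  if (nrow(resid) != nrow(K))
    stop("residuals have ", nrow(resid), " rows but K is ", nrow(K), " x ",
         ncol(K))
  U <- colSums(resid * (K %*% resid))
  attr(U, "variant") <- variant
  U
}

#' Mixture-chi-square null weights for the score statistic
#'
#' Under H0 with Gaussian errors, `U = e' K e` with `e` the residual of a
#' white-noise vector is distributed as `sum_j lambda_j * chisq_1`, where the
#' lambda_j are the nonzero eigenvalues of `Q' K Q` and `Q` is a rank-revealing
#' factor of the residual covariance `P = tau2 * (I - X (X'X)^{-1} X')`
#' (`P = Q Q'`, rank N - p). Used for distributional validation only; the
#' inference path is permutation-based.
#'
#' @param X N x p covariate matrix (full rank).
#' @param K N x N relatedness matrix.
#' @param tau2 white-noise variance under the null.
#' @return eigenvalues in decreasing order (length N - p).
#' @export
null_mixture_weights <- function(X, K, tau2 = 1) {
  X <- as.matrix(X)
  K <- as.matrix(K)
  N <- nrow(X)
  if (nrow(K) != N) stop("K must be ", N, " x ", N)
  if (tau2 <= 0) stop("tau2 must be positive")
  P <- tau2 * (diag(N) - X %*% solve(crossprod(X), t(X)))
  ep <- eigen((P + t(P)) / 2, symmetric = TRUE)
  keep <- ep$values > max(ep$values) * 1e-10
  Q <- ep$vectors[, keep, drop = FALSE] %*% diag(sqrt(ep$values[keep]),
                                                 sum(keep))
  lam <- eigen(crossprod(Q, K %*% Q), symmetric = TRUE,
               only.values = TRUE)$values
  lam[abs(lam) < max(abs(lam), 1) * 1e-12] <- 0
  sort(lam, decreasing = TRUE)
}

#' Sample from a mixture of chi-square(1) variables
#'
#' Draws from `sum_j lambda_j * chisq_1`, the null law of the score statistic.
#'
#' @param n number of draws.
#' @param lambda mixture weights (eigenvalues).
#' @return numeric vector of length `n`.
#' @export
rmixture_chisq <- function(n, lambda) {
  lambda <- lambda[lambda != 0]
  if (!length(lambda)) return(numeric(n))
  colSums(lambda * matrix(stats::rchisq(n * length(lambda), df = 1),
                          nrow = length(lambda)))
}

#' Moment-matched upper tail probability of a chi-square mixture
#'
#' Satterthwaite-style gamma approximation matching the first two moments of
#' `sum_j lambda_j * chisq_1`; a quick validation utility, not the inference
#' path.
#'
#' @param q quantile(s).
#' @param lambda mixture weights.
#' @return upper-tail probabilities `P(U > q)`.
#' @export
pmixture_chisq <- function(q, lambda) {
  mu <- sum(lambda)
  v <- 2 * sum(lambda^2)
  if (v <= 0) return(as.numeric(q < mu))
  shape <- mu^2 / v
  rate <- mu / v
  stats::pgamma(q, shape = shape, rate = rate, lower.tail = FALSE)
}
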
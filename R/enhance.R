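# Cluster enhancement: neighborhood sums, permutation standardization,
# adaptive maxima over radii, and the global maximum.

# Internal workhorse: Umat is n_active x m (columns are observed/permuted
# statistics over active vertices). Returns a (n_active * n_radii) x m matrix
# stacked radius-major (rows 1..n_active belong to the first radius).
.nbhd_sums <- function(Umat, nbhd) {
  do.call(rbind, lapply(nbhd$indicator, function(A) as.matrix(A %*% Umat)))
}

#' Neighborhood sums of vertex statistics
#'
#' `S_r(v) = sum of U(v*) over v* in N_r(v)` for every radius in the index.
#'
#' @param U numeric vector of vertex statistics, length V (full mesh).
#' @param nbhd a `cleanv_nbhd` neighborhood index.
#' @return matrix with one row per radius and one column per vertex; masked
#'   vertices are `NA`.
#' @export
neighborhood_sums <- function(U, nbhd) {
  stopifnot(inherits(nbhd, "cleanv_nbhd"))
  U <- as.numeric(U)
  if (length(U) != nbhd$V)
    stop("`U` must have one entry per mesh vertex (", nbhd$V, ")")
  if (any(!is.finite(U[nbhd$active]))) stop("`U` must be finite")
  Sa <- .nbhd_sums(matrix(U[nbhd$active], ncol = 1L), nbhd)
  S <- matrix(NA_real_, length(nbhd$radii), nbhd$V,
              dimnames = list(paste0("r", nbhd$radii), NULL))
  for (k in seq_along(nbhd$radii))
    S[k, nbhd$active] <- Sa[(k - 1L) * length(nbhd$active) +
                              seq_along(nbhd$active), 1L]
  S
}

#' Permutation standardization of neighborhood sums
#'
#' Standardizes each (radius, vertex) sum by a sample mean and sample
#' standard deviation (denominator n - 1) estimated from permuted statistics,
#' applying the same per-cell affine transform to the observed and every
#' permuted sum. After this step every statistic lives on a common,
#' approximately standard normal scale, making the maximization over radii
#' and vertices comparable.
#'
#' With `moments = "pooled"` (the default) the observed statistic joins the
#' B permuted ones when the moments are estimated. Because the transform is
#' then a symmetric function of all B + 1 exchangeable values, the observed
#' and permuted maxima remain exactly exchangeable under the null, so the
#' downstream threshold is calibrated at any permutation count. With
#' `moments = "permuted"` the moments come from the B permuted sums alone;
#' the permuted standardized values then have mean 0 and standard deviation
#' 1 exactly, but the observed maximum is slightly inflated relative to the
#' permuted ones at small B (the two conventions coincide as B grows).
#'
#' @param S_obs numeric vector of observed sums (any stacking of (radius,
#'   vertex) cells).
#' @param S_perm matrix with `length(S_obs)` rows and B columns of permuted
#'   sums.
#' @param moments `"pooled"` or `"permuted"`; see Details.
#' @return list with `T_obs` (standardized observed) and `T_perm`
#'   (standardized permuted matrix).
#' @export
standardize_sums <- function(S_obs, S_perm,
                             moments = c("pooled", "permuted")) {
  moments <- match.arg(moments)
  S_obs <- as.numeric(S_obs)
  S_perm <- as.matrix(S_perm)
  if (length(S_obs) != nrow(S_perm))
    stop("`S_perm` must have one row per entry of `S_obs`")
  B <- ncol(S_perm)
  if (B < 2L) stop("need at least two permutations to estimate moments")
  pool <- if (moments == "pooled") cbind(S_obs, S_perm) else S_perm
  mu <- rowMeans(pool)
  ss <- sqrt(rowSums((pool - mu)^2) / (ncol(pool) - 1))
  bad <- which(ss == 0 | !is.finite(ss))
  if (length(bad))
    stop("zero permutation variance at ", length(bad),
         " (radius, vertex) cell(s); first stacked index ", bad[1L],
         " - data are degenerate or the kernel is exchangeable")
  list(T_obs = (S_obs - mu) / ss, T_perm = (S_perm - mu) / ss)
}

#' Adaptive maximum over radii
#'
#' The enhanced statistic of a vertex is the maximum of its standardized
#' neighborhood statistics across the radius set, approximating the unknown
#' best cluster size per vertex.
#'
#' @param Tr matrix of standardized statistics, one row per radius, one
#'   column per vertex.
#' @param radii radius labels, one per row of `Tr` (optional).
#' @return list with `Tv` (per-vertex maxima) and `radius` (argmax radius per
#'   vertex; ties take the smallest radius).
#' @export
adaptive_max <- function(Tr, radii = NULL) {
  Tr <- as.matrix(Tr)
  if (is.null(radii)) radii <- seq_len(nrow(Tr))
  if (length(radii) != nrow(Tr))
    stop("`radii` must have one entry per row of `Tr`")
  j <- max.col(t(Tr), ties.method = "first")
  list(Tv = Tr[cbind(j, seq_len(ncol(Tr)))], radius = radii[j])
}

#' Global maximum statistic
#'
#' `T = max over unmasked v of Tv(v)`, the scalar test statistic whose
#' permutation distribution yields the FWER threshold. Ties report the lowest
#' vertex index.
#'
#' @param Tv per-vertex adaptive statistics (NA allowed at masked vertices).
#' @param mask optional logical inclusion vector.
#' @return the maximum, with attribute `vertex` (argmax index).
#' @export
global_max <- function(Tv, mask = NULL) {
  Tv <- as.numeric(Tv)
  ok <- !is.na(Tv)
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  if (!any(ok)) stop("no unmasked vertices")
  idx <- which(ok)
  v <- idx[which.max(Tv[idx])]
  structure(Tv[v], vertex = v)
}
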
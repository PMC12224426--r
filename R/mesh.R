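#' Surface geometry container
#'
#' Bundles vertex coordinates, triangle faces, a per-vertex inclusion mask
#' (e.g., to exclude the medial wall), and an optional precomputed geodesic
#' distance matrix. Distances are computed lazily by [geodesic_distances()].
#'
#' @param coords numeric matrix of vertex positions in mm, one row per vertex,
#'   with 2 or 3 columns (a third zero coordinate is appended for planar
#'   meshes).
#' @param faces integer matrix with three vertex indices (1-based) per row, or
#'   `NULL` when only a precomputed distance matrix will be supplied.
#' @param mask logical vector flagging vertices to include; defaults to all.
#' @param D optional precomputed V x V geodesic distance matrix (mm). When
#'   supplied it overrides graph-based distances, e.g., to use exact polyhedral
#'   geodesics computed elsewhere.
#' @return an object of class `cleanv_surface`.
#' @seealso [geodesic_distances()], [build_neighborhoods()], [load_mesh()]
#' @export
surface_geometry <- function(coords, faces = NULL, mask = NULL, D = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) == 2L) coords <- cbind(coords, 0)
  if (ncol(coords) != 3L)
    stop("`coords` must have 2 or 3 columns (x, y[, z])")
  if (anyNA(coords)) stop("vertex coordinates contain missing values")
  V <- nrow(coords)
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L)
      stop("faces must be triangles: three vertex indices per row, got ",
           ncol(faces), " columns")
    storage.mode(faces) <- "integer"
    if (anyNA(faces) || any(faces < 1L) || any(faces > V))
      stop("face index out of range [1, ", V, "]")
  }
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  if (length(mask) != V || anyNA(mask))
    stop("`mask` must be a logical vector with one entry per vertex")
  if (!any(mask)) stop("mask excludes every vertex")
  if (!is.null(D)) D <- .validate_distances(D, V)
  structure(list(coords = coords, faces = faces, mask = mask, D = D),
            class = "cleanv_surface")
}

#' Geometry from a precomputed distance matrix
#'
#' For workflows where geodesic distances come from external software, the
#' mesh itself is not needed: neighborhoods only threshold distances.
#'
#' @param D square symmetric nonnegative distance matrix (mm).
#' @param coords optional vertex coordinates; when absent, a 1-d placeholder
#'   ordering is used (it only affects the NNGP vertex ordering).
#' @inheritParams surface_geometry
#' @return a `cleanv_surface` with `D` set and no faces.
#' @export
surface_from_distances <- function(D, coords = NULL, mask = NULL) {
  D <- as.matrix(D)
  if (is.null(coords)) coords <- cbind(seq_len(nrow(D)), 0, 0)
  surface_geometry(coords, faces = NULL, mask = mask, D = D)
}

.validate_distances <- function(D, V) {
  D <- as.matrix(D)
  dimnames(D) <- NULL
  if (!.is_square(D) || nrow(D) != V)
    stop("distance matrix must be ", V, " x ", V)
  if (any(D < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  if (max(abs(D - t(D)), na.rm = TRUE) > 1e-8 * max(1, max(D[is.finite(D)])))
    stop("distance matrix must be symmetric")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' @export
print.cleanv_surface <- function(x, ...) {
  cat("Surface geometry: ", nrow(x$coords), " vertices (",
      sum(x$mask), " unmasked), ",
      if (is.null(x$faces)) 0L else nrow(x$faces), " faces, distances ",
      if (is.null(x$D)) "not computed" else "available", "\n", sep = "")
  invisible(x)
}

#' Geodesic distances over the mesh graph
#'
#' Computes all-pairs shortest-path distances on the edge-weighted mesh graph,
#' with edge weights equal to Euclidean edge lengths. This graph geodesic is a
#' deterministic approximation to the exact polyhedral geodesic; it is
#' adequate here because distances are only thresholded at coarse (mm-scale)
#' neighborhood radii. Masked vertices are removed from the graph before the
#' computation, so all their distances are infinite.
#'
#' @param geom a `cleanv_surface`. If `geom$D` is already set it is returned
#'   unchanged.
#' @return the geometry with `D` filled.
#' @export
geodesic_distances <- function(geom) {
  stopifnot(inherits(geom, "cleanv_surface"))
  if (!is.null(geom$D)) return(geom)
  if (is.null(geom$faces) || nrow(geom$faces) == 0L)
    stop("mesh has no faces and no precomputed distances")
  V <- nrow(geom$coords)
  f <- geom$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]  # degenerate (repeated-index) faces
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  keep <- geom$mask[e[, 1L]] & geom$mask[e[, 2L]]
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0L) stop("no edges remain inside the mask")
  w <- sqrt(rowSums((geom$coords[e[, 1L], , drop = FALSE] -
                     geom$coords[e[, 2L], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = V, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(e)))
  D <- igraph::distances(g, weights = w)
  dimnames(D) <- NULL
  diag(D) <- 0
  act <- which(geom$mask)
  if (any(!is.finite(D[act, act])))
    warning("mesh is disconnected within the mask; ",
            "cross-component distances are infinite")
  geom$D <- D
  geom
}

#' Multi-radius geodesic neighborhood index
#'
#' For each radius r and unmasked vertex v, records the neighbor set
#' N_r(v) = \{v* unmasked : d(v, v*) <= r\}. Radius 0 is always included so
#' that the original vertex-level statistic participates in the adaptive
#' maximization. The index is built once per (distances, radii) pair and
#' reused across all permutations.
#'
#' @param geom a `cleanv_surface`; distances are computed if absent.
#' @param radii numeric vector of nonnegative radii in mm; deduplicated,
#'   sorted, and 0 prepended if absent. Default 0:20 mm.
#' @return an object of class `cleanv_nbhd` with fields `radii`, `members`
#'   (per radius, a length-V list of sorted neighbor indices; `NULL` at masked
#'   vertices), `active` (unmasked vertex indices), and sparse indicator
#'   matrices used internally for fast neighborhood sums.
#' @export
build_neighborhoods <- function(geom, radii = 0:20) {
  geom <- geodesic_distances(geom)
  radii <- as.numeric(radii)
  if (length(radii) == 0L || anyNA(radii)) stop("`radii` must be numeric")
  if (any(radii < 0)) stop("radii must be nonnegative")
  radii <- sort(unique(c(0, radii)))
  active <- which(geom$mask)
  Dsub <- geom$D[active, active, drop = FALSE]
  V <- nrow(geom$D)
  members <- indicator <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    M <- Dsub <= radii[k]
    indicator[[k]] <- methods::as(Matrix::Matrix(M * 1, sparse = TRUE),
                                  "generalMatrix")
    mem <- vector("list", V)
    mem[active] <- lapply(seq_along(active),
                          function(j) active[which(M[j, ])])
    members[[k]] <- mem
  }
  structure(list(radii = radii, members = members, indicator = indicator,
                 active = active, V = V),
            class = "cleanv_nbhd")
}

#' @export
print.cleanv_nbhd <- function(x, ...) {
  cat("Neighborhood index: ", length(x$active), " active vertices, radii {",
      paste(x$radii, collapse = ", "), "} mm\n", sep = "")
  invisible(x)
}

# Restrict an existing index to a subset of its radii (used by the ablated
# pipeline variants so neighborhoods are never rebuilt).
.subset_nbhd <- function(nbhd, radii) {
  keep <- match(sort(unique(c(0, radii))), nbhd$radii)
  if (anyNA(keep)) stop("requested radii not present in the neighborhood index")
  nbhd$radii <- nbhd$radii[keep]
  nbhd$members <- nbhd$members[keep]
  nbhd$indicator <- nbhd$indicator[keep]
  nbhd
}
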
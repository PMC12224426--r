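# Independent brute-force oracles used across the suite.

# Quadratic form d' K d by an explicit double loop.
brute_quadform <- function(d, K) {
  s <- 0
  for (i in seq_along(d))
    for (j in seq_along(d))
      s <- s + d[i] * K[i, j] * d[j]
  s
}

# Edge-weighted adjacency of a mesh (Inf where no edge, 0 on the diagonal).
mesh_adjacency <- function(geom) {
  V <- nrow(geom$coords)
  W <- matrix(Inf, V, V)
  diag(W) <- 0
  f <- geom$faces
  for (r in seq_len(nrow(f))) {
    for (pr in list(c(1L, 2L), c(2L, 3L), c(1L, 3L))) {
      a <- f[r, pr[1L]]; b <- f[r, pr[2L]]
      if (a != b) {
        w <- sqrt(sum((geom$coords[a, ] - geom$coords[b, ])^2))
        W[a, b] <- W[b, a] <- min(W[a, b], w)
      }
    }
  }
  W
}

# All-pairs shortest paths by Floyd-Warshall.
floyd_warshall <- function(W) {
  V <- nrow(W)
  for (k in seq_len(V))
    for (i in seq_len(V))
      for (j in seq_len(V))
        if (W[i, k] + W[k, j] < W[i, j]) W[i, j] <- W[i, k] + W[k, j]
  W
}

# Four-vertex tetrahedron, the smallest closed triangle mesh.
tetrahedron_tables <- function() {
  list(coords = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
       faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# Three vertices on a line with edge lengths 1 and 2 (D[1,3] = 3).
line3_geometry <- function() {
  surface_from_distances(rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)),
                         coords = cbind(c(0, 1, 3), 0, 0))
}

# Strip class/attribute decoration from a kinship matrix for comparisons.
as_mat <- function(K) matrix(as.numeric(K), nrow(K))
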
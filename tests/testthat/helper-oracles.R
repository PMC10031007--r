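# Independent brute-force oracles used across the suite. They deliberately
# re-derive each quantity by a different route than the package code.

# Closest distance from q to triangle (a, b, c) by candidate enumeration:
# the plane projection (if its barycentrics are inside), the three clamped
# edge projections, and the three vertices.
oracle_point_tri_dist <- function(q, a, b, c) {
  cands <- list(a, b, c)
  seg <- function(p0, p1) {
    d <- p1 - p0
    t <- sum((q - p0) * d) / sum(d * d)
    p0 + min(max(t, 0), 1) * d
  }
  cands <- c(cands, list(seg(a, b), seg(b, c), seg(c, a)))
  n <- pracma::cross(b - a, c - a)
  if (sum(n^2) > 0) {
    n <- n / sqrt(sum(n^2))
    proj <- q - sum((q - a) * n) * n
    # inside test via consistent cross products
    s1 <- sum(pracma::cross(b - a, proj - a) * n)
    s2 <- sum(pracma::cross(c - b, proj - b) * n)
    s3 <- sum(pracma::cross(a - c, proj - c) * n)
    if (s1 >= -1e-12 && s2 >= -1e-12 && s3 >= -1e-12) {
      cands <- c(cands, list(proj))
    }
  }
  min(vapply(cands, function(p) sqrt(sum((q - p)^2)), numeric(1)))
}

# Exhaustive nearest-face scan over all triangles of a mesh.
oracle_closest <- function(mesh, q) {
  d <- vapply(seq_len(nrow(mesh$faces)), function(f) {
    oracle_point_tri_dist(q, mesh$vertices[mesh$faces[f, 1], ],
                          mesh$vertices[mesh$faces[f, 2], ],
                          mesh$vertices[mesh$faces[f, 3], ])
  }, numeric(1))
  list(distance = min(d), face = which.min(d), all = d)
}

# Ray-crossing parity for point-in-mesh classification, vectorised over
# faces; repeated with independent ray directions and decided by majority.
oracle_inside_parity <- function(mesh, q,
                                 dirs = rbind(c(1, 0.1234, 0.342),
                                              c(-0.31, 1, 0.77),
                                              c(0.05, -0.93, 1))) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  votes <- apply(dirs, 1L, function(d) {
    d <- d / sqrt(sum(d^2))
    pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                d[3] * e2[, 1] - d[1] * e2[, 3],
                d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    tv <- matrix(q, nrow(f), 3L, byrow = TRUE) - a
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    vv <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
    tt <- rowSums(e2 * qv) / det
    hits <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 0
    sum(hits) %% 2 == 1
  })
  sum(votes) >= 2
}

# Dijkstra shortest path on the vertex graph of a surface mesh, connecting
# the mesh vertices nearest to the requested anchors (an upper bound on the
# geodesic that tightens with mesh density).
oracle_graph_path_length <- function(mesh, from, to) {
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  w <- sqrt(rowSums((mesh$vertices[edges[, 1], ] - mesh$vertices[edges[, 2], ])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  i <- which.min(rowSums(sweep(mesh$vertices, 2, from)^2))
  j <- which.min(rowSums(sweep(mesh$vertices, 2, to)^2))
  igraph::distances(g, v = i, to = j)[1, 1]
}

# Deterministic uniform points in a box.
runif_pts <- function(n, lo, hi, seed) {
  set.seed(seed)
  matrix(stats::runif(3 * n, lo, hi), n, 3L)
}

# Flat square grid mesh in the z = z0 plane (open, for normal tests).
flat_grid_mesh <- function(n = 5, z0 = 0) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  idx <- function(i, j) (j - 1L) * n + i
  tris <- list()
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  knee_mesh(cbind(g$x, g$y, z0), do.call(rbind, tris))
}

# Closed unit cube mesh (8 vertices, 12 faces, outward winding).
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  faces <- rbind(
    c(1, 3, 7), c(1, 7, 5),  # x = 0
    c(2, 8, 4), c(2, 6, 8),  # x = 1
    c(1, 5, 6), c(1, 6, 2),  # y = 0
    c(3, 4, 8), c(3, 8, 7),  # y = 1
    c(1, 4, 3), c(1, 2, 4),  # z = 0
    c(5, 7, 8), c(5, 8, 6))  # z = 1
  knee_mesh(v, faces)
}

# Regular tetrahedron written as an ASCII PLY string.
tetra_ply_lines <- function(bad_face_index = FALSE) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(0, 2, 1), c(0, 1, 3), c(0, 3, 2), c(1, 2, 3))
  if (bad_face_index) f[1, 2] <- 99L
  c("ply", "format ascii 1.0", "element vertex 4",
    "property double x", "property double y", "property double z",
    "element face 4", "property list uchar int vertex_indices", "end_header",
    apply(v, 1, paste, collapse = " "),
    paste("3", apply(f, 1, paste, collapse = " ")))
}
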
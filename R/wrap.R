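#' Obstacle set for elastic wrapping
#'
#' The wrap engine keeps paths and membranes outside a set of watertight
#' surfaces (bone + cartilage composites, and previously built soft-tissue
#' meshes added in build order). Each surface may carry an inflation offset:
#' wrapped nodes are kept at least that far outside it, which is how tube-like
#' obstacles compensate the chordal shrinkage of their discretised surface.
#'
#' @param surfaces list of watertight [knee_mesh()] objects.
#' @param inflation numeric vector of per-surface offsets in mm (recycled).
#' @return object of class `obstacle_set`.
#' @export
obstacle_set <- function(surfaces = list(), inflation = 0) {
  if (inherits(surfaces, "knee_mesh")) surfaces <- list(surfaces)
  inflation <- rep_len(as.numeric(inflation), length(surfaces))
  if (any(inflation < 0)) stop("inflation offsets must be >= 0")
  for (i in seq_along(surfaces)) {
    if (!is_watertight(surfaces[[i]])) {
      stop("obstacle surface ", i, " is not watertight")
    }
  }
  structure(list(surfaces = surfaces, inflation = inflation),
            class = "obstacle_set")
}

#' Append a surface to an obstacle set
#' @param obstacles an [obstacle_set()].
#' @param surface a watertight [knee_mesh()].
#' @param inflation offset in mm for the new surface.
#' @return the extended [obstacle_set()].
#' @export
add_obstacle <- function(obstacles, surface, inflation = 0) {
  obstacle_set(c(obstacles$surfaces, list(surface)),
               c(obstacles$inflation, inflation))
}

obstacle_args <- function(obstacles) {
  list(V = lapply(obstacles$surfaces, `[[`, "vertices"),
       F = lapply(obstacles$surfaces, `[[`, "faces"),
       inflate = obstacles$inflation)
}

#' Project points out of obstacles
#'
#' Points found inside (or within an obstacle's inflation offset of) any
#' obstacle are moved to the closest point of the most deeply penetrated
#' surface, repeatedly until no violation remains; outside points are
#' untouched. The operation is idempotent.
#'
#' @param points k x 3 matrix (or 3-vector).
#' @param obstacles an [obstacle_set()].
#' @param extra_offset additional clearance in mm, scalar or per point.
#' @return corrected points, same shape as the input.
#' @export
project_out <- function(points, obstacles, extra_offset = 0) {
  pm <- if (is.matrix(points)) points else matrix(points, 1L, 3L)
  if (length(obstacles$surfaces) == 0L) return(points)
  oa <- obstacle_args(obstacles)
  out <- cpp_project_points(pm, oa$V, oa$F, oa$inflate,
                            as.numeric(extra_offset))
  if (!is.matrix(points)) out[1L, ] else out
}

# Anchors are fixed and never projected, so they must not start inside an
# obstacle. They may legitimately sit on a surface (e.g. meniscal roots on the
# tibial plateau) even when interior nodes carry a positive offset, so offsets
# are not enforced at the anchors themselves.
check_anchor_clear <- function(points, obstacles) {
  if (length(obstacles$surfaces) == 0L) return(invisible(TRUE))
  pm <- if (is.matrix(points)) points else matrix(points, 1L, 3L)
  oa <- obstacle_args(obstacles)
  for (o in seq_along(oa$V)) {
    w <- cpp_winding_number(oa$V[[o]], oa$F[[o]], pm)
    d <- cpp_closest_points(oa$V[[o]], oa$F[[o]], pm)$distance
    if (any(w > 0.5 & d > 1e-5)) {
      stop("anchor point lies inside obstacle ", o,
           sprintf(" (depth %.3g mm)", max(d[w > 0.5])))
    }
  }
  invisible(TRUE)
}

#' Relaxation settings for the wrap engine
#'
#' @param omega successive over-relaxation factor in (0, 2); each single-node
#'   update with `omega < 2` strictly decreases the discrete elastic energy.
#' @param tol convergence threshold on the maximum per-node displacement (mm).
#' @param max_iter iteration cap; non-convergence yields a warning, the result
#'   is still returned flagged.
#' @return list of settings.
#' @export
wrap_params <- function(omega = 1.5, tol = 1e-4, max_iter = 10000L) {
  stopifnot(omega > 0, omega < 2, tol > 0, max_iter >= 1)
  list(omega = omega, tol = tol, max_iter = as.integer(max_iter))
}

wrap_result <- function(raw, kind, dims = NULL) {
  res <- structure(list(nodes = raw$nodes, kind = kind, dims = dims,
                        iterations = raw$iterations,
                        final_max_displacement = raw$final_max_displacement,
                        energy_trace = raw$energy_trace,
                        converged = raw$converged),
                   class = "wrap_result")
  if (!raw$converged) {
    warning(sprintf(
      "wrap did not converge in %d iterations (last max displacement %.3g mm)",
      raw$iterations, raw$final_max_displacement))
  }
  res
}

#' @export
print.wrap_result <- function(x, ...) {
  cat(sprintf("<wrap_result> %s, %d nodes, %d iterations, final energy %.6g\n",
              x$kind, nrow(x$nodes), x$iterations,
              x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}

#' Total polyline length of a chain wrap
#' @param result a chain `wrap_result`.
#' @return length in mm.
#' @export
wrap_length <- function(result) {
  sum(sqrt(rowSums(diff(result$nodes)^2)))
}

#' Elastic chain wrapped over obstacles
#'
#' An elastic line of `n_nodes` nodes connects `start` to `end`. Interior
#' nodes are iteratively relaxed toward the midpoint of their neighbours
#' (minimising the discrete elastic energy, the sum of squared segment
#' lengths) while any node found penetrating an obstacle is returned to the
#' closest point on the penetrated surface. The converged chain is the
#' discrete taut string: straight where free, geodesic-like where in contact.
#'
#' @param start,end anchor points (3-vectors), fixed throughout; must lie
#'   outside all obstacles.
#' @param obstacles an [obstacle_set()].
#' @param n_nodes chain resolution (>= 3).
#' @param params a [wrap_params()] list.
#' @return a `wrap_result` with ordered `nodes` (n_nodes x 3), the iteration
#'   count, per-iteration `energy_trace` (non-increasing), and convergence
#'   status.
#' @export
wrap_chain <- function(start, end, obstacles = obstacle_set(), n_nodes = 100L,
                       params = wrap_params()) {
  wrap_chain_offset(start, end, obstacles, n_nodes,
                    offset_profile = rep(0, n_nodes), params = params)
}

#' Elastic chain with per-node minimum obstacle offsets
#'
#' As [wrap_chain()], but node `i` is kept at distance at least
#' `offset_profile[i]` outside every obstacle (on top of any per-obstacle
#' inflation). This is the primitive behind meniscal path wrapping (offset =
#' half the local meniscal height) and cruciate centerlines (constant minimal
#' offset).
#'
#' @inheritParams wrap_chain
#' @param offset_profile numeric vector of length `n_nodes`, offsets in mm
#'   (>= 0). Anchor offsets are checked against the anchors' actual clearance.
#' @return a `wrap_result`.
#' @export
wrap_chain_offset <- function(start, end, obstacles = obstacle_set(),
                              n_nodes = 100L, offset_profile,
                              params = wrap_params()) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  offset_profile <- rep_len(as.numeric(offset_profile), n_nodes)
  if (any(offset_profile < 0)) stop("offsets must be >= 0")
  check_anchor_clear(rbind(start, end), obstacles)
  tt <- seq(0, 1, length.out = n_nodes)
  P0 <- outer(1 - tt, as.numeric(start)) + outer(tt, as.numeric(end))
  oa <- obstacle_args(obstacles)
  raw <- cpp_wrap_chain(P0, offset_profile, oa$V, oa$F, oa$inflate,
                        params$omega, params$tol, params$max_iter)
  wrap_result(raw, "chain")
}

#' Elastic membrane wrapped over obstacles
#'
#' A grid of springs connects an origin curve to an insertion curve: column
#' `j` joins `origin_curve[j, ]` to `insertion_curve[j, ]` through
#' `n_rows - 2` interior rows, with springs along both grid directions. The
#' boundary rows (the curves) stay fixed; interior nodes relax under the same
#' energy-minimisation and penetration-projection contract as [wrap_chain()].
#'
#' @param origin_curve,insertion_curve k x 3 matrices with the same k >= 2.
#' @param obstacles an [obstacle_set()].
#' @param n_rows number of grid rows including the two fixed curves (>= 3).
#' @param closed logical: treat the curves as closed loops (periodic columns),
#'   used for sleeve-like structures such as the patellar tendon.
#' @param offset minimum clearance (mm) interior nodes keep from every
#'   obstacle (e.g. half a ligament thickness so an extruded band clears).
#' @param cross_weight relative stiffness of the springs running across the
#'   fibre direction (between adjacent columns). 1 is an isotropic membrane;
#'   0 leaves only the fibre chains, as used for sleeve structures whose
#'   cross-section is dictated by the attachment rims, not by membrane
#'   tension.
#' @param params a [wrap_params()] list.
#' @return a `wrap_result` whose `nodes` hold the grid row-major
#'   (`dims = c(n_rows, k)`); use [wrap_grid_mesh()] to triangulate it.
#' @export
wrap_membrane <- function(origin_curve, insertion_curve,
                          obstacles = obstacle_set(), n_rows = 30L,
                          closed = FALSE, offset = 0, cross_weight = 1,
                          params = wrap_params()) {
  origin_curve <- as.matrix(origin_curve)
  insertion_curve <- as.matrix(insertion_curve)
  k <- nrow(origin_curve)
  if (nrow(insertion_curve) != k) {
    stop("origin and insertion curves must have the same number of points")
  }
  if (k < 2L) stop("curves need at least 2 points")
  n_rows <- as.integer(n_rows)
  if (n_rows < 3L) stop("n_rows must be >= 3")
  check_anchor_clear(rbind(origin_curve, insertion_curve), obstacles)
  P0 <- matrix(0, n_rows * k, 3L)
  for (r in seq_len(n_rows)) {
    a <- (r - 1) / (n_rows - 1)
    P0[(r - 1L) * k + seq_len(k), ] <- (1 - a) * origin_curve + a * insertion_curve
  }
  oa <- obstacle_args(obstacles)
  raw <- cpp_wrap_grid(P0, n_rows, k, closed, rep(as.numeric(offset), n_rows * k),
                       oa$V, oa$F, oa$inflate,
                       params$omega, params$tol, params$max_iter,
                       as.numeric(cross_weight))
  res <- wrap_result(raw, "membrane", dims = c(n_rows, k))
  res$closed_cols <- closed
  res
}

#' Grid node matrix of a membrane wrap
#' @param result a membrane `wrap_result`.
#' @param row,col grid indices.
#' @return 3-vector, or the full `n_rows x k x 3` array when indices missing.
#' @export
wrap_grid_nodes <- function(result, row = NULL, col = NULL) {
  d <- result$dims
  arr <- aperm(array(t(result$nodes), dim = c(3L, d[2L], d[1L])), c(3L, 2L, 1L))
  if (is.null(row)) return(arr)
  arr[row, col, ]
}

#' Triangulated surface of a membrane wrap
#'
#' Interconnects the relaxed grid nodes into a flat triangle mesh (two
#' triangles per grid quad).
#'
#' @param result a membrane `wrap_result`.
#' @return a [knee_mesh()] (open strip, or open sleeve when the wrap was
#'   closed).
#' @export
wrap_grid_mesh <- function(result) {
  d <- result$dims
  nr <- d[1L]; nc <- d[2L]
  idx <- function(r, c) (r - 1L) * nc + c
  closed <- isTRUE(result$closed_cols)
  tris <- list()
  cmax <- if (closed) nc else nc - 1L
  for (r in seq_len(nr - 1L)) {
    for (c in seq_len(cmax)) {
      c2 <- if (c == nc) 1L else c + 1L
      tris[[length(tris) + 1L]] <- c(idx(r, c), idx(r + 1L, c), idx(r + 1L, c2))
      tris[[length(tris) + 1L]] <- c(idx(r, c), idx(r + 1L, c2), idx(r, c2))
    }
  }
  knee_mesh(result$nodes, do.call(rbind, tris), bone_label = "membrane")
}
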
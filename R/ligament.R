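#' Ligament specification table
#'
#' The modeled main knee ligaments with their assigned mid-substance
#' thicknesses (mm), taken from cadaveric and MRI literature: MPFL 2.90,
#' LPFL 1.80, sMCL 2.10 (used for both its anterior and posterior bundle),
#' LCL 2.20, ALL 1.50, POL 1.00, OPL 1.44. Origin/insertion columns name the
#' landmark entries the predictor looks up.
#'
#' @return data frame with columns `name`, `origin`, `insertion`,
#'   `thickness`.
#' @export
default_ligament_table <- function() {
  data.frame(
    name = c("MPFL", "LPFL", "sMCL_ant", "sMCL_post", "LCL", "ALL", "POL", "OPL"),
    origin = c("MPFL_origin", "LPFL_origin", "sMCL_origin", "sMCL_origin",
               "LCL_origin", "ALL_origin", "POL_origin", "OPL_origin"),
    insertion = c("MPFL_insertion", "LPFL_insertion", "sMCL_ant_insertion",
                  "sMCL_post_insertion", "LCL_insertion", "ALL_insertion",
                  "POL_insertion", "OPL_insertion"),
    thickness = c(2.90, 1.80, 2.10, 2.10, 2.20, 1.50, 1.00, 1.44),
    stringsAsFactors = FALSE)
}

#' Thickness of one ligament
#' @param name ligament name from [default_ligament_table()].
#' @return thickness in mm.
#' @export
ligament_thickness <- function(name) {
  tab <- default_ligament_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown ligament: ", name)
  tab$thickness[i]
}

#' Reduce an attachment area to an ordered curve
#'
#' Attachment areas are delineated as vertex groups on the bone; the wrap
#' membrane needs a matched open curve across each. The vertices are
#' projected onto their best-fit plane, ordered along the principal axis of
#' the area, and resampled to `n` points along the resulting polyline (via
#' an interpolating spline when enough points exist).
#'
#' @param points k x 3 matrix of attachment vertices.
#' @param n number of curve points.
#' @return n x 3 matrix.
#' @export
attachment_curve <- function(points, n) {
  P <- as.matrix(points)
  if (nrow(P) == 1L) return(matrix(rep(P, each = n), n, 3L))
  cen <- colMeans(P)
  X <- sweep(P, 2L, cen)
  sv <- svd(X)
  ord <- order(X %*% sv$v[, 1L])
  path <- P[ord, , drop = FALSE]
  # drop coincident consecutive points
  keep <- c(TRUE, rowSums(diff(path)^2) > 1e-16)
  path <- path[keep, , drop = FALSE]
  if (nrow(path) == 1L) return(matrix(rep(path, each = n), n, 3L))
  if (nrow(path) == 2L) {
    tt <- seq(0, 1, length.out = n)
    return(outer(1 - tt, path[1L, ]) + outer(tt, path[2L, ]))
  }
  spline_resample(fit_spline(path, closed = FALSE), n)
}

#' Order a closed attachment loop by polar angle
#'
#' Vertex loops (patellar tendon origin/insertion rims) are ordered by polar
#' angle in their best-fit plane around the centroid, producing a closed,
#' non-self-crossing loop for spline fitting.
#'
#' @param points k x 3 matrix (k >= 3).
#' @return reordered k x 3 matrix.
#' @export
order_loop <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stop("a loop needs at least 3 vertices")
  cen <- colMeans(P)
  X <- sweep(P, 2L, cen)
  sv <- svd(X)
  u <- X %*% sv$v[, 1L]
  v <- X %*% sv$v[, 2L]
  P[order(atan2(v, u)), , drop = FALSE]
}

#' Predict a ligament band by elastic membrane wrapping
#'
#' The origin and insertion attachment areas are reduced to matched curves;
#' an elastic membrane is wrapped between them around the obstacle set; the
#' relaxed flat mesh is then given a volume by symmetric extrusion of the
#' ligament-specific thickness about the midsurface, closed by side walls.
#' Interior membrane nodes keep a clearance of half the thickness so the
#' extruded solid clears the obstacles; any solid vertex still penetrating
#' (e.g. at the fixed attachment rows on the bone surface) is projected
#' back onto the obstacle surface.
#'
#' @param name ligament name (see [default_ligament_table()]).
#' @param origin_points,insertion_points attachment vertex groups (k x 3
#'   matrices) from landmark transfer.
#' @param obstacles an [obstacle_set()].
#' @param thickness mid-substance thickness in mm; defaults to the table
#'   value for `name`.
#' @param n_cols,n_rows membrane grid resolution.
#' @param params a [wrap_params()] list.
#' @return object of class `ligament_mesh` with `spec`, `midsurface` (a
#'   membrane `wrap_result`) and `solid` (watertight [knee_mesh()]).
#' @export
predict_ligament <- function(name, origin_points, insertion_points,
                             obstacles = obstacle_set(),
                             thickness = ligament_thickness(name),
                             n_cols = 20L, n_rows = 30L,
                             params = wrap_params()) {
  origin_points <- as.matrix(origin_points)
  insertion_points <- as.matrix(insertion_points)
  if (nrow(origin_points) == 0L || nrow(insertion_points) == 0L) {
    stop("empty attachment group")
  }
  if (thickness <= 0) stop("thickness must be > 0")
  if (nrow(origin_points) == 1L && nrow(insertion_points) == 1L) {
    # point-to-point degenerates to a chain with a tube of diameter thickness
    chain <- wrap_chain(project_out(origin_points[1L, ], obstacles),
                        project_out(insertion_points[1L, ], obstacles),
                        obstacles, n_nodes = n_rows, params = params)
    tube <- build_tube(chain$nodes, rep(thickness / 2, nrow(chain$nodes)))
    solid <- tube$surface
    solid$vertices <- project_out(solid$vertices, obstacles)
    solid$bone_label <- name
    return(structure(list(spec = list(name = name, thickness = thickness),
                          midsurface = chain, solid = solid),
                     class = "ligament_mesh"))
  }
  oc <- attachment_curve(origin_points, n_cols)
  ic <- attachment_curve(insertion_points, n_cols)
  # match curve directions: reverse the insertion curve if that shortens the
  # total fibre length (crossing columns)
  # attachment curves live on the bone surface; interpolation may dip a
  # fraction of a millimetre inside, so lift them back out first
  oc <- project_out(oc, obstacles)
  ic <- project_out(ic, obstacles)
  fwd <- sum(sqrt(rowSums((oc - ic)^2)))
  rev <- sum(sqrt(rowSums((oc - ic[nrow(ic):1L, , drop = FALSE])^2)))
  if (rev < fwd) ic <- ic[nrow(ic):1L, , drop = FALSE]
  # ligaments are modeled as elastic fibre chains (one per column) that are
  # interconnected into a flat mesh afterwards; cross springs would contract
  # the free band edges toward the middle
  mid <- wrap_membrane(oc, ic, obstacles, n_rows = n_rows,
                       offset = thickness / 2, cross_weight = 0,
                       params = params)
  solid <- extrude_membrane(mid, thickness)
  solid$vertices <- project_out(solid$vertices, obstacles)
  solid$bone_label <- name
  structure(list(spec = list(name = name, thickness = thickness),
                 midsurface = mid, solid = solid),
            class = "ligament_mesh")
}

#' @export
print.ligament_mesh <- function(x, ...) {
  cat(sprintf("<ligament_mesh> %s: thickness %.2f mm, %d solid vertices\n",
              x$spec$name, x$spec$thickness, nrow(x$solid$vertices)))
  invisible(x)
}

# Symmetric +-t/2 extrusion of a membrane grid along its node normals,
# closed by side walls along the grid boundary.
extrude_membrane <- function(mid, thickness) {
  d <- mid$dims
  nr <- d[1L]; nc <- d[2L]
  G <- wrap_grid_nodes(mid)
  N <- array(0, dim = dim(G))
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      dr <- G[min(r + 1L, nr), c, ] - G[max(r - 1L, 1L), c, ]
      dc <- G[r, min(c + 1L, nc), ] - G[r, max(c - 1L, 1L), ]
      n <- pracma_cross(dr, dc)
      ln <- sqrt(sum(n^2))
      N[r, c, ] <- if (ln > 0) n / ln else c(0, 0, 1)
    }
  }
  idx <- function(r, c) (r - 1L) * nc + c
  top <- matrix(0, nr * nc, 3L)
  bot <- matrix(0, nr * nc, 3L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    top[idx(r, c), ] <- G[r, c, ] + (thickness / 2) * N[r, c, ]
    bot[idx(r, c), ] <- G[r, c, ] - (thickness / 2) * N[r, c, ]
  }
  off <- nr * nc
  tris <- list()
  for (r in seq_len(nr - 1L)) for (c in seq_len(nc - 1L)) {
    a <- idx(r, c); b <- idx(r, c + 1L); a2 <- idx(r + 1L, c); b2 <- idx(r + 1L, c + 1L)
    tris[[length(tris) + 1L]] <- c(a, a2, b2)
    tris[[length(tris) + 1L]] <- c(a, b2, b)
    tris[[length(tris) + 1L]] <- off + c(a, b2, a2)
    tris[[length(tris) + 1L]] <- off + c(a, b, b2)
  }
  wall <- function(edge) {
    # edge: vector of grid node indices along the boundary, ordered
    for (i in seq_len(length(edge) - 1L)) {
      a <- edge[i]; b <- edge[i + 1L]
      tris[[length(tris) + 1L]] <<- c(a, b, off + b)
      tris[[length(tris) + 1L]] <<- c(a, off + b, off + a)
    }
  }
  wall(vapply(seq_len(nc), function(c) idx(1L, c), integer(1)))
  wall(vapply(seq_len(nr), function(r) idx(r, nc), integer(1)))
  wall(rev(vapply(seq_len(nc), function(c) idx(nr, c), integer(1))))
  wall(rev(vapply(seq_len(nr), function(r) idx(r, 1L), integer(1))))
  mesh <- knee_mesh(rbind(top, bot), do.call(rbind, tris), bone_label = "ligament")
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Predict the patellar tendon as a closed wrapped sleeve
#'
#' Closed splines are fitted on the origin (patellar) and insertion (tibial)
#' vertex loops; both are resampled at the same count of corresponding
#' arc-length parameters, starting from the most medial vertex and travelling
#' in matched directions; corresponding points are connected by membrane
#' columns wrapped over the obstacle set. The resulting closed sleeve is the
#' tendon: its thickness is inherent to the vertex positions, not an
#' assigned value.
#'
#' @param origin_points,insertion_points vertex loops (k x 3 matrices,
#'   k >= 3) from landmark transfer.
#' @param obstacles an [obstacle_set()].
#' @param n_cols circumferential resolution of the sleeve.
#' @param n_rows rows along the tendon course.
#' @param medial_dir unit vector defining "medial" for the parameter origin.
#' @param params a [wrap_params()] list.
#' @return a `ligament_mesh` whose `solid` is the open-ended sleeve mesh.
#' @export
predict_patellar_tendon <- function(origin_points, insertion_points,
                                    obstacles = obstacle_set(),
                                    n_cols = 24L, n_rows = 30L,
                                    medial_dir = c(-1, 0, 0),
                                    params = wrap_params()) {
  ring <- function(points) {
    loop <- order_loop(points)
    spl <- fit_spline(loop, closed = TRUE)
    # start the parameterization at the most medial control point
    dense <- seq(0, 1, length.out = 512L)
    pts <- spline_eval(spl, dense)
    t0 <- dense[which.max(pts %*% medial_dir)]
    spline_resample(spl, n_cols, t_start = t0)
  }
  oc <- project_out(ring(origin_points), obstacles)
  ic <- project_out(ring(insertion_points), obstacles)
  fwd <- sum(sqrt(rowSums((oc - ic)^2)))
  rev_ic <- ic[c(1L, nrow(ic):2L), , drop = FALSE]  # reverse travel, same start
  rev <- sum(sqrt(rowSums((oc - rev_ic)^2)))
  if (rev < fwd) ic <- rev_ic
  # fibre springs only: the sleeve's cross-section is dictated by the
  # attachment rims; circumferential tension would neck a free sleeve
  mid <- wrap_membrane(oc, ic, obstacles, n_rows = n_rows, closed = TRUE,
                       cross_weight = 0, params = params)
  solid <- wrap_grid_mesh(mid)
  solid$vertices <- project_out(solid$vertices, obstacles)
  solid$bone_label <- "PT"
  structure(list(spec = list(name = "PT", thickness = NA_real_),
                 midsurface = mid, solid = solid),
            class = "ligament_mesh")
}
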
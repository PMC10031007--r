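#' Triangular meniscal cross-section
#'
#' The meniscal body is numerically simplified as a triangle of varying
#' height and width along its course: a thick outer edge of vertical extent
#' `height` at the node (the outer rim), tapering to an apex at distance
#' `width` toward the meniscal center.
#'
#' @param node 3-vector on the centerline (outer rim).
#' @param toward_center unit vector from the node toward the meniscal center.
#' @param up unit vector orthogonal to `toward_center` (tibial plateau
#'   normal).
#' @param height,width positive extents in mm.
#' @return 3 x 3 matrix: apex, outer-top, outer-bottom.
#' @export
cross_section_triangle <- function(node, toward_center, up, height, width) {
  if (height <= 0 || width <= 0) stop("height and width must be > 0")
  if (abs(sum(toward_center^2) - 1) > 1e-6 || abs(sum(up^2) - 1) > 1e-6 ||
      abs(sum(toward_center * up)) > 1e-6) {
    stop("toward_center and up must be orthonormal")
  }
  rbind(apex = node + width * toward_center,
        top = node + (height / 2) * up,
        bottom = node - (height / 2) * up)
}

#' Meniscal center of a wrapped centerline
#'
#' Arc-length-weighted centroid of the centerline nodes, projected onto the
#' centerline's best-fit plane (the meniscus lies on the tibial plateau, so
#' this plane is the plateau plane). The width direction of every
#' cross-section points from its node toward this center.
#'
#' @param centerline k x 3 matrix of ordered nodes (k >= 3, not collinear).
#' @return list with `center` (3-vector) and `plane_normal` (unit 3-vector).
#' @export
meniscal_center <- function(centerline) {
  P <- as.matrix(centerline)
  if (nrow(P) < 3L) stop("centerline needs at least 3 nodes")
  seg <- sqrt(rowSums(diff(P)^2))
  w <- c(seg, 0) / 2 + c(0, seg) / 2
  cen <- colSums(P * w) / sum(w)
  X <- sweep(P, 2L, cen)
  sv <- svd(X)
  if (sv$d[2L] < 1e-6 * sv$d[1L]) {
    stop("centerline is collinear; meniscal center undefined")
  }
  normal <- sv$v[, 3L]
  # project the centroid onto the best-fit plane (it lies on it already,
  # being the weighted mean only up to the arc-length weighting)
  center <- cen - sum((cen - colMeans(P)) * normal) * normal
  list(center = center, plane_normal = normal)
}

#' Build a static meniscus between tibial and femoral surfaces
#'
#' Three steps: (1) an elastic tube path is wrapped from the anterior to the
#' posterior root while enforcing a per-node offset equal to half the local
#' meniscal height, which forces the path around the femoral condyle without
#' osseous or cartilage penetration; (2) at equidistant stations along the
#' path, triangular cross-sections are erected with the width projected
#' toward the meniscal center and the height orthogonal to it, and
#' interconnected into a closed wedge mesh; (3) mesh nodes found penetrating
#' the composite osseous-cartilage surface are projected back onto it, so
#' the meniscal edges adapt to fit between the cartilage layers.
#'
#' @param obstacles an [obstacle_set()] holding the tibial and femoral
#'   bone+cartilage composites (and anything else the meniscus must avoid).
#' @param anterior_root,posterior_root root points (3-vectors) on or near the
#'   tibial surface, typically from landmark transfer.
#' @param height_profile,width_profile `polynomial_profile` objects of the
#'   meniscal height and width versus relative outer length in `[0, 1]`.
#' @param side `"medial"` or `"lateral"` (metadata).
#' @param n_nodes number of centerline stations.
#' @param params a [wrap_params()] list.
#' @param up_hint optional direction; the plateau-plane normal is oriented to
#'   have a positive dot product with it (default +z).
#' @param center optional explicit meniscal center (3-vector). By default the
#'   center is the arc-length-weighted centroid of the wrapped path
#'   ([meniscal_center()]); an explicit center supports degenerate,
#'   near-straight paths and custom center definitions. With an explicit
#'   center the `up` direction is `up_hint` itself.
#' @return object of class `meniscus_model` with `centerline`
#'   (`wrap_result`), `surface` (watertight [knee_mesh()]), `center`,
#'   `height_profile`, `width_profile`, `side`.
#' @export
build_meniscus <- function(obstacles, anterior_root, posterior_root,
                           height_profile, width_profile, side = "medial",
                           n_nodes = 60L, params = wrap_params(),
                           up_hint = c(0, 0, 1), center = NULL) {
  n_nodes <- as.integer(n_nodes)
  s <- seq(0, 1, length.out = n_nodes)
  h <- eval_profile(height_profile, s)
  d <- eval_profile(width_profile, s)
  if (mean(h[-c(1L, n_nodes)] < 0) > 0.5 || mean(d[-c(1L, n_nodes)] < 0) > 0.5) {
    stop("meniscal profiles are non-positive over more than half the span")
  }
  floor_mm <- 0.05
  if (all(h <= floor_mm)) {
    warning("height profile is degenerate (everywhere at the floor); ",
            "building a flat ribbon")
  }
  h <- pmax(h, floor_mm)
  d <- pmax(d, floor_mm)
  chain <- wrap_chain_offset(anterior_root, posterior_root, obstacles,
                             n_nodes = n_nodes, offset_profile = h / 2,
                             params = params)
  P <- chain$nodes
  if (is.null(center)) {
    cen <- meniscal_center(P)
    up <- cen$plane_normal
    if (sum(up * up_hint) < 0) up <- -up
    center <- cen$center
  } else {
    center <- as.numeric(center)
    up <- up_hint / sqrt(sum(up_hint^2))
  }
  # per-node relative position: normalized cumulative chord length
  arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  s_node <- arc / arc[length(arc)]
  hh <- pmax(eval_profile(height_profile, s_node), floor_mm)
  dd <- pmax(eval_profile(width_profile, s_node), floor_mm)
  verts <- matrix(0, 3L * n_nodes, 3L)
  for (i in seq_len(n_nodes)) {
    tc <- center - P[i, ]
    tc <- tc - sum(tc * up) * up
    ntc <- sqrt(sum(tc^2))
    if (ntc < 1e-9) stop("centerline node coincides with the meniscal center")
    tc <- tc / ntc
    verts[(i - 1L) * 3L + 1:3, ] <-
      cross_section_triangle(P[i, ], tc, up, hh[i], dd[i])
  }
  vid <- function(i, k) (i - 1L) * 3L + k  # k: 1 apex, 2 top, 3 bottom
  tris <- list()
  for (i in seq_len(n_nodes - 1L)) {
    for (k in 1:3) {
      k2 <- k %% 3L + 1L
      a <- vid(i, k); b <- vid(i, k2)
      a2 <- vid(i + 1L, k); b2 <- vid(i + 1L, k2)
      tris[[length(tris) + 1L]] <- c(a, a2, b2)
      tris[[length(tris) + 1L]] <- c(a, b2, b)
    }
  }
  tris[[length(tris) + 1L]] <- c(vid(1L, 1L), vid(1L, 2L), vid(1L, 3L))
  tris[[length(tris) + 1L]] <- c(vid(n_nodes, 1L), vid(n_nodes, 3L), vid(n_nodes, 2L))
  surface <- knee_mesh(verts, do.call(rbind, tris),
                       bone_label = paste0(side, "_meniscus"))
  if (mesh_volume(surface) < 0) {
    surface$faces <- surface$faces[, c(1L, 3L, 2L)]
  }
  # step 3: project penetrating nodes onto the outer osseous-cartilage surface
  surface$vertices <- project_out(surface$vertices, obstacles)
  structure(list(side = side, anterior_root = as.numeric(anterior_root),
                 posterior_root = as.numeric(posterior_root),
                 centerline = chain, center = center,
                 height_profile = height_profile,
                 width_profile = width_profile, surface = surface),
            class = "meniscus_model")
}

#' @export
print.meniscus_model <- function(x, ...) {
  cat(sprintf("<meniscus_model> %s: %d centerline nodes, %d surface vertices\n",
              x$side, nrow(x$centerline$nodes), nrow(x$surface$vertices)))
  invisible(x)
}
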
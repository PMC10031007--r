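#' Default polynomial degrees for cruciate radius profiles
#'
#' The degrees retained by the sensitivity analysis: 2 for the ACL and 4 for
#' the PCL.
#' @return named integer vector.
#' @export
default_radius_degrees <- function() c(ACL = 2L, PCL = 4L)

#' Profile samples from per-slice thickness measurements
#'
#' Cruciate thickness is measured on regularly spaced image slices over the
#' origin-to-insertion course; slice positions are normalized to the relative
#' course in `[0, 1]` and thicknesses halved into radii.
#'
#' @param positions numeric vector of monotonically increasing slice
#'   positions (any unit).
#' @param thickness numeric vector of thicknesses (mm), same length.
#' @param structure_label `"ACL_radius"` or `"PCL_radius"`.
#' @return a [profile_samples()] of radii versus relative course.
#' @export
thickness_samples_from_slices <- function(positions, thickness,
                                          structure_label = "ACL_radius") {
  if (length(positions) < 2L) stop("at least 2 slices required")
  if (length(positions) != length(thickness)) {
    stop("positions and thickness must have equal length")
  }
  if (any(diff(positions) <= 0)) stop("slice positions must be strictly increasing")
  s <- (positions - positions[1L]) / (positions[length(positions)] - positions[1L])
  profile_samples(s, thickness / 2, structure_label = structure_label)
}

#' Predict a cruciate ligament as a variable-radius tube
#'
#' The centerline is modeled from origin to insertion as a series of
#' connected spring elements (15 by default) whose position is optimized by
#' shortest-path elastic relaxation; connecting nodes are spatially
#' constrained to a minimal offset from every obstacle, similar to the
#' cruciate ligament width. A tube with the polynomial radius profile is
#' then fitted around the centerline using Frenet-Serret frames. For the
#' PCL, the previously built ACL tube is appended to the obstacle set (with
#' chordal inflation of its discretised surface) so the PCL wraps around the
#' ACL on its course.
#'
#' @param name `"ACL"` or `"PCL"`.
#' @param origin,insertion attachment points (3-vectors) from landmark
#'   transfer.
#' @param obstacles an [obstacle_set()] (bones + cartilage + menisci +
#'   ligaments in build order).
#' @param radius_profile a `polynomial_profile` of tube radius (mm) versus
#'   relative course.
#' @param n_segments number of spring elements (default 15, i.e. 16 nodes).
#' @param min_offset minimal node clearance from obstacles (mm); default is
#'   the mean profile width (twice the mean radius).
#' @param acl optional previously built `cruciate_model` of the ACL, added
#'   to the obstacles when predicting the PCL.
#' @param n_circumferential tube ring resolution.
#' @param params a [wrap_params()] list.
#' @return object of class `cruciate_model` with `name`, `centerline`
#'   (`wrap_result`), `radius_profile`, `min_offset` and `tube`
#'   (a `tube_mesh`).
#' @export
predict_cruciate <- function(name, origin, insertion,
                             obstacles = obstacle_set(), radius_profile,
                             n_segments = 15L, min_offset = NULL,
                             acl = NULL, n_circumferential = 24L,
                             params = wrap_params()) {
  name <- match.arg(name, c("ACL", "PCL"))
  n_nodes <- as.integer(n_segments) + 1L
  s <- seq(0, 1, length.out = 256L)
  rbar <- mean(pmax(eval_profile(radius_profile, s), 0))
  if (rbar <= 0) stop("radius profile is non-positive")
  if (is.null(min_offset)) min_offset <- 2 * rbar
  if (name == "PCL" && !is.null(acl)) {
    obstacles <- add_obstacle(obstacles, acl$tube$surface,
                              inflation = tube_chordal_inflation(acl$tube))
  }
  chain <- wrap_chain_offset(origin, insertion, obstacles, n_nodes = n_nodes,
                             offset_profile = rep(min_offset, n_nodes),
                             params = params)
  radii <- radius_profile_from_polynomial(radius_profile, n_nodes)
  tube <- build_tube(chain$nodes, radii,
                     n_circumferential = n_circumferential)
  # the end rings around the attachment anchors lie half inside the bone;
  # project penetrating surface vertices back onto the obstacle surfaces
  tube$surface$vertices <- project_out(tube$surface$vertices, obstacles)
  tube$surface$bone_label <- name
  structure(list(name = name, centerline = chain,
                 radius_profile = radius_profile, min_offset = min_offset,
                 tube = tube),
            class = "cruciate_model")
}

#' @export
print.cruciate_model <- function(x, ...) {
  cat(sprintf("<cruciate_model> %s: %d segments, min offset %.2f mm, radii %.2f-%.2f mm\n",
              x$name, nrow(x$centerline$nodes) - 1L, x$min_offset,
              min(x$tube$radii), max(x$tube$radii)))
  invisible(x)
}
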
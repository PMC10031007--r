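#' Frenet-Serret frames along a centerline, with rotation-minimizing fallback
#'
#' Tangents come from central finite differences. Where the local curvature
#' exceeds `curvature_min`, the normal is the Frenet normal (derivative of the
#' unit tangent); on straight stretches, where the Frenet frame is undefined,
#' the previous normal is propagated by rotation-minimizing (parallel)
#' transport using the double-reflection construction. Binormal = tangent x
#' normal.
#'
#' @param centerline k x 3 matrix of ordered, distinct points (k >= 2).
#' @param closed logical: treat the centerline as a closed loop (periodic
#'   finite differences, no one-sided end tangents).
#' @param curvature_min curvature threshold (1/mm) below which transport
#'   replaces the Frenet normal.
#' @return list with `tangent`, `normal`, `binormal` (k x 3 each, orthonormal
#'   triads).
#' @export
estimate_frames <- function(centerline, closed = FALSE, curvature_min = 1e-6) {
  P <- as.matrix(centerline)
  k <- nrow(P)
  if (k < 2L) stop("centerline needs at least 2 points")
  seg <- diff(P)
  if (any(rowSums(seg^2) < 1e-24)) {
    stop("duplicated consecutive centerline nodes at position ",
         which(rowSums(seg^2) < 1e-24)[1L])
  }
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) v else v / n
  }
  Tg <- matrix(0, k, 3L)
  if (closed) {
    Tg[1L, ] <- unit(P[2L, ] - P[k, ])
    Tg[k, ] <- unit(P[1L, ] - P[k - 1L, ])
  } else {
    Tg[1L, ] <- unit(seg[1L, ])
    Tg[k, ] <- unit(seg[k - 1L, ])
  }
  if (k > 2L) {
    for (i in 2:(k - 1L)) Tg[i, ] <- unit(P[i + 1L, ] - P[i - 1L, ])
  }
  Nm <- matrix(0, k, 3L)
  Bn <- matrix(0, k, 3L)
  # curvature vector by finite differences of the unit tangent w.r.t. arc length
  ds <- sqrt(rowSums(seg^2))
  curv_vec <- function(i) {
    if (i == 1L) {
      if (closed) (Tg[2L, ] - Tg[k, ]) / (ds[1L] + ds[k - 1L])
      else (Tg[2L, ] - Tg[1L, ]) / ds[1L]
    } else if (i == k) {
      if (closed) (Tg[1L, ] - Tg[k - 1L, ]) / (ds[1L] + ds[k - 1L])
      else (Tg[k, ] - Tg[k - 1L, ]) / ds[k - 1L]
    } else (Tg[i + 1L, ] - Tg[i - 1L, ]) / (ds[i - 1L] + ds[i])
  }
  # initial normal: Frenet where curved, else any vector orthogonal to T
  cv <- curv_vec(1L)
  cv <- cv - sum(cv * Tg[1L, ]) * Tg[1L, ]
  if (sqrt(sum(cv^2)) > curvature_min) {
    Nm[1L, ] <- unit(cv)
  } else {
    ref <- if (abs(Tg[1L, 1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    Nm[1L, ] <- unit(ref - sum(ref * Tg[1L, ]) * Tg[1L, ])
  }
  Bn[1L, ] <- unit(pracma_cross(Tg[1L, ], Nm[1L, ]))
  for (i in 2:k) {
    cv <- curv_vec(i)
    cv <- cv - sum(cv * Tg[i, ]) * Tg[i, ]
    if (sqrt(sum(cv^2)) > curvature_min) {
      n <- unit(cv)
      # keep continuity: never flip by more than 90 degrees
      if (sum(n * Nm[i - 1L, ]) < 0) n <- -n
      Nm[i, ] <- n
    } else {
      # double-reflection rotation-minimizing transport (Wang et al. 2008)
      v1 <- P[i, ] - P[i - 1L, ]
      c1 <- sum(v1 * v1)
      rL <- Nm[i - 1L, ] - (2 / c1) * sum(v1 * Nm[i - 1L, ]) * v1
      tL <- Tg[i - 1L, ] - (2 / c1) * sum(v1 * Tg[i - 1L, ]) * v1
      v2 <- Tg[i, ] - tL
      c2 <- sum(v2 * v2)
      n <- if (c2 > 1e-24) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
      n <- n - sum(n * Tg[i, ]) * Tg[i, ]
      Nm[i, ] <- unit(n)
    }
    Bn[i, ] <- unit(pracma_cross(Tg[i, ], Nm[i, ]))
    # re-orthogonalize the normal
    Nm[i, ] <- unit(pracma_cross(Bn[i, ], Tg[i, ]))
  }
  Bn[1L, ] <- unit(pracma_cross(Tg[1L, ], Nm[1L, ]))
  Nm[1L, ] <- unit(pracma_cross(Bn[1L, ], Tg[1L, ]))
  list(tangent = Tg, normal = Nm, binormal = Bn)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build a variable-radius tube mesh around a centerline
#'
#' Places a ring of `n_circumferential` vertices in each node's
#' normal-binormal plane at the node's radius and triangulates adjacent
#' rings; open centerlines are capped with triangle fans so the surface is
#' watertight (needed when a tube later serves as a wrapping obstacle).
#'
#' @param centerline k x 3 matrix (k >= 2).
#' @param radii per-node radii in mm (> 0), recycled to k.
#' @param n_circumferential ring segment count.
#' @param closed logical: connect the last ring back to the first
#'   (torus-like centerlines) instead of capping.
#' @return object of class `tube_mesh`: list with `centerline`, `radii`,
#'   `frames`, `n_circumferential` and `surface` (a watertight
#'   [knee_mesh()]). Self-intersecting output (curvature radius below the
#'   tube radius) is flagged via attribute `"may_self_intersect"`, not
#'   repaired.
#' @export
build_tube <- function(centerline, radii, n_circumferential = 24L,
                       closed = FALSE) {
  P <- as.matrix(centerline)
  k <- nrow(P)
  if (k < 2L) stop("centerline needs at least 2 nodes")
  radii <- rep_len(as.numeric(radii), k)
  if (any(radii <= 0)) stop("tube radii must be > 0")
  nc <- as.integer(n_circumferential)
  fr <- estimate_frames(P, closed = closed)
  ang <- 2 * pi * (seq_len(nc) - 1L) / nc
  verts <- matrix(0, k * nc, 3L)
  for (i in seq_len(k)) {
    ring <- outer(cos(ang), fr$normal[i, ]) + outer(sin(ang), fr$binormal[i, ])
    verts[(i - 1L) * nc + seq_len(nc), ] <-
      matrix(P[i, ], nc, 3L, byrow = TRUE) + radii[i] * ring
  }
  rid <- function(i, j) (i - 1L) * nc + j  # ring i, segment j
  tris <- vector("list", 0L)
  last <- if (closed) k else k - 1L
  for (i in seq_len(last)) {
    i2 <- if (i == k) 1L else i + 1L
    for (j in seq_len(nc)) {
      j2 <- if (j == nc) 1L else j + 1L
      tris[[length(tris) + 1L]] <- c(rid(i, j), rid(i2, j), rid(i2, j2))
      tris[[length(tris) + 1L]] <- c(rid(i, j), rid(i2, j2), rid(i, j2))
    }
  }
  if (!closed) {
    # end caps: fan around apex vertices at the centerline endpoints
    apex1 <- nrow(verts) + 1L
    apex2 <- nrow(verts) + 2L
    verts <- rbind(verts, P[1L, ], P[k, ])
    for (j in seq_len(nc)) {
      j2 <- if (j == nc) 1L else j + 1L
      tris[[length(tris) + 1L]] <- c(apex1, rid(1L, j), rid(1L, j2))
      tris[[length(tris) + 1L]] <- c(apex2, rid(k, j2), rid(k, j))
    }
  }
  surface <- knee_mesh(verts, do.call(rbind, tris), bone_label = "tube")
  if (mesh_volume(surface) < 0) {
    surface$faces <- surface$faces[, c(1L, 3L, 2L)]
  }
  # curvature-to-radius self-intersection flag
  flag <- FALSE
  if (k > 2L) {
    for (i in 2:(k - 1L)) {
      e1 <- P[i, ] - P[i - 1L, ]
      e2 <- P[i + 1L, ] - P[i, ]
      cosang <- sum(e1 * e2) / (sqrt(sum(e1^2)) * sqrt(sum(e2^2)))
      theta <- acos(pmin(pmax(cosang, -1), 1))
      if (theta > 1e-9) {
        rcurv <- 0.5 * (sqrt(sum(e1^2)) + sqrt(sum(e2^2))) / theta
        if (rcurv < radii[i]) { flag <- TRUE; break }
      }
    }
  }
  out <- structure(list(centerline = P, radii = radii, frames = fr,
                        n_circumferential = nc, closed = closed,
                        surface = surface),
                   class = "tube_mesh")
  attr(out, "may_self_intersect") <- flag
  out
}

#' @export
print.tube_mesh <- function(x, ...) {
  cat(sprintf("<tube_mesh> %d nodes, radii %.2f-%.2f mm, %d segments%s\n",
              nrow(x$centerline), min(x$radii), max(x$radii),
              x$n_circumferential,
              if (isTRUE(attr(x, "may_self_intersect"))) " [may self-intersect]" else ""))
  invisible(x)
}

#' Per-node radii from a polynomial profile
#'
#' Evaluates the profile at equidistant relative arc-length stations and
#' floors the result at a minimum radius; floored stations are reported in a
#' warning.
#'
#' @param profile a `polynomial_profile` defined on `[0, 1]`.
#' @param n_nodes number of stations.
#' @param floor_radius minimum admissible radius in mm.
#' @return numeric vector of radii.
#' @export
radius_profile_from_polynomial <- function(profile, n_nodes,
                                           floor_radius = 0.1) {
  s <- seq(0, 1, length.out = n_nodes)
  r <- eval_profile(profile, s)
  if (all(r <= 0)) stop("radius profile is non-positive everywhere")
  low <- which(r < floor_radius)
  if (length(low)) {
    warning("radius floored at ", length(low), " station(s): ",
            paste(utils::head(low, 5L), collapse = ", "),
            if (length(low) > 5L) ", ..." else "")
    r[low] <- floor_radius
  }
  r
}

#' Chordal inflation compensating a discretised tube obstacle
#'
#' A ring of `n` vertices at radius `r` has inscribed radius `r cos(pi/n)`;
#' inflating the polygonal surface by `r (1 - cos(pi/n))` restores clearance
#' guarantees with respect to the ideal round tube.
#' @param tube a `tube_mesh`.
#' @return inflation offset in mm.
#' @export
tube_chordal_inflation <- function(tube) {
  max(tube$radii) * (1 - cos(pi / tube$n_circumferential))
}
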
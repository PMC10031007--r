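#' Corresponded triangle mesh
#'
#' Constructs the mesh container used throughout the package. Meshes of the
#' same bone across subjects are expected to share vertex count and ordering
#' ("corresponded" meshes), so vertex `i` refers to the same anatomical
#' location in every case. Coordinates are in millimetres, right-handed frame;
#' face indices are 1-based.
#'
#' @param vertices numeric matrix, n x 3 (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices with
#'   counter-clockwise (outward) winding for closed meshes.
#' @param bone_label one of `"femur"`, `"tibia_fibula"`, `"patella"`, or
#'   another free label for derived surfaces (cartilage, tube, meniscus).
#' @param case_id character identifier of the case the mesh belongs to.
#' @return an object of class `knee_mesh`.
#' @export
knee_mesh <- function(vertices, faces, bone_label = "unknown", case_id = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) == 0L) stop("empty mesh: no vertices")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      bad <- which(faces < 1L | faces > nrow(vertices), arr.ind = TRUE)[1L, ]
      stop(sprintf("face %d refers to vertex index %d outside [1, %d]",
                   bad[1L], faces[bad[1L], bad[2L]], nrow(vertices)))
    }
    degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    if (any(degen)) {
      stop(sprintf("degenerate face %d: repeated vertex index", which(degen)[1L]))
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 bone_label = bone_label, case_id = case_id),
            class = "knee_mesh")
}

#' @export
print.knee_mesh <- function(x, ...) {
  cat(sprintf("<knee_mesh> %s%s: %d vertices, %d faces\n", x$bone_label,
              if (nzchar(x$case_id)) paste0(" [", x$case_id, "]") else "",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a `knee_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Check that two meshes are vertex-corresponded
#'
#' Corresponded meshes share vertex count and the exact face array; only
#' vertex positions differ.
#' @param a,b `knee_mesh` objects.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_correspondence <- function(a, b) {
  if (nrow(a$vertices) != nrow(b$vertices)) {
    stop("correspondence violation: vertex counts differ (",
         nrow(a$vertices), " vs ", nrow(b$vertices), ")")
  }
  if (!identical(dim(a$faces), dim(b$faces)) || !all(a$faces == b$faces)) {
    stop("correspondence violation: face arrays differ")
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Mesh I/O: ASCII PLY (preferred: preserves vertex order), OBJ, STL.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = "PLY", obj = "OBJ", stl = "STL",
         stop("cannot infer mesh format from extension '", ext, "'"))
}

#' Read a triangle surface mesh
#'
#' Supports ASCII PLY (preferred, preserves vertex ordering and hence
#' correspondence), Wavefront OBJ, and ASCII STL. STL stores no shared
#' vertices, so STL input is vertex-merged with a stated tolerance and is not
#' correspondence-safe.
#'
#' @param path file path.
#' @param format `"PLY"`, `"STL"`, or `"OBJ"`; inferred from the extension if
#'   missing.
#' @param bone_label,case_id metadata attached to the mesh.
#' @param merge_tol vertex merge tolerance in mm for STL input.
#' @return a [knee_mesh()].
#' @export
read_mesh <- function(path, format = guess_format(path), bone_label = "unknown",
                      case_id = "", merge_tol = 1e-6) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- toupper(format)
  res <- switch(format,
    PLY = read_ply(path),
    OBJ = read_obj(path),
    STL = read_stl(path, merge_tol),
    stop("unsupported mesh format: ", format))
  knee_mesh(res$vertices, res$faces, bone_label = bone_label, case_id = case_id)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply") {
    stop("not a PLY file: ", path)
  }
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("PLY header not terminated: ", path)
  hdr <- lines[seq_len(hdr_end)]
  if (any(grepl("^format\\s+binary", hdr))) {
    stop("binary PLY not supported; export as ASCII: ", path)
  }
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || nv == 0L) stop("empty or malformed PLY: no vertices in ", path)
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                  function(s) as.numeric(s[1:3]), numeric(3)))
  faces <- NULL
  if (!is.na(nf) && nf > 0L) {
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fl, function(s) {
      k <- as.integer(s[1L])
      if (k != 3L) stop("non-triangular face (", k, " vertices) in ", path)
      as.integer(s[2:4]) + 1L  # PLY is 0-based on disk
    }, integer(3)))
  } else {
    faces <- matrix(integer(0), 0L, 3L)
  }
  list(vertices = vtx, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("empty or malformed OBJ: no vertices in ", path)
  vtx <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(s) as.numeric(s[2:4]), numeric(3)))
  faces <- if (length(fl)) {
    t(vapply(strsplit(trimws(fl), "\\s+"), function(s) {
      if (length(s) != 4L) stop("non-triangular face in ", path)
      as.integer(sub("/.*", "", s[2:4]))  # OBJ is 1-based on disk
    }, integer(3)))
  } else matrix(integer(0), 0L, 3L)
  list(vertices = vtx, faces = faces)
}

read_stl <- function(path, merge_tol) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*solid", lines[1L]))) {
    stop("binary STL not supported; export as ASCII: ", path)
  }
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL: ", path)
  }
  raw <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(s) as.numeric(s[2:4]), numeric(3)))
  key <- apply(round(raw / merge_tol), 1L, paste, collapse = "_")
  idx <- match(key, unique(key))
  vtx <- raw[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = vtx, faces = faces)
}

#' Write a triangle surface mesh
#'
#' @param mesh a [knee_mesh()].
#' @param path output file path.
#' @param format `"PLY"`, `"OBJ"` or `"STL"`; inferred from the extension if
#'   missing.
#' @param digits significant digits written for coordinates.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = guess_format(path), digits = 9L) {
  format <- toupper(format)
  fmt <- paste0("%.", digits, "g")
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "PLY") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf(paste(fmt, fmt, fmt), v[, 1], v[, 2], v[, 3]), con)
    if (nrow(f)) writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (format == "OBJ") {
    writeLines(sprintf(paste("v", fmt, fmt, fmt), v[, 1], v[, 2], v[, 3]), con)
    if (nrow(f)) writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "STL") {
    writeLines("solid mesh", con)
    fn <- face_normals(mesh)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf(paste("facet normal", fmt, fmt, fmt),
                         fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf(paste("    vertex", fmt, fmt, fmt), p[1], p[2], p[3]), con)
      }
      writeLines(c("  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else stop("unsupported mesh format: ", format)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Normals and proximity queries

#' Per-face unit normals
#' @param mesh a [knee_mesh()].
#' @return m x 3 matrix of unit normals following face winding.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) stop("zero-area face ", which(len == 0)[1L])
  n / len
}

#' Per-vertex unit normals (angle-weighted)
#'
#' Face normals are accumulated at each vertex weighted by the incident corner
#' angle, which is robust to triangulation density on quasi-isometric meshes,
#' then normalized. Orientation is outward for closed meshes with consistent
#' counter-clockwise winding.
#'
#' @param mesh a [knee_mesh()].
#' @return n x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  acc <- matrix(0, nrow(v), 3L)
  corner_angle <- function(i0, i1, i2) {
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    c1 <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)), .Machine$double.xmin)
    acos(pmin(pmax(c1, -1), 1))
  }
  for (k in 1:3) {
    i0 <- f[, k]
    i1 <- f[, k %% 3L + 1L]
    i2 <- f[, (k + 1L) %% 3L + 1L]
    w <- corner_angle(i0, i1, i2)
    for (d in 1:3) {
      acc[, d] <- acc[, d] + unname(tapply(w * fn[, d], factor(i0, levels = seq_len(nrow(v))), sum, default = 0))
    }
  }
  len <- sqrt(rowSums(acc^2))
  zero <- len < .Machine$double.eps * 100
  if (any(zero & tabulate(f, nbins = nrow(v)) > 0)) {
    stop("degenerate one-ring at vertex ", which(zero)[1L])
  }
  len[zero] <- 1
  acc / len
}

#' Closest point on a mesh surface
#'
#' Exhaustive point-to-triangle minimisation; ties are broken by the lowest
#' face index, making the query deterministic.
#'
#' @param mesh a [knee_mesh()].
#' @param q a 3-vector or k x 3 matrix of query points.
#' @return for a single point, a list with `point`, `face_index`, `distance`
#'   (unsigned, mm) and `inside` (winding-number test for closed meshes, `NA`
#'   otherwise); for a matrix, a list of such results.
#' @export
closest_point <- function(mesh, q) {
  qm <- if (is.matrix(q)) q else matrix(q, 1L, 3L)
  res <- cpp_closest_points(mesh$vertices, mesh$faces, qm)
  wt <- is_watertight(mesh)
  inside <- if (wt) cpp_winding_number(mesh$vertices, mesh$faces, qm) > 0.5 else rep(NA, nrow(qm))
  out <- lapply(seq_len(nrow(qm)), function(i) {
    list(point = res$point[i, ], face_index = res$face[i],
         distance = res$distance[i],
         inside = inside[i] & res$distance[i] > 1e-9)
  })
  if (!is.matrix(q)) out[[1L]] else out
}

#' Generalized winding number of points with respect to a mesh
#'
#' @param mesh a [knee_mesh()].
#' @param q k x 3 matrix (or 3-vector) of query points.
#' @return numeric vector; approximately 1 inside a watertight mesh, 0 outside.
#' @export
winding_number <- function(mesh, q) {
  qm <- if (is.matrix(q)) q else matrix(q, 1L, 3L)
  cpp_winding_number(mesh$vertices, mesh$faces, qm)
}

#' Point-in-mesh test
#'
#' Uses the generalized winding number. A point within `tol` of the surface is
#' reported as outside, so that projection onto the surface is idempotent.
#'
#' @param mesh a closed (watertight) [knee_mesh()].
#' @param q 3-vector or k x 3 matrix.
#' @param tol surface band half-width in mm.
#' @return logical vector.
#' @export
is_inside <- function(mesh, q, tol = 1e-6) {
  if (!is_watertight(mesh)) {
    stop("mesh is not watertight; signed inside/outside queries are undefined, ",
         "use unsigned closest_point() instead")
  }
  qm <- if (is.matrix(q)) q else matrix(q, 1L, 3L)
  w <- cpp_winding_number(mesh$vertices, mesh$faces, qm)
  d <- cpp_closest_points(mesh$vertices, mesh$faces, qm)$distance
  w > 0.5 & d > tol
}

#' Watertightness check
#'
#' A mesh is watertight when every edge is shared by exactly two faces with
#' opposite orientation.
#' @param mesh a [knee_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  dir_key <- paste(he[, 1], he[, 2])
  !any(duplicated(dir_key))  # each directed edge once => consistent winding
}

#' Signed volume enclosed by a watertight mesh
#' @param mesh a closed [knee_mesh()] with outward winding.
#' @return volume in mm^3 (positive for outward winding).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Vertex adjacency list
#' @param mesh a [knee_mesh()].
#' @return list of integer vectors, neighbours of each vertex.
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  both <- rbind(he, he[, c(2, 1)])
  adj <- split(both[, 2], factor(both[, 1], levels = seq_len(nrow(mesh$vertices))))
  lapply(adj, function(x) sort(unique(x)))
}

#' Evenly spread sample points on a mesh surface
#'
#' Deterministic per-face sampling used by penetration and intersection scans:
#' each face contributes its vertices, edge midpoints and centroid, plus a
#' subdivision refined until sample spacing is below `spacing`.
#'
#' @param mesh a [knee_mesh()].
#' @param spacing target maximum sample spacing (mm).
#' @return k x 3 matrix of surface points.
#' @export
sample_surface_points <- function(mesh, spacing = 1) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  longest <- sqrt(pmax(rowSums(e^2), rowSums(e2^2),
                       rowSums((e - e2)^2)))
  pts <- list(v)
  for (i in seq_len(nrow(f))) {
    k <- ceiling(longest[i] / spacing)
    if (k < 2) next
    bar <- expand.grid(a = 0:k, b = 0:k)
    bar <- bar[bar$a + bar$b <= k & (bar$a > 0 | bar$b > 0) &
                 (bar$a + bar$b < k | (bar$a > 0 & bar$b > 0)), , drop = FALSE]
    if (nrow(bar) == 0) next
    u <- bar$a / k
    w <- bar$b / k
    p <- outer(1 - u - w, v[f[i, 1], ]) + outer(u, v[f[i, 2], ]) + outer(w, v[f[i, 3], ])
    pts[[length(pts) + 1L]] <- p
  }
  do.call(rbind, pts)
}

## ---------------------------------------------------------------------------
## Splines

#' Interpolating 3D spline through ordered control points
#'
#' Natural cubic interpolation per coordinate against the normalized
#' chord-length parameter; closed curves use periodic end conditions. The
#' paper's source tooling exposes only "spline" curves; the natural cubic with
#' chord-length parameterization is this package's stated choice.
#'
#' @param points k x 3 matrix of ordered control points; no coincident
#'   consecutive points.
#' @param closed logical; closed curves need at least 3 points.
#' @return an object of class `knee_spline` evaluable on `[0, 1]`.
#' @export
fit_spline <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  need <- if (closed) 3L else 2L
  if (nrow(points) < need) {
    stop("spline needs at least ", need, " points (", nrow(points), " given)")
  }
  pts <- if (closed) rbind(points, points[1L, , drop = FALSE]) else points
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg < 1e-12)) stop("coincident consecutive control points at position ",
                             which(seg < 1e-12)[1L])
  t <- c(0, cumsum(seg)) / sum(seg)
  method <- if (closed) "periodic" else "natural"
  fx <- stats::splinefun(t, pts[, 1], method = method)
  fy <- stats::splinefun(t, pts[, 2], method = method)
  fz <- stats::splinefun(t, pts[, 3], method = method)
  structure(list(control_points = points, closed = closed, knots = t,
                 fx = fx, fy = fy, fz = fz),
            class = "knee_spline")
}

#' Evaluate a spline
#' @param spline a `knee_spline`.
#' @param t parameter values in `[0, 1]` (closed splines evaluate periodically).
#' @return length(t) x 3 matrix.
#' @export
spline_eval <- function(spline, t) {
  if (spline$closed) t <- t %% 1
  cbind(spline$fx(t), spline$fy(t), spline$fz(t))
}

#' Spline arc length
#' @param spline a `knee_spline`.
#' @param t0,t1 parameter interval.
#' @param n quadrature resolution.
#' @return arc length in mm.
#' @export
spline_length <- function(spline, t0 = 0, t1 = 1, n = 2048L) {
  tt <- seq(t0, t1, length.out = n + 1L)
  p <- spline_eval(spline, tt)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Resample a spline at equal arc-length stations
#' @param spline a `knee_spline`.
#' @param n number of stations.
#' @param t_start parameter at which the first station is placed (closed
#'   splines only).
#' @return n x 3 matrix of points.
#' @export
spline_resample <- function(spline, n, t_start = 0) {
  dense <- seq(0, 1, length.out = 4096L)
  p <- spline_eval(spline, t_start + dense)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  s <- s / s[length(s)]
  targets <- if (spline$closed) seq(0, 1, length.out = n + 1L)[-(n + 1L)] else
    seq(0, 1, length.out = n)
  tq <- stats::approx(s, t_start + dense, xout = targets, ties = "ordered")$y
  spline_eval(spline, tq)
}
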
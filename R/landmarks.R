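#' Named landmark sets on corresponded meshes
#'
#' A landmark set maps anatomical names (e.g. `"LCL_origin_femur"`,
#' `"MM_anterior_root"`) to groups of vertex indices on a named bone. Because
#' meshes are corresponded, indices annotated once on a template transfer to
#' any case of the same bone without further geometric computation.
#'
#' @param entries named list; each element a list with `bone` (character) and
#'   `indices` (integer vector, 1-based).
#' @param provenance `"manual"`, `"averaged"` or `"transferred"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(entries, provenance = "manual") {
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("landmark entries must have unique names")
  }
  entries <- lapply(entries, function(e) {
    list(bone = as.character(e$bone), indices = as.integer(e$indices))
  })
  structure(list(entries = entries, provenance = provenance),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d entries (%s)\n", length(x$entries), x$provenance))
  invisible(x)
}

#' Anchor free points to their nearest mesh vertices
#'
#' Establishes landmark locations in relation to the bony surface: each point
#' is replaced by the index of its nearest vertex, ties broken by the lowest
#' index.
#'
#' @param mesh a [knee_mesh()].
#' @param points k x 3 matrix (or 3-vector) of points in mm.
#' @return integer vector of vertex indices.
#' @export
anchor_points <- function(mesh, points) {
  pm <- if (is.matrix(points)) points else matrix(points, 1L, 3L)
  v <- mesh$vertices
  vapply(seq_len(nrow(pm)), function(i) {
    d2 <- (v[, 1] - pm[i, 1])^2 + (v[, 2] - pm[i, 2])^2 + (v[, 3] - pm[i, 3])^2
    which.min(d2)  # which.min returns the first (lowest) index on ties
  }, integer(1))
}

#' Average one landmark across cases
#'
#' Component-wise arithmetic centroid of the same landmark observed in several
#' cases; used to pool manual annotations before anchoring the average on the
#' template.
#'
#' @param cases k x 3 matrix, one row per case.
#' @return 3-vector.
#' @export
average_landmark <- function(cases) {
  cases <- if (is.matrix(cases)) cases else matrix(cases, ncol = 3L)
  if (nrow(cases) == 0L) stop("no cases to average")
  colMeans(cases)
}

#' Transfer landmarks to a corresponded target mesh
#'
#' Pure index lookup: returns the target's vertex coordinates at the stored
#' indices. No geometric computation is involved, which is what keeps the
#' transfer anatomically consistent across the corresponded cohort.
#'
#' @param set a [landmark_set()].
#' @param target a [knee_mesh()] whose `bone_label` matches the requested
#'   entries.
#' @param names which entries to transfer; default all entries on the target
#'   bone.
#' @return named list of k x 3 coordinate matrices.
#' @export
transfer_landmarks <- function(set, target, names = NULL) {
  sel <- if (is.null(names)) {
    names(set$entries)[vapply(set$entries, function(e) e$bone == target$bone_label, logical(1))]
  } else names
  out <- lapply(sel, function(nm) {
    e <- set$entries[[nm]]
    if (is.null(e)) stop("unknown landmark: ", nm)
    if (e$bone != target$bone_label) {
      stop(sprintf("landmark '%s' is on bone '%s', target mesh is '%s'",
                   nm, e$bone, target$bone_label))
    }
    if (any(e$indices < 1L | e$indices > nrow(target$vertices))) {
      stop(sprintf("landmark '%s' index out of range for %d-vertex mesh",
                   nm, nrow(target$vertices)))
    }
    target$vertices[e$indices, , drop = FALSE]
  })
  stats::setNames(out, sel)
}

#' Single attachment point of a (possibly multi-vertex) landmark
#'
#' Attachment areas are stored as index groups; their representative point is
#' the centroid of the transferred vertices.
#' @param set a [landmark_set()].
#' @param target a [knee_mesh()].
#' @param name landmark name.
#' @return 3-vector.
#' @export
landmark_point <- function(set, target, name) {
  colMeans(transfer_landmarks(set, target, name)[[1L]])
}

#' Replace one landmark entry (anatomical-variant modeling)
#'
#' Re-assigning a root or attachment reference (e.g. moving a meniscal
#' anterior root insertion to model an anatomical insertion variant) is a pure
#' landmark swap; all downstream geometry then follows the new reference.
#'
#' @param set a [landmark_set()].
#' @param name entry to replace.
#' @param new_indices integer vertex indices.
#' @param bone optional new bone label (defaults to the existing one).
#' @return a new [landmark_set()] with only the named entry replaced.
#' @export
swap_variant <- function(set, name, new_indices, bone = NULL) {
  if (is.null(set$entries[[name]])) stop("unknown landmark: ", name)
  set$entries[[name]]$indices <- as.integer(new_indices)
  if (!is.null(bone)) set$entries[[name]]$bone <- bone
  set
}

#' Read / write landmark sets as JSON
#'
#' Files are JSON objects keyed by anatomical name, each with `bone` and
#' `indices`. A top-level `"zero_based": true` flag marks files authored
#' against 0-based indexing; such indices are shifted to 1-based at load.
#'
#' @param path JSON file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  zero_based <- isTRUE(obj$zero_based)
  obj$zero_based <- NULL
  provenance <- if (!is.null(obj$provenance)) obj$provenance else "manual"
  obj$provenance <- NULL
  entries <- lapply(obj, function(e) {
    idx <- as.integer(e$indices)
    list(bone = e$bone, indices = if (zero_based) idx + 1L else idx)
  })
  landmark_set(entries, provenance = provenance)
}

#' @rdname read_landmarks
#' @param set a [landmark_set()].
#' @export
write_landmarks <- function(set, path) {
  obj <- c(set$entries, list(provenance = set$provenance, zero_based = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
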
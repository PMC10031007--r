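#' Per-vertex cartilage thickness map
#'
#' A thickness map assigns a non-negative thickness (mm) to every vertex of a
#' named articular region of a bone mesh. Thickness is measured along the
#' bone vertex normal; boundary ("edge") vertices of the region are sealed to
#' zero so a projected cartilage surface attaches smoothly to the bone. The
#' map carries the femoral length of its case (or the cohort mean) so maps
#' can be scaled between differently sized knees.
#'
#' @param bone_label bone the map lives on.
#' @param region integer vertex indices of the articular region (1-based).
#' @param values numeric vector of thicknesses, one per region vertex.
#' @param edge_indices subset of `region` forming its boundary.
#' @param reference_length femoral length (mm) the values refer to.
#' @param region_name optional label (e.g. `"medial_plateau"`).
#' @return object of class `thickness_map`.
#' @export
thickness_map <- function(bone_label, region, values, edge_indices = integer(),
                          reference_length = NA_real_, region_name = "") {
  region <- as.integer(region)
  if (length(values) != length(region)) {
    stop("values and region must have equal length")
  }
  if (any(values < -1e-12)) stop("thickness values must be >= 0")
  if (!all(edge_indices %in% region)) stop("edge_indices must be a subset of region")
  structure(list(bone_label = bone_label, region = region,
                 values = pmax(as.numeric(values), 0),
                 edge_indices = as.integer(edge_indices),
                 reference_length = reference_length,
                 region_name = region_name),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s/%s: %d vertices, mean %.2f mm (ref length %.1f mm)\n",
              x$bone_label, x$region_name, length(x$region), mean(x$values),
              x$reference_length))
  invisible(x)
}

#' Boundary vertices of a mesh region
#'
#' A region vertex is an edge vertex when it has at least one mesh neighbour
#' outside the region. Regions covering a closed component have no boundary.
#'
#' @param mesh a [knee_mesh()].
#' @param region integer vertex indices.
#' @return integer vector (subset of `region`).
#' @export
region_edges <- function(mesh, region) {
  inreg <- logical(nrow(mesh$vertices))
  inreg[region] <- TRUE
  adj <- vertex_adjacency(mesh)
  region[vapply(region, function(i) any(!inreg[adj[[i]]]), logical(1))]
}

#' Measure cartilage thickness from corresponded bone and cartilage meshes
#'
#' For every region vertex a ray is cast from the bone vertex along its
#' outward normal; the distance to the first intersection with the cartilage
#' surface is the node-specific thickness. Rays that miss within `cutoff`
#' fall back to the distance to the corresponding cartilage vertex (the
#' meshes are vertex-corresponded by construction). Inward-displaced
#' (negative) cases clamp to zero: cartilage cannot lie inside bone.
#'
#' @param bone,cartilage vertex-corresponded [knee_mesh()] objects.
#' @param region integer vertex indices of the articular region.
#' @param reference_length femoral length (mm) recorded on the map.
#' @param cutoff maximum ray length in mm before the fallback applies.
#' @param region_name label stored on the map.
#' @return a [thickness_map()] (unsealed; apply [seal_edges()]).
#' @export
compute_thickness <- function(bone, cartilage, region,
                              reference_length = NA_real_, cutoff = 50,
                              region_name = "") {
  check_correspondence(bone, cartilage)
  region <- as.integer(region)
  if (length(region) == 0L) stop("empty region")
  nrm <- vertex_normals(bone)
  origins <- bone$vertices[region, , drop = FALSE]
  dirs <- nrm[region, , drop = FALSE]
  hit <- cpp_ray_mesh(cartilage$vertices, cartilage$faces, origins, dirs)
  vals <- hit$t
  miss <- !is.finite(vals) | vals > cutoff
  if (any(miss)) {
    diffv <- cartilage$vertices[region[miss], , drop = FALSE] - origins[miss, , drop = FALSE]
    d <- sqrt(rowSums(diffv^2))
    inward <- rowSums(diffv * dirs[miss, , drop = FALSE]) < 0
    d[inward] <- 0
    vals[miss] <- d
  }
  thickness_map(bone$bone_label, region, pmax(vals, 0),
                edge_indices = region_edges(bone, region),
                reference_length = reference_length,
                region_name = region_name)
}

#' Seal region edges to zero thickness
#'
#' Adjusts the thickness at the region's boundary vertices to zero so the
#' predicted cartilage surface attaches smoothly to the bone. Idempotent; a
#' region without boundary is returned unchanged.
#'
#' @param map a [thickness_map()].
#' @return the sealed [thickness_map()].
#' @export
seal_edges <- function(map) {
  if (length(map$edge_indices)) {
    map$values[match(map$edge_indices, map$region)] <- 0
  }
  map
}

#' Mean thickness map across cases, normalized by femoral length
#'
#' Each case's values are first normalized to the cohort-mean femoral length
#' (multiplied by `mean(lengths) / case_length`), then averaged per vertex.
#' The returned map stores the cohort mean as its `reference_length`;
#' prediction for a new knee rescales by `target_length / reference_length`.
#'
#' @param maps list of [thickness_map()] objects sharing bone and region,
#'   each carrying its case `reference_length`.
#' @return the mean [thickness_map()].
#' @export
mean_map <- function(maps) {
  if (length(maps) == 0L) stop("no maps to average")
  r0 <- maps[[1L]]$region
  lens <- vapply(maps, `[[`, numeric(1), "reference_length")
  if (any(!is.finite(lens) | lens <= 0)) {
    stop("every map must carry a positive reference_length")
  }
  for (m in maps[-1L]) {
    if (!identical(m$region, r0) || m$bone_label != maps[[1L]]$bone_label) {
      stop("maps mix regions or bones")
    }
  }
  lbar <- mean(lens)
  vals <- rowMeans(vapply(seq_along(maps),
                          function(i) maps[[i]]$values * (lbar / lens[i]),
                          numeric(length(r0))))
  thickness_map(maps[[1L]]$bone_label, r0, vals,
                edge_indices = maps[[1L]]$edge_indices,
                reference_length = lbar,
                region_name = maps[[1L]]$region_name)
}

#' Femoral length from designated landmarks
#'
#' Euclidean distance between two designated length landmarks (vertex-index
#' entries of a landmark set), so partial distal meshes work as long as the
#' landmarks exist. Multi-vertex landmark groups reduce to their centroid.
#'
#' @param femur the femur [knee_mesh()].
#' @param landmarks a [landmark_set()] containing the two entries.
#' @param entry_names character vector of length 2.
#' @return length in mm.
#' @export
femoral_length <- function(femur, landmarks,
                           entry_names = c("femur_length_proximal",
                                           "femur_length_distal")) {
  if (length(entry_names) != 2L) stop("exactly two landmark names required")
  p1 <- landmark_point(landmarks, femur, entry_names[1L])
  p2 <- landmark_point(landmarks, femur, entry_names[2L])
  sqrt(sum((p1 - p2)^2))
}

#' Predict a cartilage surface by normal projection of a thickness map
#'
#' Returns a copy of the bone mesh whose region vertices are displaced
#' outward along their vertex normals by the map values scaled with
#' `target_length / reference_length`. Edge values are zero after sealing, so
#' the surface attaches smoothly; non-region vertices are untouched and
#' displacements are never negative.
#'
#' @param bone the target bone [knee_mesh()].
#' @param mean a (sealed) mean [thickness_map()].
#' @param target_length femoral length of the target knee (mm); defaults to
#'   the map's reference length (no rescaling).
#' @return a [knee_mesh()] of the combined bone + cartilage outer surface,
#'   vertex-corresponded with `bone`.
#' @export
predict_cartilage <- function(bone, mean, target_length = mean$reference_length) {
  if (any(mean$region < 1L | mean$region > nrow(bone$vertices))) {
    stop("map region does not fit the bone mesh")
  }
  scale <- target_length / mean$reference_length
  if (!is.finite(scale)) scale <- 1
  disp <- pmax(mean$values * scale, 0)
  nrm <- vertex_normals(bone)
  out <- bone
  out$vertices[mean$region, ] <- bone$vertices[mean$region, , drop = FALSE] +
    disp * nrm[mean$region, , drop = FALSE]
  out$bone_label <- bone$bone_label
  out$case_id <- bone$case_id
  out
}

#' Relative error map (error over local mean thickness)
#'
#' Point-dependent errors are expressed relative to the point-dependent mean
#' thickness. Vertices whose mean thickness falls below `floor` (sealed
#' edges) are reported as `NA` rather than divided.
#'
#' @param error numeric vector of per-vertex errors (mm), aligned with the
#'   map's region.
#' @param mean a [thickness_map()].
#' @param floor minimum thickness (mm) for the ratio to be defined.
#' @return numeric vector of ratios with `NA` where undefined.
#' @export
relative_error_map <- function(error, mean, floor = 0.05) {
  if (length(error) != length(mean$region)) {
    stop("error vector does not match the map region")
  }
  out <- error / mean$values
  out[mean$values < floor] <- NA_real_
  out
}

#' Read / write thickness maps (CSV + JSON sidecar)
#'
#' The CSV holds columns `vertex_index`, `thickness_mm`; the JSON sidecar
#' (same path with extension `.json`) records bone, region name, edge indices
#' and reference length.
#'
#' @param map a [thickness_map()].
#' @param path CSV file path.
#' @return `path` (write) or a [thickness_map()] (read).
#' @export
write_thickness_map <- function(map, path) {
  utils::write.csv(data.frame(vertex_index = map$region,
                              thickness_mm = map$values),
                   path, row.names = FALSE)
  side <- list(bone = map$bone_label, region_name = map$region_name,
               reference_length = map$reference_length,
               edge_indices = map$edge_indices)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thickness_map
#' @export
read_thickness_map <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  thickness_map(side$bone, df$vertex_index, df$thickness_mm,
                edge_indices = as.integer(side$edge_indices),
                reference_length = side$reference_length,
                region_name = side$region_name)
}
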
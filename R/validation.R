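#' Surface-distance report
#'
#' Bundles per-point distances with the three validation metrics: RMSE (the
#' square root of the average of all squared distances), ASD (the average of
#' all distances) and HD (the maximum distance). By the power-mean
#' inequality `asd <= rmse <= hd` always holds.
#'
#' @param distances non-negative numeric vector of per-point distances (mm).
#' @return object of class `distance_report` with `distances`, `rmse`, `asd`,
#'   `hd` and `n`.
#' @export
distance_report <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) == 0L) stop("no distances to summarise")
  if (any(d < 0)) stop("distances must be >= 0")
  structure(list(distances = d, rmse = sqrt(mean(d^2)), asd = mean(d),
                 hd = max(d), n = length(d)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> n=%d  RMSE %.3f  ASD %.3f  HD %.3f mm\n",
              x$n, x$rmse, x$asd, x$hd))
  invisible(x)
}

#' Compare reference points against a predicted surface or point set
#'
#' Nearest-neighbour, one-directional comparison: for each reference point
#' the distance to the nearest predicted point (point-set input) or to the
#' predicted surface (mesh input) enters the metrics. A symmetric variant
#' pools both directions.
#'
#' @param predicted a [knee_mesh()] or a k x 3 point matrix.
#' @param reference k x 3 matrix of reference points.
#' @param symmetric logical; pool reference-to-predicted and
#'   predicted-to-reference distances.
#' @return a [distance_report()].
#' @export
compare_points_to_surface <- function(predicted, reference, symmetric = FALSE) {
  reference <- as.matrix(reference)
  if (nrow(reference) == 0L) stop("empty reference set")
  one_way <- function(pred, ref) {
    if (inherits(pred, "knee_mesh")) {
      cpp_closest_points(pred$vertices, pred$faces, ref)$distance
    } else {
      pred <- as.matrix(pred)
      if (nrow(pred) == 0L) stop("empty predicted set")
      vapply(seq_len(nrow(ref)), function(i) {
        sqrt(min((pred[, 1] - ref[i, 1])^2 + (pred[, 2] - ref[i, 2])^2 +
                   (pred[, 3] - ref[i, 3])^2))
      }, numeric(1))
    }
  }
  d <- one_way(predicted, reference)
  if (symmetric) {
    pred_pts <- if (inherits(predicted, "knee_mesh")) predicted$vertices else as.matrix(predicted)
    ref_target <- reference
    d <- c(d, one_way(ref_target, pred_pts))
  }
  distance_report(d)
}

#' Compare two thickness maps in value space
#'
#' Feeds the per-vertex absolute thickness differences of two maps over the
#' same region into the metric formulas (value-space, not surface-space).
#'
#' @param predicted,measured [thickness_map()] objects on the same region.
#' @return a [distance_report()].
#' @export
compare_thickness_maps <- function(predicted, measured) {
  if (!identical(predicted$region, measured$region)) {
    stop("thickness maps cover different regions")
  }
  distance_report(abs(predicted$values - measured$values))
}

#' Leave-one-out experiment driver
#'
#' For each case `i`, a model is built from all other cases, case `i` is
#' predicted from it, and the prediction is compared with the case's own
#' measurement. The pooled summary reports median and range per metric,
#' mirroring the convention of leave-one-out validation tables.
#'
#' @param cohort list of cases (any structure the callbacks understand).
#' @param builder `function(training_cases) -> model`.
#' @param predictor `function(model, case) -> prediction`.
#' @param comparator `function(prediction, case) -> distance_report`.
#' @return list with `per_case` (list of [distance_report()]s) and `pooled`
#'   (data frame of median / min / max per metric).
#' @export
leave_one_out <- function(cohort, builder, predictor, comparator) {
  n <- length(cohort)
  if (n < 2L) stop("leave-one-out needs at least 2 cases")
  per_case <- lapply(seq_len(n), function(i) {
    model <- builder(cohort[-i])
    pred <- predictor(model, cohort[[i]])
    comparator(pred, cohort[[i]])
  })
  metric <- function(name) vapply(per_case, `[[`, numeric(1), name)
  pooled <- data.frame(
    metric = c("rmse", "asd", "hd"),
    median = c(stats::median(metric("rmse")), stats::median(metric("asd")),
               stats::median(metric("hd"))),
    min = c(min(metric("rmse")), min(metric("asd")), min(metric("hd"))),
    max = c(max(metric("rmse")), max(metric("asd")), max(metric("hd"))))
  list(per_case = per_case, pooled = pooled)
}

#' Point-dependent mean error map across cases
#'
#' Averages corresponded per-vertex error magnitudes over cases; the result
#' highlights regions that carry most variation when rendered as a colour
#' map.
#'
#' @param errors list of numeric vectors (equal lengths, corresponded
#'   vertices), or a matrix with one column per case.
#' @return numeric vector of per-vertex means.
#' @export
pointwise_error_map <- function(errors) {
  if (is.list(errors)) {
    len <- unique(vapply(errors, length, integer(1)))
    if (length(len) != 1L) stop("error vectors differ in length")
    errors <- do.call(cbind, errors)
  }
  rowMeans(errors)
}

#' Maximum penetration depth of points into obstacles
#'
#' Winding-number scan: a point is penetrating when its generalized winding
#' number exceeds 1/2; its depth is the distance to the obstacle surface
#' (minus any inflation offset credit). Used to verify the wrap engine's
#' no-penetration contract on built structures.
#'
#' @param points k x 3 matrix.
#' @param obstacles an [obstacle_set()].
#' @return maximum depth in mm (0 when nothing penetrates).
#' @export
max_penetration_depth <- function(points, obstacles) {
  pm <- as.matrix(points)
  depth <- 0
  for (s in obstacles$surfaces) {
    w <- cpp_winding_number(s$vertices, s$faces, pm)
    inside <- w > 0.5
    if (any(inside)) {
      d <- cpp_closest_points(s$vertices, s$faces,
                              pm[inside, , drop = FALSE])$distance
      depth <- max(depth, d)
    }
  }
  depth
}

#' Do two watertight meshes intersect?
#'
#' Dense winding-number scan: surface sample points of each mesh are tested
#' for containment in the other. Empty intersection at the sampling density
#' `spacing` means no sample of either surface lies inside the other.
#'
#' @param a,b watertight [knee_mesh()] objects.
#' @param spacing surface sampling density in mm.
#' @return list with `intersects` (logical) and `max_depth` (mm).
#' @export
meshes_intersect <- function(a, b, spacing = 0.5) {
  pa <- sample_surface_points(a, spacing)
  pb <- sample_surface_points(b, spacing)
  da <- max_penetration_depth(pa, obstacle_set(list(b)))
  db <- max_penetration_depth(pb, obstacle_set(list(a)))
  list(intersects = max(da, db) > 1e-6, max_depth = max(da, db))
}
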
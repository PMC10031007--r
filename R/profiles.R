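#' Profile samples of a structure dimension versus relative position
#'
#' Meniscal height/width measurements are expressed against the relative
#' position along the outer rim from anterior to posterior root; cruciate
#' thickness against the relative origin-to-insertion course. Positions are
#' in `[0, 1]`, values in mm.
#'
#' @param s numeric vector of relative positions in `[0, 1]`.
#' @param values numeric vector of measurements (mm), same length.
#' @param structure_label one of `"MM_height"`, `"MM_width"`, `"LM_height"`,
#'   `"LM_width"`, `"ACL_radius"`, `"PCL_radius"` (or a free label).
#' @return object of class `profile_samples`.
#' @export
profile_samples <- function(s, values, structure_label = "profile") {
  if (length(s) != length(values)) stop("s and values must have equal length")
  if (length(s) < 2L) stop("at least 2 samples required")
  if (any(s < -1e-12 | s > 1 + 1e-12)) stop("relative positions must lie in [0, 1]")
  if (any(values < 0)) stop("profile values must be non-negative")
  structure(list(s = as.numeric(s), values = as.numeric(values),
                 structure_label = structure_label),
            class = "profile_samples")
}

# Orthogonal-basis least squares evaluated through predict(); power-basis
# coefficients recovered from Chebyshev-node interpolation where the
# conversion is numerically meaningful.
poly_fit_model <- function(s, values, degree) {
  if (degree == 0L) {
    structure(list(degree = 0L, mean = mean(values)), class = "poly0")
  } else {
    df <- data.frame(s = s, y = values)
    stats::lm(y ~ poly(s, degree), data = df)
  }
}

poly_fit_eval <- function(model, s) {
  if (inherits(model, "poly0")) rep(model$mean, length(s))
  else unname(stats::predict(model, newdata = data.frame(s = s)))
}

#' Fit a polynomial profile
#'
#' Least-squares polynomial of the requested degree. Fitting is carried out on
#' an orthogonal polynomial basis for numerical stability; ordinary
#' (ascending) power-basis coefficients are recovered and reported for
#' degrees up to 12.
#'
#' @param samples a [profile_samples()].
#' @param degree polynomial degree; must be below the number of distinct
#'   positions.
#' @return object of class `polynomial_profile` with fields `coefficients`
#'   (ascending powers), `degree`, `fit_rmse` (mm) and `structure_label`.
#' @export
fit_polynomial <- function(samples, degree) {
  s <- samples$s
  y <- samples$values
  ndist <- length(unique(s))
  if (degree >= ndist) {
    stop(sprintf("degree %d is underdetermined with %d distinct positions",
                 degree, ndist))
  }
  model <- poly_fit_model(s, y, degree)
  fitted <- poly_fit_eval(model, s)
  rmse <- sqrt(mean((y - fitted)^2))
  coef <- NULL
  if (degree <= 12L) {
    # interpolate the fitted polynomial at Chebyshev nodes on [0,1] and solve
    # the (well-conditioned at low degree) Vandermonde system
    k <- degree + 1L
    nodes <- 0.5 + 0.5 * cos(pi * (2 * seq_len(k) - 1) / (2 * k))
    Vm <- outer(nodes, 0:degree, `^`)
    coef <- as.numeric(solve(Vm, poly_fit_eval(model, nodes)))
  }
  structure(list(coefficients = coef, degree = as.integer(degree),
                 fit_rmse = rmse, reference_rmse = NA_real_,
                 model = model, structure_label = samples$structure_label),
            class = "polynomial_profile")
}

#' Evaluate a polynomial profile
#' @param profile a `polynomial_profile`.
#' @param s positions in `[0, 1]`.
#' @return numeric vector of values (mm).
#' @export
eval_profile <- function(profile, s) {
  poly_fit_eval(profile$model, s)
}

#' Build a profile directly from power-basis coefficients
#' @param coefficients ascending power-basis coefficients.
#' @param structure_label label carried by the profile.
#' @return a `polynomial_profile`.
#' @export
polynomial_profile <- function(coefficients, structure_label = "profile") {
  degree <- length(coefficients) - 1L
  # represent through a dense exact fit so eval_profile() has a single path
  s <- seq(0, 1, length.out = max(2L * degree + 2L, 8L))
  y <- as.numeric(outer(s, 0:degree, `^`) %*% coefficients)
  model <- poly_fit_model(s, y, degree)
  structure(list(coefficients = as.numeric(coefficients), degree = degree,
                 fit_rmse = 0, reference_rmse = NA_real_, model = model,
                 structure_label = structure_label),
            class = "polynomial_profile")
}

#' @export
print.polynomial_profile <- function(x, ...) {
  cat(sprintf("<polynomial_profile> %s: degree %d, fit RMSE %.4g mm\n",
              x$structure_label, x$degree, x$fit_rmse))
  invisible(x)
}

#' Select the polynomial degree by sensitivity against an over-fitted reference
#'
#' Fits polynomials of increasing degree and compares each, on a dense
#' position grid, to an intentionally over-fitted reference polynomial
#' (degree 20 by default) standing in for ground truth. The evolution of this
#' RMSE with degree exhibits an elbow; the selected degree is the last one
#' whose incremental improvement still exceeds `improvement_tol` times the
#' degree-0 RMSE.
#'
#' @param samples a [profile_samples()].
#' @param max_degree largest candidate degree.
#' @param reference_degree degree of the over-fitted reference (lowered with a
#'   warning when the samples cannot support it).
#' @param improvement_tol elbow threshold, fraction of the degree-0 RMSE.
#' @param grid_n dense comparison grid resolution.
#' @return selected degree (integer).
#' @export
select_degree <- function(samples, max_degree = 8L, reference_degree = 20L,
                          improvement_tol = 0.05, grid_n = 1000L) {
  ndist <- length(unique(samples$s))
  if (reference_degree > ndist - 1L) {
    reference_degree <- ndist - 1L
    warning("too few samples for the requested reference degree; lowered to ",
            reference_degree)
  }
  if (max_degree >= reference_degree) {
    max_degree <- reference_degree - 1L
  }
  grid <- seq(0, 1, length.out = grid_n)
  ref_model <- poly_fit_model(samples$s, samples$values, reference_degree)
  ref <- poly_fit_eval(ref_model, grid)
  rmse <- vapply(0:max_degree, function(d) {
    fit <- poly_fit_model(samples$s, samples$values, d)
    sqrt(mean((poly_fit_eval(fit, grid) - ref)^2))
  }, numeric(1))
  scale <- rmse[1L]
  # absolute floor: a fit already indistinguishable from the reference wins
  floor_rmse <- 1e-9 * max(1, mean(abs(samples$values)))
  for (d in 0:max_degree) {
    if (rmse[d + 1L] <= floor_rmse) return(d)
    if (d >= 1L && (rmse[d] - rmse[d + 1L]) <= improvement_tol * scale) {
      return(d - 1L)
    }
  }
  max_degree
}

#' Default polynomial degrees per structure
#'
#' The degrees retained by the sensitivity analysis on the study cohort:
#' ACL radius 2, PCL radius 4, medial meniscus height 6 and width 4, lateral
#' meniscus height and width both 4.
#'
#' @return named integer vector.
#' @export
default_profile_degrees <- function() {
  c(ACL_radius = 2L, PCL_radius = 4L,
    MM_height = 6L, MM_width = 4L,
    LM_height = 4L, LM_width = 4L)
}

#' Read / write profile samples as CSV (columns s, value_mm, label)
#' @param path CSV path.
#' @param label optional label filter on read.
#' @return a [profile_samples()].
#' @export
read_profile_samples <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  if (!is.null(label)) df <- df[df$label == label, , drop = FALSE]
  profile_samples(df$s, df$value_mm,
                  structure_label = if (is.null(label)) df$label[1L] else label)
}

#' @rdname read_profile_samples
#' @param samples a [profile_samples()].
#' @export
write_profile_samples <- function(samples, path) {
  utils::write.csv(data.frame(s = samples$s, value_mm = samples$values,
                              label = samples$structure_label),
                   path, row.names = FALSE)
  invisible(path)
}
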
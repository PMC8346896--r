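#' Trajectory functional form
#'
#' Describes the age basis shared by all groups' log-rate curves: a
#' polynomial in transformed age (default cubic) or a cubic B-spline with
#' interior knots.  Age is centered and scaled before powers are taken,
#' `a* = (age - center) / scale`, which conditions the cubic design matrix;
#' the defaults (center 21.5, scale 10) map the observed 10-33 range roughly
#' onto [-1.2, 1.2].
#'
#' @param degree polynomial degree (>= 0); ignored when `knots` is given.
#' @param knots optional strictly increasing interior knot ages for a cubic
#'   B-spline basis.
#' @param center,scale age transform parameters, in years.
#' @param bounds boundary ages of the spline basis (ignored for
#'   polynomials); knots must lie strictly inside.
#' @return a `trajectory_spec` object.
#' @export
trajectory_spec <- function(degree = 3L, knots = NULL,
                            center = 21.5, scale = 10, bounds = c(10, 33)) {
  if (is.null(knots)) {
    if (degree < 0L || degree != as.integer(degree))
      stop_arg("degree must be a nonnegative integer")
  } else {
    if (is.unsorted(knots, strictly = TRUE))
      stop_arg("spline knots must be strictly increasing")
    if (min(knots) <= bounds[1L] || max(knots) >= bounds[2L])
      stop_arg("spline knots must lie strictly inside the basis bounds")
  }
  structure(list(basis = if (is.null(knots)) "polynomial" else "spline",
                 degree = as.integer(degree), knots = knots,
                 center = center, scale = scale, bounds = bounds),
            class = "trajectory_spec")
}

# design matrix of the log-rate curve at the given ages
traj_basis <- function(spec, age) {
  a <- (age - spec$center) / spec$scale
  if (spec$basis == "polynomial") {
    X <- outer(a, 0:spec$degree, `^`)
    colnames(X) <- paste0("a", 0:spec$degree)
  } else {
    k <- (spec$knots - spec$center) / spec$scale
    bk <- (spec$bounds - spec$center) / spec$scale
    B <- suppressWarnings(
      splines::bs(a, knots = k, degree = 3L, intercept = FALSE,
                  Boundary.knots = bk))
    X <- cbind(1, B)
    colnames(X) <- c("a0", paste0("s", seq_len(ncol(B))))
  }
  X
}

n_basis <- function(spec) {
  if (spec$basis == "polynomial") spec$degree + 1L
  else length(spec$knots) + 4L
}

basis_names <- function(spec) {
  if (spec$basis == "polynomial") paste0("a", 0:spec$degree)
  else c("a0", paste0("s", seq_len(length(spec$knots) + 3L)))
}

# total polynomial order, used as the model-selection tie-break
basis_order <- function(spec) {
  if (spec$basis == "polynomial") spec$degree else length(spec$knots) + 3L
}

#' @export
print.trajectory_spec <- function(x, ...) {
  if (x$basis == "polynomial")
    cat("<trajectory_spec> polynomial degree ", x$degree, sep = "")
  else
    cat("<trajectory_spec> cubic spline, knots at ",
        paste(x$knots, collapse = ", "), sep = "")
  cat(", age transform (age - ", x$center, ")/", x$scale, "\n", sep = "")
  invisible(x)
}
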
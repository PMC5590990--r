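#' Smoothing kernel specification
#'
#' Defines the cubic spline smoothing kernel used throughout the SPH solver.
#' The kernel has compact support of radius `2h`: particles farther apart
#' than twice the smoothing length do not interact.
#'
#' @param h Smoothing length (m). Default practice is `h = 1.3 * dx` for a
#'   lattice spacing `dx`.
#' @param dim Spatial dimension, 2 for planar benchmark scenes or 3.
#' @return An object of class `kernel_spec` with fields `h`,
#'   `support_radius` (= 2h) and `dim`.
#' @export
kernel_spec <- function(h, dim = 3) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("invalid kernel configuration: smoothing length h must be > 0")
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3")
  structure(list(h = h, support_radius = 2 * h, dim = as.integer(dim)),
            class = "kernel_spec")
}

#' Cubic spline kernel and its gradient
#'
#' Evaluates the cubic spline kernel W and its analytic gradient with
#' respect to the displacement `r`. W vanishes for distances at or beyond
#' `2h` and integrates to 1 over its support ball.
#'
#' @param r Displacement vector(s) (m): a numeric vector of length `dim`,
#'   or a matrix with one displacement per row.
#' @param h Smoothing length (m), must be positive.
#' @param dim Spatial dimension (2 or 3).
#' @return A list with `W` (numeric vector, units 1/m^dim) and `gradW`
#'   (matrix, one gradient per row, units 1/m^(dim+1)).
#' @export
cubic_spline_kernel <- function(r, h, dim = 3) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("invalid kernel configuration: smoothing length h must be > 0")
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  out <- cpp_cubic_kernel(as.matrix(r), h, as.integer(dim))
  out
}

#' SPH kernel interpolation of a particle field
#'
#' Interpolates particle-carried values at arbitrary points using the SPH
#' summation `sum_b m_b A_b / rho_b W(x - r_b, h)`. An empty neighborhood
#' (no particle within `2h` of the evaluation point) returns 0 by
#' convention.
#'
#' @param field_values Numeric vector (one value per particle) or matrix
#'   (one row per particle) of the field to interpolate.
#' @param state A [fluid_state()].
#' @param at Evaluation point(s): vector or matrix (one point per row).
#' @param kernel A [kernel_spec()].
#' @param shepard If `TRUE`, apply Shepard (partition-of-unity)
#'   renormalization; the raw summation is the default.
#' @return Interpolated value(s): a vector (one per point) if
#'   `field_values` is a vector, else a matrix.
#' @export
kernel_interpolate <- function(field_values, state, at, kernel,
                               shepard = FALSE) {
  stopifnot(inherits(state, "fluid_state"), inherits(kernel, "kernel_spec"))
  if (nrow(state$positions) == 0) stop("state must be nonempty")
  vec <- is.null(dim(field_values))
  vals <- if (vec) matrix(field_values, ncol = 1) else as.matrix(field_values)
  if (is.null(dim(at))) at <- matrix(at, nrow = 1)
  out <- cpp_interpolate(as.matrix(at), state$positions, vals,
                         state$densities, state$masses, kernel$h,
                         kernel$dim, shepard)
  if (vec) drop(out) else out
}
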
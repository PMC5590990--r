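#' SPH particle system state
#'
#' Container for the weakly-compressible SPH fluid: positions, velocities,
#' densities, masses and pressures per particle plus the (global) dynamic
#' viscosity. Blood defaults: reference density 1056 kg/m^3, viscosity
#' 0.0035 Pa s.
#'
#' @param positions n x dim matrix (m).
#' @param velocities n x dim matrix (m/s).
#' @param densities length-n vector (kg/m^3), all positive.
#' @param masses length-n vector (kg), all positive.
#' @param pressures length-n vector (Pa); defaults to zero.
#' @param mu Dynamic viscosity (Pa s), global scalar.
#' @return An object of class `fluid_state`.
#' @export
fluid_state <- function(positions, velocities, densities, masses,
                        pressures = NULL, mu = 0.0035) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (is.null(pressures)) pressures <- numeric(n)
  if (nrow(velocities) != n || length(densities) != n ||
      length(masses) != n || length(pressures) != n)
    stop("fluid_state arrays must be congruent in length")
  if (ncol(velocities) != ncol(positions))
    stop("positions and velocities must share a dimension")
  if (any(masses <= 0)) stop("all particle masses must be > 0")
  if (any(densities <= 0)) stop("all particle densities must be > 0")
  structure(list(positions = positions, velocities = velocities,
                 densities = as.numeric(densities),
                 masses = as.numeric(masses),
                 pressures = as.numeric(pressures), mu = mu,
                 dim = ncol(positions)),
            class = "fluid_state")
}

#' @export
print.fluid_state <- function(x, ...) {
  cat("SPH fluid state:", nrow(x$positions), "particles in", x$dim, "D\n")
  cat("  density range:", paste(signif(range(x$densities), 6), collapse = " - "),
      "kg/m^3, mu =", x$mu, "Pa s\n")
  invisible(x)
}

#' Weakly-compressible equations of state
#'
#' Artificial pressure-density closures for weakly-compressible SPH.
#' `eos_linear` is `P = c0^2 (rho - rho0)`; `eos_tait` is the Tait/Cole
#' form `P = rho0 c0^2 / gamma ((rho/rho0)^gamma - 1)`. Both vanish at the
#' reference density, are strictly increasing, and have linearized
#' stiffness `c0^2` at `rho0`. The artificial sound speed `c0` should be
#' at least 10x the fastest expected flow speed so density fluctuations
#' stay around 1%.
#'
#' @param rho0 Reference density (kg/m^3).
#' @param c0 Artificial speed of sound (m/s), positive.
#' @param gamma Tait exponent (default 7).
#' @param p_min Pressure floor (Pa). The default `-Inf` keeps the strictly
#'   increasing law; free-surface scenes set 0 to suppress the tensile
#'   (clumping) instability, standard WCSPH practice.
#' @return An object of class `eos`.
#' @export
eos_linear <- function(rho0, c0, p_min = -Inf) {
  if (c0 <= 0) stop("c0 must be > 0")
  structure(list(kind = "linear", rho0 = rho0, c0 = c0, p_min = p_min),
            class = "eos")
}

#' @rdname eos_linear
#' @export
eos_tait <- function(rho0, c0, gamma = 7, p_min = -Inf) {
  if (c0 <= 0) stop("c0 must be > 0")
  structure(list(kind = "tait", rho0 = rho0, c0 = c0, gamma = gamma,
                 p_min = p_min),
            class = "eos")
}

#' Pressure from density
#'
#' @param rho Density (kg/m^3), positive.
#' @param eos An equation of state from [eos_linear()] or [eos_tait()].
#' @return Pressure (Pa).
#' @export
eos_pressure <- function(rho, eos) {
  stopifnot(inherits(eos, "eos"))
  if (any(rho <= 0)) stop("corrupted state: non-positive density")
  p <- if (eos$kind == "linear") {
    eos$c0^2 * (rho - eos$rho0)
  } else {
    eos$rho0 * eos$c0^2 / eos$gamma * ((rho / eos$rho0)^eos$gamma - 1)
  }
  if (is.finite(eos$p_min %||% -Inf)) p <- pmax(p, eos$p_min)
  p
}

#' Neighbor pair search
#'
#' Finds exactly the unordered particle pairs closer than `cutoff`
#' (typically `2h`), excluding self-pairs. Uses a cell-linked list, or a
#' minimal-image all-pairs scan for periodic boxes.
#'
#' @param positions n x dim matrix of coordinates (finite).
#' @param cutoff Interaction radius (m).
#' @param period Length-dim vector; entry L > 0 makes that axis periodic
#'   with box length L, 0 means non-periodic. Default non-periodic.
#' @return A list with 1-based index vectors `i`, `j` (i < j), the
#'   minimal-image displacement matrix `dx` (= x_i - x_j) and distances `r`.
#' @export
neighbor_search <- function(positions, cutoff, period = NULL) {
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.null(period)) period <- numeric(ncol(positions))
  cpp_neighbor_pairs(positions, cutoff, as.numeric(period))
}

#' Continuity-equation density rate
#'
#' `drho_a/dt = sum_b m_b (v_a - v_b) . gradW_ab`, summed over the given
#' neighbor pairs. Self terms vanish identically.
#'
#' @param state A [fluid_state()].
#' @param neighbors Pair list from [neighbor_search()].
#' @param kernel A [kernel_spec()].
#' @return Numeric vector drho/dt (kg/m^3/s) per particle.
#' @export
density_rate <- function(state, neighbors, kernel) {
  sph_rates(state, neighbors, kernel)$drho
}

#' Momentum-equation acceleration
#'
#' Symmetric pressure term plus the physical viscous term:
#' `dv_a/dt = -sum_b m_b (P_a+P_b)/(rho_a rho_b) gradW_ab
#'           + sum_b m_b (mu_a+mu_b) v_ab /(rho_a rho_b r_ab^2) (r_ab . gradW_ab)`.
#' Pairwise contributions are equal and opposite, so total linear momentum
#' is conserved to round-off. A coincident pair (r = 0) contributes zero
#' and raises a warning.
#'
#' @inheritParams density_rate
#' @param alpha Monaghan artificial-viscosity coefficient (default 0 =
#'   the printed equations only).
#' @param c0 Sound speed used by the artificial viscosity (ignored when
#'   `alpha = 0`).
#' @return n x dim matrix of accelerations (m/s^2).
#' @export
momentum_rate <- function(state, neighbors, kernel, alpha = 0, c0 = 0) {
  sph_rates(state, neighbors, kernel, alpha = alpha, c0 = c0)$acc
}

# One pass over the pair list computing both rates.
sph_rates <- function(state, neighbors, kernel, alpha = 0, c0 = 0) {
  stopifnot(inherits(state, "fluid_state"), inherits(kernel, "kernel_spec"))
  n <- nrow(state$positions)
  mu <- rep_len(state$mu, n)
  out <- cpp_sph_rates(neighbors$i, neighbors$j, neighbors$dx, neighbors$r,
                       state$velocities, state$densities, state$pressures,
                       state$masses, mu, kernel$h, kernel$dim, alpha, c0)
  if (out$n_coincident > 0)
    warning(sprintf("%d coincident particle pair(s) skipped in SPH rates",
                    out$n_coincident))
  out
}

#' Summation density
#'
#' `rho_a = sum_b m_b W_ab` including the self contribution `m_a W(0, h)`.
#'
#' @inheritParams density_rate
#' @return Density vector (kg/m^3).
#' @export
summation_density <- function(state, neighbors, kernel) {
  cpp_summation_density(neighbors$i, neighbors$j, neighbors$r,
                        state$masses, kernel$h, kernel$dim,
                        nrow(state$positions))
}

#' Advance the fluid one explicit step
#'
#' Symplectic (semi-implicit) Euler: accelerations and density rates are
#' evaluated at the current state, velocities are kicked, positions drift
#' with the new velocities, and densities integrate the continuity rate.
#' The time step must respect the acoustic CFL condition
#' `dt <= cfl * h / (c0 + max|v|)`.
#'
#' @param state A [fluid_state()].
#' @param kernel A [kernel_spec()].
#' @param eos Equation of state; pressures are refreshed from densities
#'   before the force evaluation.
#' @param dt Time step (s).
#' @param external_accel n x dim matrix (or single row recycled) of body
#'   accelerations, e.g. gravity (m/s^2). Optional.
#' @param neighbors Optional precomputed pair list (rebuilt if omitted).
#' @param period Periodicity vector passed to [neighbor_search()];
#'   positions are wrapped into the box on periodic axes.
#' @param cfl CFL safety factor (default 0.25) used for the stability
#'   check.
#' @param alpha Optional Monaghan artificial viscosity coefficient.
#' @return The advanced `fluid_state`.
#' @export
step_fluid <- function(state, kernel, eos, dt, external_accel = NULL,
                       neighbors = NULL, period = NULL, cfl = 0.25,
                       alpha = 0) {
  stopifnot(inherits(state, "fluid_state"), inherits(eos, "eos"))
  vmax <- if (nrow(state$velocities)) max(sqrt(rowSums(state$velocities^2))) else 0
  dt_max <- cfl * kernel$h / (eos$c0 + vmax)
  if (dt > dt_max * (1 + 1e-9))
    stop(sprintf("configuration error: dt = %g violates CFL bound %g",
                 dt, dt_max))
  if (is.null(neighbors))
    neighbors <- neighbor_search(state$positions, kernel$support_radius,
                                 period)
  state$pressures <- eos_pressure(state$densities, eos)
  rates <- sph_rates(state, neighbors, kernel, alpha = alpha, c0 = eos$c0)
  acc <- rates$acc
  if (!is.null(external_accel)) {
    if (is.null(dim(external_accel)))
      external_accel <- matrix(external_accel, nrow(acc), ncol(acc),
                               byrow = TRUE)
    acc <- acc + external_accel
  }
  state$velocities <- state$velocities + dt * acc
  state$positions <- state$positions + dt * state$velocities
  state$densities <- state$densities + dt * rates$drho
  if (!is.null(period)) {
    for (k in seq_along(period)) {
      if (period[k] > 0)
        state$positions[, k] <- state$positions[, k] %% period[k]
    }
  }
  state$pressures <- eos_pressure(state$densities, eos)
  state
}
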
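#' Structural dynamic state
#'
#' @param mesh A [structural_mesh()].
#' @return A list with zero displacement and velocity fields, class
#'   `structure_state`.
#' @export
structure_state <- function(mesh) {
  n <- nrow(mesh$nodes)
  structure(list(u = matrix(0, n, 3), v = matrix(0, n, 3)),
            class = "structure_state")
}

#' Advance the structure one explicit central-difference step
#'
#' Lumped-mass explicit dynamics: nodal accelerations from internal
#' (membrane + truss) forces, external forces and optional
#' mass-proportional damping; velocities and displacements are advanced
#' with the central-difference (symplectic Euler) update. Prescribed
#' nodes overwrite the computed kinematics.
#'
#' @param mesh A [structural_mesh()].
#' @param state A [structure_state()].
#' @param external n x 3 matrix of external nodal forces (N), or `NULL`.
#' @param dt Time step (s); must be below the element-wise stable
#'   increment (not checked here beyond non-finiteness of the update --
#'   scenes choose a safe substep count).
#' @param prescribed Optional list with `idx` (node indices), `u`
#'   (length(idx) x 3 displacements) and optionally `v` (velocities) that
#'   override the computed motion.
#' @param damping Mass-proportional damping rate (1/s), default 0.
#' @param slack Chordae slack-in-compression flag.
#' @param vcap Nodal speed guard (m/s): velocities are clipped to this
#'   magnitude (default `Inf`). Tissue nodes in the cardiac scenes move
#'   at a few m/s at most, so a generous cap suppresses non-physical
#'   transients without touching the resolved dynamics.
#' @return The advanced `structure_state`.
#' @export
step_structure <- function(mesh, state, external = NULL, dt,
                           prescribed = NULL, damping = 0, slack = TRUE,
                           vcap = Inf) {
  f <- membrane_internal_forces(mesh, state$u) +
    truss_internal_forces(mesh, state$u, slack = slack)
  if (!is.null(external)) f <- f + external
  m <- pmax(mesh$mass, 1e-30)
  acc <- f / m
  if (damping > 0) acc <- acc - damping * state$v
  state$v <- state$v + dt * acc
  if (is.finite(vcap)) {
    sp <- sqrt(rowSums(state$v^2))
    over <- sp > vcap
    if (any(over)) state$v[over, ] <- state$v[over, ] * (vcap / sp[over])
  }
  state$u <- state$u + dt * state$v
  if (!is.null(prescribed)) {
    idx <- prescribed$idx
    state$u[idx, ] <- prescribed$u
    state$v[idx, ] <- if (!is.null(prescribed$v)) prescribed$v else 0
  }
  if (any(!is.finite(state$u)))
    stop("structural integration diverged (time step above stable increment?)")
  state
}

#' Kinetic energy of the structure
#'
#' @param mesh A [structural_mesh()].
#' @param state A [structure_state()].
#' @return Kinetic energy (J).
#' @export
structure_kinetic_energy <- function(mesh, state) {
  0.5 * sum(mesh$mass * rowSums(state$v^2))
}
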
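#' Penalty contact configuration
#'
#' Node-to-surface contact between SPH particles and FE faces. A particle
#' within `thickness` of a face receives a normal penalty force
#' proportional to its penetration of the contact layer; the exact
#' opposite reaction is distributed to the face nodes by barycentric
#' weights, so contact conserves linear momentum to machine precision.
#'
#' @param stiffness Penalty stiffness (N/m of penetration). The default
#'   `NULL` lets [contact_auto_stiffness()] scale it from particle mass
#'   and time step.
#' @param thickness Contact layer thickness (m); should be at least half
#'   the particle spacing (default in scenes: 0.8 x spacing).
#' @param tangential Tangential velocity-damping coefficient (N s/m),
#'   default 0 = frictionless normal contact.
#' @param normal_damping Normal dashpot coefficient (N s/m), default 0 =
#'   the pure penalty-spring force `stiffness x depth`. The runner
#'   auto-sets a sub-critical dashpot to suppress contact chatter; the
#'   total normal force is never allowed to become adhesive.
#' @param pressure_coupling If `TRUE` (the runner's setting) and particle
#'   pressures are supplied, each contacted particle also receives the
#'   ghost-pressure boundary force `2 P_a V_a omega(d)` along the normal
#'   -- the pressure contribution its truncated kernel is missing beyond
#'   the surface -- so the interface transmits the fluid pressure
#'   accurately; the reaction goes to the face nodes as usual.
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(stiffness = NULL, thickness, tangential = 0,
                           normal_damping = 0, pressure_coupling = FALSE) {
  if (!is.null(stiffness) && stiffness <= 0) stop("stiffness must be > 0")
  if (thickness <= 0) stop("thickness must be > 0")
  structure(list(stiffness = stiffness, thickness = thickness,
                 tangential = tangential, normal_damping = normal_damping,
                 pressure_coupling = pressure_coupling),
            class = "contact_config")
}

# integral of the 3D cubic spline kernel over a plane at distance s from
# the particle: omega(s) = (2/h) int_{s/h}^{2} f(q) q dq  (1/m)
kernel_plane_integral <- function(s, h) {
  q0 <- pmin(abs(s) / h, 2)
  F1 <- function(q) q^2 / 2 - 0.375 * q^4 + 0.15 * q^5
  F2 <- function(q) q^2 - q^3 + 0.375 * q^4 - 0.05 * q^5
  upper <- F2(2) - F2(pmax(q0, 1))
  lower <- ifelse(q0 < 1, F1(1) - F1(q0), 0)
  (2 / h) * (upper + lower)
}

#' Stable penalty stiffness from particle mass and time step
#'
#' `k = m / (beta dt^2)` keeps the penalty spring stable at the
#' acoustic-CFL time step.
#'
#' @param particle_mass Representative particle mass (kg).
#' @param dt Time step (s).
#' @param beta Safety factor (default 4).
#' @return Stiffness (N/m).
#' @export
contact_auto_stiffness <- function(particle_mass, dt, beta = 4) {
  particle_mass / (beta * dt^2)
}

#' Detect particle-surface contacts
#'
#' Finds every particle lying within the contact thickness of a membrane
#' face, with the face-plane projection inside the face. Each qualifying
#' (particle, face) pair appears exactly once; a projection falling
#' exactly on a shared edge is assigned to the lowest element index.
#' Degenerate (zero-area) faces are excluded with a warning.
#'
#' @param particles A [fluid_state()] (3D), or an n x 3 position matrix.
#' @param surface A [structural_mesh()] with triangles; current node
#'   positions are `surface$nodes + displacements`.
#' @param config A [contact_config()].
#' @param displacements Optional n x 3 nodal displacements of the surface.
#' @return A list of parallel vectors: `particle`, `element`, `depth`
#'   (>= 0), `normal` (rows point from the face toward the particle) and
#'   barycentric `weights`.
#' @export
detect_contacts <- function(particles, surface, config,
                            displacements = NULL) {
  pos <- if (inherits(particles, "fluid_state")) particles$positions
         else as.matrix(particles)
  nodes <- surface$nodes
  if (!is.null(displacements)) nodes <- nodes + displacements
  out <- cpp_detect_contacts(pos, nodes, surface$triangles,
                             config$thickness)
  if (out$n_degenerate > 0)
    warning(sprintf("%d degenerate face(s) excluded from contact",
                    out$n_degenerate))
  out
}

#' Penalty contact forces
#'
#' Normal force `stiffness x depth` along the face normal on each
#' particle; equal and opposite reactions distributed to the face nodes
#' by barycentric weights. An optional tangential damping force
#' proportional to the relative tangential velocity emulates no-slip more
#' closely (off by default).
#'
#' @param contacts Output of [detect_contacts()].
#' @param config A [contact_config()] with a concrete `stiffness`.
#' @param surface The [structural_mesh()] the contacts refer to.
#' @param n_particles Number of particles (rows of the returned particle
#'   force matrix).
#' @param particle_vel Optional particle velocities (for tangential
#'   damping).
#' @param surface_vel Optional nodal velocities of the surface.
#' @param particle_pressure,particle_volume Optional per-particle
#'   pressures (Pa) and volumes (m^3) for the ghost-pressure boundary
#'   force (see [contact_config()]).
#' @param h Smoothing length (m), required for the ghost-pressure term.
#' @return List with `particle_forces` (n_particles x 3, N) and
#'   `nodal_forces` (surface nodes x 3, N); the two sum to zero exactly.
#' @export
penalty_forces <- function(contacts, config, surface, n_particles,
                           particle_vel = NULL, surface_vel = NULL,
                           particle_pressure = NULL,
                           particle_volume = NULL, h = NULL) {
  npn <- nrow(surface$nodes)
  pf <- matrix(0, n_particles, 3)
  nf <- matrix(0, npn, 3)
  m <- length(contacts$particle)
  if (m == 0)
    return(list(particle_forces = pf, nodal_forces = nf))
  k <- config$stiffness
  if (is.null(k)) stop("contact stiffness not set")
  fmag <- k * contacts$depth
  if (isTRUE(config$pressure_coupling) && !is.null(particle_pressure)) {
    dist <- config$thickness - contacts$depth
    omega <- kernel_plane_integral(dist, h)
    fmag <- fmag + 2 * particle_pressure[contacts$particle] *
      particle_volume[contacts$particle] * omega
  }
  fvec <- contacts$normal * fmag
  if ((config$tangential > 0 || (config$normal_damping %||% 0) > 0) &&
      !is.null(particle_vel)) {
    tri <- surface$triangles[contacts$element, , drop = FALSE]
    sv <- if (is.null(surface_vel)) matrix(0, npn, 3) else surface_vel
    vsurf <- contacts$weights[, 1] * sv[tri[, 1], , drop = FALSE] +
      contacts$weights[, 2] * sv[tri[, 2], , drop = FALSE] +
      contacts$weights[, 3] * sv[tri[, 3], , drop = FALSE]
    vrel <- particle_vel[contacts$particle, , drop = FALSE] - vsurf
    vn <- rowSums(vrel * contacts$normal)
    if ((config$normal_damping %||% 0) > 0) {
      # dashpot opposing normal approach; total normal force >= 0
      fn <- pmax(fmag - config$normal_damping * vn, 0)
      fvec <- contacts$normal * fn
    }
    if (config$tangential > 0) {
      vt <- vrel - vn * contacts$normal
      fvec <- fvec - config$tangential * vt
    }
  }
  acc <- rowsum(fvec, contacts$particle)
  idx <- as.integer(rownames(acc))
  pf[idx, ] <- pf[idx, ] + acc
  tri <- surface$triangles[contacts$element, , drop = FALSE]
  for (kk in 1:3) {
    acc <- rowsum(-contacts$weights[, kk] * fvec, tri[, kk])
    idx <- as.integer(rownames(acc))
    nf[idx, ] <- nf[idx, ] + acc
  }
  list(particle_forces = pf, nodal_forces = nf)
}

# Exact penalty evaluation for a frozen candidate (particle, element)
# pair list against the CURRENT surface configuration. Used inside
# structural substeps: particles are frozen over the fluid step, the
# mesh moves, so depths must be re-measured each substep.
eval_contact_pairs <- function(pidx, eidx, ppos, mesh, u, config,
                               particle_vel = NULL, surface_vel = NULL,
                               particle_pressure = NULL,
                               particle_volume = NULL, h = NULL) {
  npn <- nrow(mesh$nodes)
  nf <- matrix(0, npn, 3)
  pfzero <- matrix(0, nrow(ppos), 3)
  if (length(pidx) == 0)
    return(list(particle_forces = pfzero, nodal_forces = nf))
  tri <- mesh$triangles[eidx, , drop = FALSE]
  nd <- mesh$nodes + u
  P1 <- nd[tri[, 1], , drop = FALSE]
  P2 <- nd[tri[, 2], , drop = FALSE]
  P3 <- nd[tri[, 3], , drop = FALSE]
  e1 <- P2 - P1; e2 <- P3 - P1
  nrm <- row_cross(e1, e2)
  a2 <- sqrt(rowSums(nrm^2))
  ok <- a2 > 1e-16
  nrm <- nrm / pmax(a2, 1e-16)
  x <- ppos[pidx, , drop = FALSE]
  dvec <- x - P1
  d <- rowSums(dvec * nrm)
  qv <- dvec - d * nrm
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  q1 <- rowSums(qv * e1); q2 <- rowSums(qv * e2)
  det <- pmax(d11 * d22 - d12 * d12, 1e-30)
  wb <- (d22 * q1 - d12 * q2) / det
  wc <- (d11 * q2 - d12 * q1) / det
  wa <- 1 - wb - wc
  th <- config$thickness
  act <- ok & abs(d) <= th & wa >= -1e-12 & wb >= -1e-12 & wc >= -1e-12
  if (!any(act))
    return(list(particle_forces = pfzero, nodal_forces = nf))
  sgn <- ifelse(d >= 0, 1, -1)
  depth <- th - abs(d)
  fmag <- config$stiffness * depth
  if (isTRUE(config$pressure_coupling) && !is.null(particle_pressure)) {
    omega <- kernel_plane_integral(abs(d), h)
    fmag <- fmag + 2 * particle_pressure[pidx] * particle_volume[pidx] *
      omega
  }
  nrm_s <- nrm * sgn
  if ((config$normal_damping %||% 0) > 0 && !is.null(particle_vel)) {
    sv <- if (is.null(surface_vel)) matrix(0, npn, 3) else surface_vel
    vsurf <- wa * sv[tri[, 1], , drop = FALSE] +
      wb * sv[tri[, 2], , drop = FALSE] +
      wc * sv[tri[, 3], , drop = FALSE]
    vrel <- particle_vel[pidx, , drop = FALSE] - vsurf
    vn <- rowSums(vrel * nrm_s)
    fmag <- pmax(fmag - config$normal_damping * vn, 0)
  }
  fmag[!act] <- 0
  fvec <- nrm_s * fmag
  pf <- pfzero
  acc <- rowsum(fvec, pidx)
  idx <- as.integer(rownames(acc))
  pf[idx, ] <- pf[idx, ] + acc
  wmat <- cbind(wa, wb, wc)
  for (kk in 1:3) {
    acc <- rowsum(-wmat[, kk] * fvec, tri[, kk])
    idx <- as.integer(rownames(acc))
    nf[idx, ] <- nf[idx, ] + acc
  }
  list(particle_forces = pf, nodal_forces = nf)
}
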
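# Time-stepping driver coupling the SPH fluid, boundary particles,
# pistons and FE structures.
#
# Particle types: 0 = fluid, 1 = static wall, 2 = prescribed moving wall
# (driven by a motion track), 100+k = plate of piston k.

#' Assemble an FSI scene
#'
#' Low-level constructor used by the `make_*` scene generators. See
#' [run_scene()] for the runner.
#'
#' @param dim 2 or 3.
#' @param dx Particle spacing (m).
#' @param pos,vel N x dim particle arrays (fluid + boundary).
#' @param rho,mass Per-particle density (kg/m^3) and mass (kg).
#' @param type Integer per particle: 0 fluid, 1 static wall, 2 moving
#'   wall, 100+k piston plate k.
#' @param eos Equation of state.
#' @param mu Dynamic viscosity (Pa s).
#' @param gravity Body acceleration (length dim).
#' @param period Periodic box lengths (length dim, 0 = non-periodic).
#' @param h Smoothing length; default `1.3 dx`.
#' @param wall_track Optional [motion_track()] over the type-2 particles
#'   (displacements relative to their positions in `pos`).
#' @param pistons List of `list(boundary, rows, update_every)` entries.
#' @param structures List of `list(name, mesh, state, prescribed_fn,
#'   substeps, damping, slack, axis)` entries.
#' @param contact A [contact_config()] (stiffness may be `NULL` for
#'   auto-scaling).
#' @param probes Named list/matrix of probe points.
#' @param flux_planes Named list of `list(origin, normal, radius)`.
#' @param recorders Named list of functions `f(sim)` returning a scalar,
#'   evaluated at every trace step.
#' @param settle_time,settle_damping Damped settling phase duration (s)
#'   and velocity damping rate (1/s) applied to fluid during settling.
#' @param alpha Monaghan artificial-viscosity coefficient (0 = the
#'   verbatim momentum equation only).
#' @param delta delta-SPH density-diffusion coefficient (0 = verbatim
#'   continuity equation; scenes default to 0.1, the literature standard).
#' @param shepard_every Apply the Shepard density filter every this many
#'   steps (0 = off).
#' @param noslip_walls Extrapolate wall-particle velocities from the
#'   adjacent fluid in the viscous term (sharper no-slip; used by the
#'   viscous channel benchmark).
#' @param wall_bc `"adami"` (default): wall-particle pressures are
#'   extrapolated from the adjacent fluid with a hydrostatic correction
#'   every step (generalized wall boundary, stiff and accurate);
#'   `"continuity"`: wall densities evolve by the continuity equation
#'   like fluid.
#' @param vmax_est Expected peak flow speed (for the CFL time step).
#' @param cfl CFL safety factor.
#' @param meta Free-form scene metadata.
#' @return An object of class `fsi_scene`.
#' @export
fsi_scene <- function(dim, dx, pos, vel, rho, mass, type, eos, mu,
                      gravity = NULL, period = NULL, h = NULL,
                      wall_track = NULL, pistons = list(),
                      structures = list(), contact = NULL,
                      probes = NULL, flux_planes = list(),
                      recorders = list(), settle_time = 0,
                      settle_damping = 30, alpha = 0, delta = 0,
                      shepard_every = 0L, noslip_walls = FALSE,
                      wall_bc = c("adami", "continuity"),
                      vmax_est = NULL, cfl = 0.25, meta = list()) {
  wall_bc <- match.arg(wall_bc)
  if (is.null(h)) h <- 1.3 * dx
  if (is.null(gravity)) gravity <- numeric(dim)
  if (is.null(vmax_est)) vmax_est <- eos$c0 / 10
  structure(list(dim = dim, dx = dx, h = h, pos = as.matrix(pos),
                 vel = as.matrix(vel), rho = rho, mass = mass,
                 type = as.integer(type), eos = eos, mu = mu,
                 gravity = gravity, period = period,
                 wall_track = wall_track, pistons = pistons,
                 structures = structures, contact = contact,
                 probes = probes, flux_planes = flux_planes,
                 recorders = recorders, settle_time = settle_time,
                 settle_damping = settle_damping, alpha = alpha,
                 delta = delta,
                 shepard_every = as.integer(shepard_every),
                 noslip_walls = noslip_walls, wall_bc = wall_bc,
                 vmax_est = vmax_est, cfl = cfl, meta = meta),
            class = "fsi_scene")
}

#' @export
print.fsi_scene <- function(x, ...) {
  cat("FSI scene:", sum(x$type == 0), "fluid +", sum(x$type != 0),
      "boundary particles (", x$dim, "D ), dx =", x$dx, "m\n")
  if (length(x$structures))
    cat("  structures:",
        paste(vapply(x$structures, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

#' Run an FSI scene
#'
#' Advances the coupled system with symplectic-Euler fluid steps,
#' central-difference structural substeps, penalty contact coupling, and
#' characteristic-controlled pistons. Deterministic: identical scene and
#' arguments reproduce identical traces bit for bit.
#'
#' @param scene An [fsi_scene()].
#' @param duration Simulated time (s) after the settling phase.
#' @param dt Time step (s); default from the acoustic CFL condition.
#' @param trace_every Trace sampling interval in steps (default: about
#'   1 ms of simulated time).
#' @param snapshot_dir If non-`NULL`, legacy-VTK particle snapshots are
#'   written here at every trace step.
#' @param verbose Print progress lines (step, t, max |v|, density
#'   fluctuation).
#' @return A list with trace matrices (`time`, `probe_p` in Pa,
#'   `probe_v`, `flux_ml_s`, `flux_cum_ml`, `contact_axial`, `kin`,
#'   `piston_pos`), the final particle arrays, and the final structure
#'   states.
#' @export
run_scene <- function(scene, duration, dt = NULL, trace_every = NULL,
                      snapshot_dir = NULL, verbose = FALSE) {
  dim <- scene$dim
  h <- scene$h
  eos <- scene$eos
  if (is.null(dt))
    dt <- scene$cfl * h / (eos$c0 + scene$vmax_est)
  if (is.null(trace_every))
    trace_every <- max(1L, round(0.001 / dt))
  pos <- scene$pos; vel <- scene$vel
  rho <- scene$rho; mass <- scene$mass
  type <- scene$type
  n <- nrow(pos)
  fluid <- which(type == 0L)
  moving <- which(type == 2L)
  period <- if (is.null(scene$period)) numeric(dim) else scene$period
  mu <- rep(scene$mu, n)
  grav <- matrix(0, n, dim)
  grav[fluid, ] <- matrix(scene$gravity, length(fluid), dim, byrow = TRUE)
  adami <- identical(scene$wall_bc %||% "adami", "adami")
  nonfluid <- which(type != 0L)
  gvec <- as.numeric(scene$gravity)
  rep_k <- contact_auto_stiffness(stats::median(mass[fluid]), dt)

  structures <- scene$structures
  contact <- scene$contact
  if (!is.null(contact) && is.null(contact$stiffness)) {
    contact$stiffness <- contact_auto_stiffness(stats::median(mass[fluid]), dt)
    # sub-critical dashpot against contact chatter
    contact$normal_damping <- 0.7 *
      sqrt(contact$stiffness * stats::median(mass[fluid]))
    contact$pressure_coupling <- TRUE
  }

  pistons <- scene$pistons
  piston_vel <- lapply(pistons, function(p) numeric(3))
  wall_ref <- if (length(moving)) pos[moving, , drop = FALSE] else NULL

  total_steps <- ceiling((scene$settle_time + duration) / dt)
  settle_steps <- ceiling(scene$settle_time / dt)
  ntr <- floor(total_steps / trace_every) + 1L
  nprobe <- if (is.null(scene$probes)) 0L else nrow(scene$probes)
  nflux <- length(scene$flux_planes)
  nstr <- length(structures)
  nrec <- length(scene$recorders)
  tr <- list(time = numeric(ntr),
             probe_p = if (nprobe) matrix(NA_real_, ntr, nprobe),
             probe_v = if (nprobe) array(NA_real_, c(ntr, nprobe, dim)),
             flux_cum_ml = if (nflux) matrix(0, ntr, nflux,
               dimnames = list(NULL, names(scene$flux_planes))),
             contact_axial = if (nstr) matrix(0, ntr, nstr,
               dimnames = list(NULL, vapply(structures, `[[`, "", "name"))),
             kin = if (nrec) matrix(NA_real_, ntr, nrec,
               dimnames = list(NULL, names(scene$recorders))),
             piston_pos = if (length(pistons)) matrix(0, ntr, length(pistons)))
  flux_acc <- numeric(max(1L, nflux))
  itr <- 1L
  t <- -scene$settle_time
  kr <- kernel_spec(h, dim)

  record <- function(step_axial) {
    tr$time[itr] <<- t
    if (nprobe) {
      st <- fluid_state(pos[fluid, , drop = FALSE],
                        vel[fluid, , drop = FALSE], rho[fluid],
                        mass[fluid], numeric(length(fluid)), scene$mu)
      st$pressures <- eos_pressure(st$densities, eos)
      out <- cpp_interpolate(scene$probes, st$positions,
                             cbind(st$pressures, st$velocities),
                             st$densities, st$masses, h, dim, TRUE)
      tr$probe_p[itr, ] <<- out[, 1]
      tr$probe_v[itr, , ] <<- out[, -1, drop = FALSE]
    }
    if (nflux) tr$flux_cum_ml[itr, ] <<- flux_acc[seq_len(nflux)]
    if (nstr) tr$contact_axial[itr, ] <<- step_axial
    if (length(pistons))
      tr$piston_pos[itr, ] <<- vapply(seq_along(pistons), function(k) {
        rows <- pistons[[k]]$rows
        mean(pos[rows, , drop = FALSE] %*% pistons[[k]]$boundary$normal)
      }, 0)
    if (nrec) {
      sim <- list(t = t, pos = pos, vel = vel, rho = rho, type = type,
                  fluid = fluid, structures = structures, eos = eos,
                  kernel = kr, mass = mass)
      tr$kin[itr, ] <<- vapply(scene$recorders, function(f) f(sim), 0)
    }
    if (!is.null(snapshot_dir))
      write_particle_vtk(file.path(snapshot_dir,
                                   sprintf("particles_%05d.vtk", itr)),
                         pos, vel, rho, eos_pressure(rho, eos), dim)
    itr <<- itr + 1L
  }

  if (!is.null(snapshot_dir))
    dir.create(snapshot_dir, recursive = TRUE, showWarnings = FALSE)

  step_axial <- numeric(max(1L, nstr))
  record(step_axial)

  for (step in seq_len(total_steps)) {
    settling <- step <= settle_steps
    # prescribed wall kinematics at time t
    if (length(moving) && !is.null(scene$wall_track) && !settling) {
      pos[moving, ] <- wall_ref + interpolate_track(scene$wall_track, t)
      vel[moving, ] <- interpolate_track(scene$wall_track, t, deriv = 1)
    }
    # piston control (characteristic relation, relaxed between updates
    # to keep the pressure feedback loop stable)
    if (length(pistons)) {
      st <- NULL
      for (k in seq_along(pistons)) {
        p <- pistons[[k]]
        if ((step - 1L) %% p$update_every == 0L) {
          if (is.null(st)) {
            st <- fluid_state(pos[fluid, , drop = FALSE],
                              vel[fluid, , drop = FALSE], rho[fluid],
                              mass[fluid], numeric(length(fluid)), scene$mu)
            st$pressures <- eos_pressure(st$densities, eos)
          }
          bc <- p$boundary
          bc$origin <- colMeans(pos[p$rows, , drop = FALSE])
          tq <- if (settling) 0 else t
          vtgt <- apply_piston(bc, tq, st, kr, eos)
          vcap <- p$vmax %||% (0.25 * eos$c0)
          vn <- sum(vtgt * bc$normal)
          if (abs(vn) > vcap) vtgt <- vtgt * vcap / abs(vn)
          th <- p$relax %||% 0.3
          piston_vel[[k]] <- (1 - th) * piston_vel[[k]] + th * vtgt
        }
        vel[p$rows, ] <- matrix(piston_vel[[k]], length(p$rows), dim,
                                byrow = TRUE)
      }
    }

    P <- eos_pressure(rho, eos)
    if (adami) {
      P <- cpp_wall_pressure(pos, P, rho, mass, type, h, dim,
                             gvec, period)
      if (is.finite(eos$p_min %||% -Inf)) P <- pmax(P, eos$p_min)
      rho[nonfluid] <- eos$rho0 + P[nonfluid] / eos$c0^2
    }
    velv <- NULL
    if (isTRUE(scene$noslip_walls)) {
      wallr <- which(type != 0L)
      vf <- cpp_interpolate(pos[wallr, , drop = FALSE],
                            pos[fluid, , drop = FALSE],
                            vel[fluid, , drop = FALSE], rho[fluid],
                            mass[fluid], h, dim, TRUE)
      velv <- vel
      velv[wallr, ] <- 2 * vel[wallr, , drop = FALSE] - vf
    }
    rates <- cpp_fluid_rates_full(pos, vel, rho, P, mass, mu, h, dim,
                                  scene$alpha %||% 0, eos$c0,
                                  scene$delta %||% 0, period, velv,
                                  type, scene$dx, rep_k)
    acc <- rates$acc + grav

    # penalty contact with structures (fluid particles only).
    # Candidate (particle, face) pairs are found once per fluid step
    # with a widened search layer; during the structural substeps the
    # penalty is re-evaluated against the moving mesh so leaflet nodes
    # never receive a frozen-force impulse. The fluid receives the
    # substep-averaged reaction, so contact momentum balances exactly.
    if (nstr) {
      fl_pos <- pos[fluid, , drop = FALSE]
      fl_vel <- vel[fluid, , drop = FALSE]
      Pfl <- P[fluid]
      Vfl <- mass[fluid] / rho[fluid]
      for (s in seq_len(nstr)) {
        str <- structures[[s]]
        cand <- cpp_detect_contacts(fl_pos, str$mesh$nodes + str$state$u,
                                    str$mesh$triangles,
                                    2.5 * contact$thickness)
        nsub <- max(1L, str$substeps)
        if (str$substeps > 0L) {
          dt_cr <- membrane_stable_dt(str$mesh, structures[[s]]$state$u)
          nsub <- as.integer(min(str$max_substeps %||% 24,
                                 max(nsub, ceiling(dt / dt_cr))))
        }
        dts <- dt / nsub
        damp <- if (settling) max(str$damping, 200) else str$damping
        pf_acc <- NULL
        naxial <- 0
        for (ss in seq_len(nsub)) {
          cf <- eval_contact_pairs(cand$particle, cand$element, fl_pos,
                                   str$mesh, structures[[s]]$state$u,
                                   contact, particle_vel = fl_vel,
                                   surface_vel = structures[[s]]$state$v,
                                   particle_pressure = Pfl,
                                   particle_volume = Vfl, h = h)
          pf_acc <- if (is.null(pf_acc)) cf$particle_forces
                    else pf_acc + cf$particle_forces
          naxial <- naxial + (if (!is.null(str$axis))
            hydrodynamic_axial_force(cf$nodal_forces, str$axis) else
            sqrt(sum(colSums(cf$nodal_forces)^2)))
          if (str$substeps > 0L) {
            presc <- if (!is.null(str$prescribed_fn))
              str$prescribed_fn(if (settling) 0 else t + ss * dts) else NULL
            structures[[s]]$state <- step_structure(
              str$mesh, structures[[s]]$state, cf$nodal_forces, dts,
              prescribed = presc, damping = damp, slack = str$slack,
              vcap = str$vcap %||% 15)
          }
        }
        acc[fluid, ] <- acc[fluid, ] + (pf_acc / nsub) / mass[fluid]
        step_axial[s] <- naxial / nsub
      }
    }

    pos_before <- if (nflux) pos[fluid, , drop = FALSE] else NULL

    # advance particles
    vel[fluid, ] <- vel[fluid, ] + dt * acc[fluid, , drop = FALSE]
    if (settling) vel[fluid, ] <- vel[fluid, ] * exp(-scene$settle_damping * dt)
    pos[fluid, ] <- pos[fluid, ] + dt * vel[fluid, , drop = FALSE]
    for (p in pistons)
      pos[p$rows, ] <- pos[p$rows, , drop = FALSE] +
        dt * vel[p$rows, , drop = FALSE]
    if (adami) rho[fluid] <- rho[fluid] + dt * rates$drho[fluid]
    else rho <- rho + dt * rates$drho
    for (k in seq_len(dim))
      if (period[k] > 0) pos[, k] <- pos[, k] %% period[k]
    if (!is.null(scene$shepard_every) && scene$shepard_every > 0L &&
        step %% scene$shepard_every == 0L) {
      nb2 <- cpp_neighbor_pairs(pos, 2 * h, period)
      rho <- cpp_shepard_density(nb2$i, nb2$j, nb2$r, mass, rho, h, dim, n)
    }

    if (nflux && !settling) {
      pa <- pos[fluid, , drop = FALSE]
      for (q in seq_len(nflux)) {
        pl <- scene$flux_planes[[q]]
        qr <- flow_rate_through_plane(pos_before, pa, mass[fluid],
                                      rho[fluid], pl, dt)
        flux_acc[q] <- flux_acc[q] + qr * dt
      }
    }

    t <- t + dt
    if (step %% trace_every == 0L) record(step_axial)
    if (verbose && step %% (trace_every * 25L) == 0L) {
      vmag <- sqrt(max(rowSums(vel[fluid, , drop = FALSE]^2)))
      message(sprintf("step %d t=%.4f max|v|=%.3f drho/rho0=%.4f",
                      step, t, vmag,
                      max(abs(rho[fluid] / eos$rho0 - 1))))
    }
  }
  tr$time <- tr$time[seq_len(itr - 1L)]
  for (nm in c("probe_p", "flux_cum_ml", "contact_axial", "kin",
               "piston_pos"))
    if (!is.null(tr[[nm]])) tr[[nm]] <- tr[[nm]][seq_len(itr - 1L), ,
                                                 drop = FALSE]
  if (!is.null(tr$probe_v))
    tr$probe_v <- tr$probe_v[seq_len(itr - 1L), , , drop = FALSE]
  tr$flux_ml_s <- if (nflux && itr > 2L)
    apply(tr$flux_cum_ml, 2, function(v) c(0, diff(v))) /
      c(1, diff(tr$time))
  tr$dt <- dt
  tr$final <- list(pos = pos, vel = vel, rho = rho, mass = mass,
                   type = type)
  tr$structures <- structures
  tr$contact <- contact
  tr
}
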
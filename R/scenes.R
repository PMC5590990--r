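# Synthetic scene generator: every solver feature and metric is testable
# from these fixtures without any external data.

# drop near-coincident points (overlapping lattice unions)
dedupe_points <- function(pos, dx) {
  key <- apply(round(pos / (dx / 2)), 1, paste, collapse = ",")
  pos[!duplicated(key), , drop = FALSE]
}

lattice2d <- function(x0, x1, y0, y1, dx) {
  xs <- seq(x0 + dx / 2, x1 - dx / 2 + 1e-12, by = dx)
  ys <- seq(y0 + dx / 2, y1 - dx / 2 + 1e-12, by = dx)
  as.matrix(expand.grid(x = xs, y = ys))
}

lattice3d <- function(x0, x1, y0, y1, z0, z1, dx) {
  xs <- seq(x0 + dx / 2, x1 - dx / 2 + 1e-12, by = dx)
  ys <- seq(y0 + dx / 2, y1 - dx / 2 + 1e-12, by = dx)
  zs <- seq(z0 + dx / 2, z1 - dx / 2 + 1e-12, by = dx)
  as.matrix(expand.grid(x = xs, y = ys, z = zs))
}

disk_points <- function(radius, dx, center = c(0, 0), z = 0) {
  g <- lattice2d(-radius, radius, -radius, radius, dx)
  g <- g[g[, 1]^2 + g[, 2]^2 <= radius^2, , drop = FALSE]
  cbind(g[, 1] + center[1], g[, 2] + center[2], z)
}

ring_points <- function(r, dx, z = 0, center = c(0, 0), phase = 0) {
  n <- max(6L, round(2 * pi * r / dx))
  a <- phase + 2 * pi * seq_len(n) / n
  cbind(center[1] + r * cos(a), center[2] + r * sin(a), z)
}

tube_shell_points <- function(radius, z0, z1, dx, layers = 2,
                              center = c(0, 0)) {
  zs <- seq(z0 + dx / 2, z1 - dx / 2 + 1e-12, by = dx)
  out <- NULL
  for (l in seq_len(layers) - 1) {
    r <- radius + dx / 2 + l * dx
    for (iz in seq_along(zs))
      out <- rbind(out, ring_points(r, dx, zs[iz], center,
                                    phase = 0.5 * (iz %% 2) * dx / r))
  }
  out
}

# 2 shell layers sampling a truncated ellipsoid (x/a)^2+(y/a)^2+(z/c)^2=1,
# z < zb, apex at z = -c.
ellipsoid_shell_points <- function(a, c, zb, dx, layers = 2) {
  th_b <- acos(zb / c) # polar angle of the base cut (z = c cos th)
  arc <- function(t) sqrt((a * cos(t))^2 + (c * sin(t))^2)
  # march polar angle from base cut to apex in ~dx arc steps
  out <- NULL
  for (l in seq_len(layers) - 1) {
    off <- dx / 2 + l * dx
    t <- th_b + (dx / 2) / arc(th_b)
    repeat {
      if (t >= pi - 0.5 * dx / arc(pi - 1e-3)) break
      r_xy <- a * sin(t); z <- c * cos(t)
      # outward normal of the ellipsoid at (r_xy, z)
      nr <- r_xy / a^2; nz <- z / c^2
      nn <- sqrt(nr^2 + nz^2); nr <- nr / nn; nz <- nz / nn
      rr <- r_xy + off * nr; zz <- z + off * nz
      out <- rbind(out, ring_points(rr, dx, zz,
                                    phase = 0.5 * (nrow(out %||% matrix(0, 0, 3)) %% 2) * dx / max(rr, dx)))
      t <- t + dx / arc(t)
    }
    # apex cap point
    out <- rbind(out, c(0, 0, -c - off))
  }
  out
}

#' Scene specification
#'
#' Named geometric/resolution parameters for the synthetic scene
#' generators. Every scene is fully reproducible from its spec: the
#' generators are deterministic (seeded where jitter is requested).
#'
#' @param kind Scene kind (informational).
#' @param dx Particle spacing (m).
#' @param seed Seed for any jittered seeding (none by default).
#' @param ... Scene-specific geometric parameters.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(kind, dx, seed = 1L, ...) {
  if (dx <= 0) stop("dx must be > 0")
  structure(c(list(kind = kind, dx = dx, seed = seed), list(...)),
            class = "scene_spec")
}

#' Hydrostatic tank benchmark scene
#'
#' A 2D box of blood-density fluid under gravity with rigid
#' boundary-particle walls. After damped settling the interior pressure
#' follows `P(z) = rho g (H - z)`.
#'
#' @param width,height Tank width and fill height (m).
#' @param dx Particle spacing (m).
#' @param rho0 Reference density (kg/m^3).
#' @param mu Viscosity (Pa s).
#' @param g Gravity (m/s^2).
#' @return An [fsi_scene()]; probes along the mid-column are preconfigured.
#' @export
make_hydrostatic_tank <- function(width = 0.04, height = 0.06, dx = 0.0015,
                                  rho0 = 1056, mu = 0.0035, g = 9.81) {
  fl <- lattice2d(0, width, 0, height, dx)
  nw <- 3
  wall <- rbind(
    lattice2d(-nw * dx, width + nw * dx, -nw * dx, 0, dx),
    lattice2d(-nw * dx, 0, 0, height + 4 * dx, dx),
    lattice2d(width, width + nw * dx, 0, height + 4 * dx, dx))
  pos <- rbind(fl, wall)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(1L, nrow(wall)))
  c0 <- 10 * sqrt(g * height)
  # hydrostatic density initialization shortens the settling transient
  rho <- rho0 + rho0 * g * pmax(height - pos[, 2], 0) / c0^2
  probes <- cbind(width / 2, seq(0.12, 0.66, length.out = 8) * height)
  fsi_scene(dim = 2, dx = dx, pos = pos, vel = matrix(0, n, 2),
            rho = rho, mass = rep(rho0 * dx^2, n), type = type,
            eos = eos_linear(rho0, c0, p_min = 0), mu = mu,
            gravity = c(0, -g),
            probes = probes, settle_time = 0.55, settle_damping = 25,
            alpha = 0.1, delta = 0.1,
            vmax_est = sqrt(g * height),
            meta = list(height = height, g = g, rho0 = rho0))
}

#' Plane Poiseuille channel benchmark scene
#'
#' A 2D gravity-driven channel, periodic in x, with no-slip
#' boundary-particle walls. The steady velocity profile is the analytic
#' parabola `u(y) = g y (H - y) / (2 nu)`. The benchmark fluid is more
#' viscous than blood so the viscous diffusion time stays short.
#'
#' @param height Channel height H (m).
#' @param length Periodic box length (m).
#' @param dx Particle spacing (m).
#' @param rho0 Density (kg/m^3).
#' @param mu Viscosity (Pa s).
#' @param gx Driving body acceleration (m/s^2).
#' @return An [fsi_scene()].
#' @export
make_poiseuille_channel <- function(height = 0.01, length = 0.024,
                                    dx = height / 16, rho0 = 1000,
                                    mu = 0.1, gx = 0.4) {
  fl <- lattice2d(0, length, 0, height, dx)
  nw <- 3
  wall <- rbind(lattice2d(0, length, -nw * dx, 0, dx),
                lattice2d(0, length, height, height + nw * dx, dx))
  pos <- rbind(fl, wall)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(1L, nrow(wall)))
  umax <- gx * height^2 / (8 * mu / rho0)
  c0 <- max(10 * umax, 0.5)
  fsi_scene(dim = 2, dx = dx, pos = pos, vel = matrix(0, n, 2),
            rho = rep(rho0, n), mass = rep(rho0 * dx^2, n), type = type,
            eos = eos_linear(rho0, c0), mu = mu, gravity = c(gx, 0),
            period = c(length, 0), delta = 0.1, noslip_walls = TRUE,
            vmax_est = umax,
            meta = list(height = height, gx = gx, nu = mu / rho0,
                        umax = umax))
}

#' Mean streamwise velocity profile across the channel
#'
#' Bin-averaged `u_x(y)` of the fluid particles, for comparison with the
#' analytic parabola.
#'
#' @param result A [run_scene()] result from the Poiseuille scene.
#' @param height Channel height (m).
#' @param nbins Number of y bins.
#' @return Data frame with `y`, `u`.
#' @export
poiseuille_profile <- function(result, height, nbins = 12) {
  fl <- result$final$type == 0L
  y <- result$final$pos[fl, 2]
  u <- result$final$vel[fl, 1]
  br <- seq(0, height, length.out = nbins + 1)
  bin <- cut(y, br, include.lowest = TRUE)
  data.frame(y = (br[-1] + br[-(nbins + 1)]) / 2,
             u = as.numeric(tapply(u, bin, mean)))
}

# isotropic MHGO parameter helper for non-valve structures (gate):
# kappa = 1/3 makes the fiber term isotropic; k1 ~ 0 leaves the matrix.
gate_material <- function(c1_kpa) {
  mhgo_params(c1 = c1_kpa, c2 = 0.5, k1 = 1e-8, k2 = 1, theta = 0,
              kappa = 1 / 3, D = 1e-5)
}

# rectangular membrane strip in the x = x0 plane, spanning y in (y0, y1)
# and z in (z0, z1); grid ny x nz nodes
strip_mesh <- function(x0, y0, y1, z0, z1, ny, nz, thickness, material,
                       matname = "gate") {
  ys <- seq(y0, y1, length.out = ny)
  zs <- seq(z0, z1, length.out = nz)
  nodes <- as.matrix(expand.grid(x = x0, y = ys, z = zs))[, c("x", "y", "z")]
  idx <- function(iy, iz) (iz - 1) * ny + iy
  tris <- NULL
  for (iz in seq_len(nz - 1)) for (iy in seq_len(ny - 1)) {
    a <- idx(iy, iz); b <- idx(iy + 1, iz)
    cc <- idx(iy + 1, iz + 1); d <- idx(iy, iz + 1)
    tris <- rbind(tris, c(a, b, cc), c(a, cc, d))
  }
  mats <- list(); mats[[matname]] <- material
  top <- which(abs(nodes[, 3] - z1) < 1e-12)
  structural_mesh(nodes, tris, thickness = thickness,
                  fiber_dir = matrix(rep(c(0, 1, 0), nrow(tris)),
                                     ncol = 3, byrow = TRUE),
                  tri_material = matname, materials = mats,
                  node_sets = list(top = top))
}

#' Elastic gate benchmark scene
#'
#' A water column retained by a membrane gate clamped along its top
#' edge, periodic in the spanwise (y) direction so the dam is free of
#' side-wall corner effects. With `rigid = TRUE` every gate node is held
#' fixed (the stiffness -> infinity limit) and the settled contact
#' resultant on the gate equals the hydrostatic force
#' `0.5 rho g H^2 w`; with a soft gate the free bottom tip deflects
#' downstream under the dam load.
#'
#' @param water_height Water column height (m).
#' @param tank_length Tank length in x (m).
#' @param width Spanwise periodic width (m).
#' @param dx Particle spacing (m).
#' @param rigid Pin all gate nodes (rigid limit).
#' @param c1_kpa Gate matrix stiffness (kPa) for the soft case.
#' @param thickness Gate thickness (m).
#' @param rho0,mu,g Fluid properties and gravity.
#' @return An [fsi_scene()].
#' @export
make_elastic_gate <- function(water_height = 0.048, tank_length = 0.04,
                              width = 0.0096, dx = 0.0024, rigid = TRUE,
                              c1_kpa = 30, thickness = 0.001,
                              rho0 = 1056, mu = 0.0035, g = 9.81) {
  fl <- lattice3d(0, tank_length - dx, 0, width, 0, water_height, dx)
  nw <- 3
  ztop <- water_height + 4 * dx
  # floor (continuing under the gate) and upstream wall; y is periodic
  wall <- dedupe_points(rbind(
    lattice3d(-nw * dx, tank_length + nw * dx, 0, width, -nw * dx, 0, dx),
    lattice3d(-nw * dx, 0, 0, width, 0, ztop, dx)), dx)
  pos <- rbind(fl, wall)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(1L, nrow(wall)))
  gate_h <- water_height + 3 * dx
  mat <- gate_material(if (rigid) 1e5 else c1_kpa)
  # gate spans beyond the periodic box in y; clamped at the top edge
  mesh <- strip_mesh(tank_length, -2 * dx, width + 2 * dx, -2 * dx,
                     gate_h,
                     ny = max(4, round((width + 4 * dx) / dx) + 1),
                     nz = max(8, round((gate_h + 2 * dx) / dx) + 1),
                     thickness = thickness, material = mat)
  pin <- if (rigid) seq_len(nrow(mesh$nodes)) else mesh$node_sets$top
  prescribed_fn <- local({
    pin_idx <- pin
    function(t) list(idx = pin_idx, u = matrix(0, length(pin_idx), 3))
  })
  str <- list(name = "gate", mesh = mesh, state = structure_state(mesh),
              prescribed_fn = prescribed_fn,
              substeps = if (rigid) 0L else 20L, damping = 20,
              slack = TRUE, axis = c(1, 0, 0))
  c0 <- 10 * sqrt(g * water_height)
  rho <- rho0 + rho0 * g * pmax(water_height - pos[, 3], 0) / c0^2
  fsi_scene(dim = 3, dx = dx, pos = pos, vel = matrix(0, n, 3),
            rho = rho, mass = rep(rho0 * dx^3, n), type = type,
            eos = eos_linear(rho0, c0, p_min = 0), mu = mu,
            gravity = c(0, 0, -g), period = c(0, width, 0),
            structures = list(str), alpha = 0.1, delta = 0.1,
            settle_time = 0.4, settle_damping = 25,
            contact = contact_config(thickness = 0.8 * dx),
            recorders = list(
              tip_x = function(sim)
                mean(sim$structures[[1]]$state$u[
                  which(abs(sim$structures[[1]]$mesh$nodes[, 3] -
                              min(sim$structures[[1]]$mesh$nodes[, 3])) <
                          1e-9), 1])),
            vmax_est = sqrt(g * water_height),
            meta = list(water_height = water_height, width = width,
                        g = g, rho0 = rho0))
}

# --- tri-leaflet valve geometry --------------------------------------------

# Leaflet surface: linear blend between the annulus arc on the tube wall
# (z = z0, radius R) and the closed free edge lying on the Y-shaped
# coaptation pattern at z = z0 + height.  The closed state is the
# stress-free reference.
trileaflet_mesh <- function(radius, z0, height, nphi = 7, ns = 5,
                            thickness = 4e-4, material,
                            matname = "av_leaflet") {
  nodes <- NULL; tris <- NULL; fib <- NULL
  free_edge <- integer(0); belly <- integer(0)
  hinge <- integer(0); tip <- integer(0); attach <- integer(0)
  for (lf in 0:2) {
    phi0 <- -pi / 2 + lf * 2 * pi / 3 # commissure angles phi0, phi0+120deg
    base <- nrow(nodes %||% matrix(0, 0, 3))
    phis <- phi0 + seq(0, 2 * pi / 3, length.out = nphi)
    svals <- seq(0, 1, length.out = ns)
    c1 <- c(radius * cos(phis[1]), radius * sin(phis[1]), z0 + height)
    c2 <- c(radius * cos(phis[nphi]), radius * sin(phis[nphi]), z0 + height)
    O <- c(0, 0, z0 + height)
    for (is in seq_len(ns)) {
      s <- svals[is]
      for (ip in seq_len(nphi)) {
        phi <- phis[ip]
        w <- c(radius * cos(phi), radius * sin(phi), z0)
        tau <- (ip - 1) / (nphi - 1)
        e <- if (tau <= 0.5) (1 - 2 * tau) * c1 + 2 * tau * O
             else (2 * tau - 1) * c2 + (2 - 2 * tau) * O
        nodes <- rbind(nodes, (1 - s) * w + s * e)
      }
    }
    idx <- function(ip, is) base + (is - 1) * nphi + ip
    for (is in seq_len(ns - 1)) for (ip in seq_len(nphi - 1)) {
      a <- idx(ip, is); b <- idx(ip + 1, is)
      cc <- idx(ip + 1, is + 1); d <- idx(ip, is + 1)
      if ((ip + is) %% 2 == 0) tris <- rbind(tris, c(a, b, cc), c(a, cc, d))
      else tris <- rbind(tris, c(a, b, d), c(b, cc, d))
    }
    # attachment: the annulus arc plus the two commissure corner nodes
    # (side edges free, as in a native valve; adjacent leaflets meet
    # only along the coaptation line)
    attach <- c(attach, idx(seq_len(nphi), 1),
                idx(1, ns), idx(nphi, ns))
    free_edge <- c(free_edge, idx(seq(2, nphi - 1), ns))
    mid <- (nphi + 1) %/% 2
    belly <- c(belly, idx(mid, (ns + 1) %/% 2))
    hinge <- c(hinge, idx(mid, 1))
    tip <- c(tip, idx(mid, ns))
  }
  # circumferential fiber direction: tangent in the azimuthal direction
  ctr <- (nodes[tris[, 1], ] + nodes[tris[, 2], ] + nodes[tris[, 3], ]) / 3
  fib <- cbind(-ctr[, 2], ctr[, 1], 0)
  bad <- sqrt(rowSums(fib^2)) < 1e-9
  if (any(bad))
    fib[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
  mats <- list(); mats[[matname]] <- material
  structural_mesh(nodes, tris, thickness = thickness, fiber_dir = fib,
                  tri_material = matname, materials = mats,
                  node_sets = list(attach = unique(attach),
                                   free_edge = free_edge, belly = belly,
                                   hinge = hinge, tip = tip))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Projected orifice area of a valve
#'
#' Shoelace area of the ordered free-edge node loop projected onto the
#' plane normal to the valve axis. Near zero for the closed (coapted)
#' reference and increasing as the leaflets open.
#'
#' @param nodes Current free-edge node positions (ordered loop, n x 3).
#' @param axis Valve axis unit vector.
#' @return Area (m^2).
#' @export
valve_orifice_area <- function(nodes, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  b1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- b1 - sum(b1 * axis) * axis; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
          axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  x <- nodes %*% b1; y <- nodes %*% b2
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Straight-tube tri-leaflet valve scene
#'
#' A rigid tube with a parametric tri-leaflet membrane valve bound to the
#' aortic-leaflet MHGO material, pressure pistons at both ends, and a
#' downstream flux plane. The default waveforms drive a forward-pressure
#' opening phase followed by a reverse-pressure closing phase, so valve
#' opening, closure and the regurgitant (closing) volume can all be
#' measured in one run.
#'
#' @param radius Tube/annulus radius (m).
#' @param tube_length Fluid column length (m).
#' @param leaflet_height Leaflet height (m).
#' @param dx Particle spacing (m).
#' @param p_forward,p_back Inlet pressure during the forward (opening)
#'   and reverse (closing) phases (mmHg).
#' @param p_out Outlet pressure during the forward phase (mmHg).
#' @param p_close Outlet pressure during the closing phase (mmHg); the
#'   reverse gradient `p_close - p_back` drives valve closure, as the
#'   diastolic aortic-ventricular gradient does physiologically.
#' @param t_switch Time of the forward-to-reverse switch (s).
#' @param rho0,mu Blood properties.
#' @param material MHGO parameters for the leaflets (default: the human
#'   aortic-leaflet row of [valve_material_table()]).
#' @param thickness Leaflet thickness (m).
#' @return An [fsi_scene()] with recorders `orifice_cm2`, `belly_vr` and
#'   `angle_deg`.
#' @export
make_tube_valve <- function(radius = 0.010, tube_length = 0.06,
                            leaflet_height = 0.011, dx = 0.002,
                            p_forward = 30, p_back = 2, p_out = 10,
                            p_close = 45, t_switch = 0.035, rho0 = 1056,
                            mu = 0.0035,
                            material = NULL, thickness = 4e-4) {
  if (is.null(material)) material <- tissue_params("av_leaflet")
  zv <- tube_length / 2 - leaflet_height / 2
  mesh <- trileaflet_mesh(radius, zv, leaflet_height, thickness = thickness,
                          material = material)
  # fluid column; carve out the leaflet contact layer
  fl <- NULL
  nz <- round(tube_length / dx)
  for (iz in seq_len(nz)) {
    z <- (iz - 0.5) * dx
    fl <- rbind(fl, disk_points(radius - 0.6 * dx, dx, z = z))
  }
  cth <- 0.8 * dx
  cts <- cpp_detect_contacts(fl, mesh$nodes, mesh$triangles, 1.3 * cth)
  if (length(cts$particle)) fl <- fl[-unique(cts$particle), , drop = FALSE]
  wall <- tube_shell_points(radius, -2 * dx, tube_length + 2 * dx, dx)
  p_in_rows_z <- c(-1.5 * dx, -0.5 * dx)
  p_out_rows_z <- c(tube_length + 0.5 * dx, tube_length + 1.5 * dx)
  # plates slightly overlap the wall-shell radius so no edge gap opens
  pl_in <- rbind(disk_points(radius + 0.4 * dx, dx, z = p_in_rows_z[1]),
                 disk_points(radius + 0.4 * dx, dx, z = p_in_rows_z[2]))
  pl_out <- rbind(disk_points(radius + 0.4 * dx, dx, z = p_out_rows_z[1]),
                  disk_points(radius + 0.4 * dx, dx, z = p_out_rows_z[2]))
  pos <- rbind(fl, wall, pl_in, pl_out)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(1L, nrow(wall)),
            rep(100L, nrow(pl_in)), rep(101L, nrow(pl_out)))
  wf_in <- data.frame(time = c(0, 0.004, 0.008, t_switch, t_switch + 0.008, 10),
                      mmhg = c(p_out, p_out, p_forward, p_forward, p_back,
                               p_back))
  bc_in <- pressure_boundary(c(0, 0, p_in_rows_z[2]), c(0, 0, 1), radius,
                             wf_in)
  wf_out <- data.frame(time = c(0, t_switch, t_switch + 0.008, 10),
                       mmhg = c(p_out, p_out, p_close, p_close))
  bc_out <- pressure_boundary(c(0, 0, p_out_rows_z[1]), c(0, 0, -1), radius,
                              wf_out)
  pistons <- list(list(boundary = bc_in, rows = which(type == 100L),
                       update_every = 2L, relax = 0.2, vmax = 1.5),
                  list(boundary = bc_out, rows = which(type == 101L),
                       update_every = 2L, relax = 0.2, vmax = 1.5))
  pin <- mesh$node_sets$attach
  prescribed_fn <- local({
    pin_idx <- pin
    function(t) list(idx = pin_idx, u = matrix(0, length(pin_idx), 3))
  })
  str <- list(name = "valve", mesh = mesh, state = structure_state(mesh),
              prescribed_fn = prescribed_fn, substeps = 8L, damping = 200,
              slack = TRUE, axis = c(0, 0, 1), vcap = 10,
              max_substeps = 24L)
  vmax <- 2
  c0 <- max(12, 8 * sqrt(mmhg_to_pa(p_forward) / rho0))
  eos <- eos_linear(rho0, c0, p_min = -1500)
  meta <- list(radius = radius, zv = zv, leaflet_height = leaflet_height,
               free_edge = free_edge_loop(mesh), rho0 = rho0)
  recorders <- list(
    orifice_cm2 = function(sim) {
      m <- sim$structures[[1]]
      nd <- m$mesh$nodes + m$state$u
      1e4 * valve_orifice_area(nd[meta$free_edge, , drop = FALSE])
    },
    belly_vr = function(sim) {
      m <- sim$structures[[1]]
      b <- m$mesh$node_sets$belly[1]
      p <- m$mesh$nodes[b, ] + m$state$u[b, ]
      rhat <- c(p[1], p[2], 0)
      rl <- sqrt(sum(rhat^2))
      if (rl < 1e-9) return(0)
      sum(m$state$v[b, ] * rhat / rl)
    },
    angle_deg = function(sim) {
      m <- sim$structures[[1]]
      h <- m$mesh$node_sets$hinge[1]; tp <- m$mesh$node_sets$tip[1]
      opening_angle(m$mesh$nodes[h, ] + m$state$u[h, ],
                    m$mesh$nodes[tp, ] + m$state$u[tp, ], c(0, 0, 1))
    })
  rho_init <- rho0 * (1 + mmhg_to_pa(p_out) / (rho0 * c0^2))
  fsi_scene(dim = 3, dx = dx, pos = pos, vel = matrix(0, n, 3),
            rho = rep(rho_init, n), mass = rep(rho0 * dx^3, n),
            type = type,
            eos = eos, mu = mu,
            pistons = pistons, structures = list(str),
            contact = contact_config(thickness = cth),
            probes = rbind(c(0, 0, zv - 2 * radius),
                           c(0, 0, min(zv + leaflet_height + 6 * radius,
                                       tube_length - 3 * dx))),
            flux_planes = list(downstream = list(
              origin = c(0, 0, zv + leaflet_height + 4 * dx),
              normal = c(0, 0, 1), radius = radius)),
            recorders = recorders, settle_time = 0.02,
            alpha = 0.15, delta = 0.1,
            vmax_est = vmax, meta = meta)
}

# ordered free-edge loop (by azimuth of the reference position, which
# traverses each leaflet's edge from commissure to commissure)
free_edge_loop <- function(mesh) {
  fe <- mesh$node_sets$free_edge
  ang <- atan2(mesh$nodes[fe, 2], mesh$nodes[fe, 1])
  # stable order: leaflet by leaflet, each edge already sequential
  fe
}

#' Closed cavity mesh of the idealized left ventricle
#'
#' Truncated-ellipsoid surface with a flat basal cap, triangulated and
#' outward-oriented, scaled radially by `s`. Used as the
#' divergence-theorem volume oracle for the wall track.
#'
#' @param a,c Radial and long semi-axes (m).
#' @param zb Basal truncation height (m).
#' @param s Radial scale factor.
#' @param nring,nphi Discretization.
#' @return List with `nodes`, `tris`.
#' @export
lv_cavity_mesh <- function(a, c, zb, s = 1, nring = 24, nphi = 36) {
  th_b <- acos(zb / c)
  ths <- seq(th_b, pi, length.out = nring + 1)
  nodes <- NULL
  for (i in seq_len(nring)) {
    th <- ths[i]
    ph <- 2 * pi * seq_len(nphi) / nphi
    nodes <- rbind(nodes, cbind(s * a * sin(th) * cos(ph),
                                s * a * sin(th) * sin(ph),
                                c * cos(th)))
  }
  apex <- nrow(nodes) + 1
  nodes <- rbind(nodes, c(0, 0, -c))
  ctr <- nrow(nodes) + 1
  nodes <- rbind(nodes, c(0, 0, zb))
  tris <- NULL
  idx <- function(i, j) (i - 1) * nphi + (j - 1) %% nphi + 1
  for (i in seq_len(nring - 1)) for (j in seq_len(nphi)) {
    # outward orientation (normals away from the cavity)
    tris <- rbind(tris,
                  c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                  c(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1)))
  }
  for (j in seq_len(nphi))
    tris <- rbind(tris, c(idx(nring, j), apex, idx(nring, j + 1)))
  for (j in seq_len(nphi))
    tris <- rbind(tris, c(idx(1, j), idx(1, j + 1), ctr))
  list(nodes = nodes, tris = tris)
}

#' Idealized left-ventricle scene
#'
#' A truncated-ellipsoid chamber whose wall motion is built from a
#' 10-keyframe cavity-volume waveform (defaults: EDV 112 ml, ESV 47 ml,
#' period 0.8 s): radial wall scaling `s_k = sqrt(V_k / V_EDV)` makes the
#' cavity volume match the waveform exactly at every keyframe, and the
#' periodic cubic-spline track interpolates between phases. Two basal
#' orifices (aortic and mitral) continue into straight tube extensions
#' closed by pressure pistons; flux planes sit in the tubes.
#'
#' @param waveform Keyframe data frame from [lv_volume_waveform()].
#' @param dx Particle spacing (m).
#' @param r_av,r_mv Orifice/tube radii (m).
#' @param tube_length Tube extension length (m).
#' @param p_av,p_mv Piston pressures (mmHg): constants or waveform tables.
#' @param rho0,mu Blood properties.
#' @param aspect Long-axis to radial-axis ratio `c/a`.
#' @return An [fsi_scene()]; `meta` carries the geometry, the track and
#'   the keyframe volumes.
#' @export
make_idealized_lv <- function(waveform = lv_volume_waveform(), dx = 0.003,
                              r_av = 0.009, r_mv = 0.013,
                              tube_length = 0.05, p_av = 10, p_mv = 10,
                              rho0 = 1056, mu = 0.0035, aspect = 1.6) {
  period <- nrow(waveform) * diff(waveform$time[1:2])
  edv <- ml_to_m3(waveform$ml[1])
  # size the ellipsoid so the truncated cavity volume equals EDV
  ub <- 0.4
  shape <- pi * (ub - ub^3 / 3 + 2 / 3) * aspect
  a <- (edv / shape)^(1 / 3)
  c <- aspect * a
  zb <- ub * c
  s_k <- sqrt(waveform$ml / waveform$ml[1])
  # wall particles on the ellipsoid below the base
  wall <- ellipsoid_shell_points(a, c, zb, dx)
  # displacement keyframes: radial scaling of x, y
  K <- length(s_k)
  disp <- array(0, c(nrow(wall), 3, K))
  for (k in seq_len(K)) {
    disp[, 1, k] <- (s_k[k] - 1) * wall[, 1]
    disp[, 2, k] <- (s_k[k] - 1) * wall[, 2]
  }
  track <- motion_track(waveform$time, disp, periodic = TRUE,
                        period = period)
  # basal plate (static) with two orifice holes
  hole_av <- c(-a * 0.45, 0); hole_mv <- c(a * 0.40, 0)
  ext <- 1.15 * a + 3 * dx
  plate <- NULL
  for (zz in c(zb + dx / 2, zb + 3 * dx / 2)) {
    g <- lattice2d(-ext, ext, -ext, ext, dx)
    keep <- (g[, 1]^2 + g[, 2]^2) <= ext^2 &
      ((g[, 1] - hole_av[1])^2 + g[, 2]^2) > r_av^2 &
      ((g[, 1] - hole_mv[1])^2 + g[, 2]^2) > r_mv^2
    plate <- rbind(plate, cbind(g[keep, , drop = FALSE], zz))
  }
  tube_av <- tube_shell_points(r_av, zb, zb + tube_length, dx,
                               center = c(hole_av[1], 0))
  tube_mv <- tube_shell_points(r_mv, zb, zb + tube_length, dx,
                               center = c(hole_mv[1], 0))
  # static skirt just below the plate, outside the end-diastolic wall:
  # seals the basal corner against leakage into the space the
  # contracting wall vacates
  r_base <- a * sin(acos(zb / c))
  skirt <- NULL
  for (zz in c(zb - dx / 2, zb - 3 * dx / 2))
    for (rr in seq(r_base + 2.6 * dx, 1.15 * a + 2 * dx, by = dx))
      skirt <- rbind(skirt, ring_points(rr, dx, zz))
  # fluid: cavity seeded as a 3D lattice clipped to a slightly offset
  # ellipsoid (tight fill; the pressurized settle closes what remains),
  # plus tube columns (piston head-space left clear)
  col_h <- tube_length - 12 * dx
  g <- lattice3d(-a, a, -a, a, -c, zb, dx)
  aoff <- a - 0.3 * dx; coff <- c - 0.3 * dx
  keep <- (g[, 1] / aoff)^2 + (g[, 2] / aoff)^2 + (g[, 3] / coff)^2 <= 1 &
    g[, 3] < zb - 0.45 * dx
  fl <- g[keep, , drop = FALSE]
  for (z in seq(zb + dx / 2, zb + col_h, by = dx)) {
    fl <- rbind(fl, disk_points(r_av - 0.4 * dx, dx,
                                center = c(hole_av[1], 0), z = z),
                disk_points(r_mv - 0.4 * dx, dx,
                            center = c(hole_mv[1], 0), z = z))
  }
  zp <- zb + col_h + dx
  pl_av <- rbind(disk_points(r_av + 0.4 * dx, dx, center = c(hole_av[1], 0),
                             z = zp),
                 disk_points(r_av + 0.4 * dx, dx, center = c(hole_av[1], 0),
                             z = zp + dx))
  pl_mv <- rbind(disk_points(r_mv + 0.4 * dx, dx, center = c(hole_mv[1], 0),
                             z = zp),
                 disk_points(r_mv + 0.4 * dx, dx, center = c(hole_mv[1], 0),
                             z = zp + dx))
  pos <- rbind(fl, wall, plate, tube_av, tube_mv, skirt, pl_av, pl_mv)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(2L, nrow(wall)),
            rep(1L, nrow(plate) + nrow(tube_av) + nrow(tube_mv) +
                  nrow(skirt)),
            rep(100L, nrow(pl_av)), rep(101L, nrow(pl_mv)))
  bc_av <- pressure_boundary(c(hole_av[1], 0, zp), c(0, 0, -1), r_av, p_av)
  bc_mv <- pressure_boundary(c(hole_mv[1], 0, zp), c(0, 0, -1), r_mv, p_mv)
  pistons <- list(list(boundary = bc_av, rows = which(type == 100L),
                       update_every = 2L, relax = 0.15, vmax = 0.8),
                  list(boundary = bc_mv, rows = which(type == 101L),
                       update_every = 2L, relax = 0.15, vmax = 0.8))
  c0 <- 12
  # initialize at the piston target pressure so settling starts close to
  # equilibrium
  p0 <- mmhg_to_pa(if (is.data.frame(p_av)) p_av$mmhg[1] else p_av)
  rho_init <- rho0 * (1 + p0 / (rho0 * c0^2))
  fsi_scene(dim = 3, dx = dx, pos = pos, vel = matrix(0, n, 3),
            rho = rep(rho_init, n), mass = rep(rho0 * dx^3, n), type = type,
            eos = eos_linear(rho0, c0, p_min = -1500), mu = mu,
            wall_track = track, pistons = pistons,
            flux_planes = list(
              av = list(origin = c(hole_av[1], 0, zb + col_h / 2),
                        normal = c(0, 0, 1), radius = r_av),
              mv = list(origin = c(hole_mv[1], 0, zb + col_h / 2),
                        normal = c(0, 0, 1), radius = r_mv)),
            settle_time = 0.18, settle_damping = 40,
            alpha = 0.15, delta = 0.1,
            vmax_est = 1.2,
            meta = list(a = a, c = c, zb = zb, s_k = s_k,
                        waveform = waveform, period = period,
                        track = track, hole_av = hole_av,
                        hole_mv = hole_mv))
}
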
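unit_square_surface <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  structural_mesh(nodes, triangles = rbind(c(1, 2, 3), c(1, 3, 4)),
                  materials = list(default = tissue_params("av_leaflet")))
}

test_that("contact detection finds exactly the particles in the contact layer", {
  surf <- unit_square_surface()
  cfg <- contact_config(stiffness = 100, thickness = 0.01)
  # far particle: empty list
  far <- detect_contacts(matrix(c(0.5, 0.5, 0.5), 1, 3), surf, cfg)
  expect_length(far$particle, 0)
  # particle over the face at penetration delta
  delta <- 1e-4
  cts <- detect_contacts(matrix(c(0.25, 0.25, 0.01 - delta), 1, 3),
                         surf, cfg)
  expect_length(cts$particle, 1)
  expect_equal(cts$depth, delta, tolerance = 1e-12)
  expect_equal(cts$normal[1, ], c(0, 0, 1))
  expect_equal(sum(cts$weights), 1, tolerance = 1e-12)
  # particle on the shared edge: assigned to exactly one face (lowest index)
  edge <- detect_contacts(matrix(c(0.5, 0.5, 0.004), 1, 3), surf, cfg)
  expect_length(edge$particle, 1)
  expect_equal(edge$element, 1L)
  # degenerate face excluded with a warning
  bad <- surf
  bad$nodes[2, ] <- bad$nodes[1, ]
  expect_warning(detect_contacts(matrix(c(0.25, 0.25, 0.004), 1, 3),
                                 bad, cfg), "degenerate")
})

test_that("penalty forces follow k x depth and balance to machine precision", {
  surf <- unit_square_surface()
  k <- 250
  cfg <- contact_config(stiffness = k, thickness = 0.01)
  # empty contacts: zero everywhere
  empty <- detect_contacts(matrix(c(5, 5, 5), 1, 3), surf, cfg)
  z <- penalty_forces(empty, cfg, surf, 1)
  expect_equal(max(abs(z$particle_forces)), 0)
  expect_equal(max(abs(z$nodal_forces)), 0)
  # single contact: force = k * depth along the normal, opposite reaction
  delta <- 1e-4
  cts <- detect_contacts(matrix(c(0.3, 0.2, 0.01 - delta), 1, 3), surf, cfg)
  pf <- penalty_forces(cts, cfg, surf, 1)
  expect_equal(pf$particle_forces[1, ], c(0, 0, k * delta),
               tolerance = 1e-12)
  expect_equal(colSums(pf$nodal_forces), -pf$particle_forces[1, ],
               tolerance = 1e-15)
  # random contact cloud: global force balance exact
  set.seed(5)
  pts <- cbind(runif(40, 0.05, 0.95), runif(40, 0.05, 0.95),
               runif(40, -0.009, 0.009))
  cts2 <- detect_contacts(pts, surf, cfg)
  pf2 <- penalty_forces(cts2, cfg, surf, 40)
  tot <- colSums(pf2$particle_forces) + colSums(pf2$nodal_forces)
  expect_lt(max(abs(tot)), 1e-13 * max(abs(pf2$particle_forces)))
})

test_that("substep contact evaluation matches the one-shot path on a static mesh", {
  surf <- unit_square_surface()
  cfg <- contact_config(stiffness = 77, thickness = 0.01)
  set.seed(9)
  pts <- cbind(runif(25, 0.1, 0.9), runif(25, 0.1, 0.9),
               runif(25, -0.008, 0.008))
  cts <- detect_contacts(pts, surf, cfg)
  ref <- penalty_forces(cts, cfg, surf, 25)
  cand <- detect_contacts(pts, surf,
                          contact_config(stiffness = 77,
                                         thickness = 0.025))
  got <- sphvalve:::eval_contact_pairs(cand$particle, cand$element, pts,
                                       surf, matrix(0, 4, 3), cfg)
  expect_equal(got$particle_forces, ref$particle_forces, tolerance = 1e-12)
  expect_equal(got$nodal_forces, ref$nodal_forces, tolerance = 1e-12)
})

test_that("contact stiffness auto-scaling follows m/(beta dt^2)", {
  expect_equal(contact_auto_stiffness(8e-6, 1e-5), 8e-6 / (4 * 1e-10))
  expect_equal(contact_auto_stiffness(8e-6, 1e-5, beta = 8),
               8e-6 / (8 * 1e-10))
  expect_error(contact_config(stiffness = -1, thickness = 0.01),
               "stiffness")
  expect_error(contact_config(thickness = 0), "thickness")
})

test_that("tangential velocity adjacent to a moving plate tracks the plate", {
  # shear cell: fixed bottom wall, tangentially moving top plate of
  # boundary particles; after the viscous transient the fluid adjacent
  # to the plate moves with it (approximate no-slip)
  dx <- 0.001
  H <- 0.008
  uplate <- 0.05
  fl <- sphvalve:::lattice2d(0, 0.02, 0, H, dx)
  bot <- sphvalve:::lattice2d(0, 0.02, -3 * dx, 0, dx)
  top <- sphvalve:::lattice2d(0, 0.02, H, H + 3 * dx, dx)
  pos <- rbind(fl, bot, top)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(1L, nrow(bot) + nrow(top)))
  vel <- matrix(0, n, 2)
  vel[seq(nrow(fl) + nrow(bot) + 1, n), 1] <- uplate
  sc <- fsi_scene(dim = 2, dx = dx, pos = pos, vel = vel,
                  rho = rep(1000, n), mass = rep(1000 * dx^2, n),
                  type = type, eos = eos_linear(1000, 1), mu = 0.05,
                  period = c(0.02, 0), delta = 0.1, vmax_est = uplate,
                  meta = list())
  res <- run_scene(sc, duration = 0.6, trace_every = 1e6)
  flm <- res$final$type == 0L
  near <- res$final$pos[flm, 2] > H - 1.5 * dx
  u_near <- mean(res$final$vel[flm, 1][near])
  expect_lt(abs(u_near - uplate) / uplate, 0.2)
})
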
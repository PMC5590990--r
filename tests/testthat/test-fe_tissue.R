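table1_mhgo <- c("av_leaflet", "anterior_mv_leaflet", "posterior_mv_leaflet")
table1_ogden <- c("basal_chordae", "strut_chordae", "marginal_chordae")

test_that("MHGO stress matches central-difference differentiation of the strain energy", {
  set.seed(42)
  for (tissue in table1_mhgo) {
    p <- tissue_params(tissue)
    errs <- replicate(100, {
      F <- random_tension_F(p)
      s_ana <- mhgo_cauchy_stress(F, p)
      s_num <- oracle_mhgo_stress(F, p)
      norm(s_ana - s_num, "F") / norm(s_num, "F")
    })
    expect_lt(max(errs), 1e-5)
  }
})

test_that("MHGO stress vanishes at the identity for every leaflet parameter set", {
  for (tissue in table1_mhgo) {
    p <- tissue_params(tissue)
    expect_lt(max(abs(mhgo_cauchy_stress(diag(3), p))), 1e-10)
    expect_equal(mhgo_strain_energy(diag(3), p), 0)
  }
})

test_that("MHGO stress is frame-indifferent: sigma(QF) = Q sigma(F) Q^T", {
  set.seed(11)
  p <- tissue_params("av_leaflet")
  for (i in 1:25) {
    F <- random_tension_F(p)
    Q <- random_rotation()
    s1 <- mhgo_cauchy_stress(Q %*% F, p)
    s2 <- Q %*% mhgo_cauchy_stress(F, p) %*% t(Q)
    expect_lt(norm(s1 - s2, "F") / norm(s2, "F"), 1e-9)
  }
})

test_that("equibiaxial stretch of the symmetric fiber families gives zero in-plane shear", {
  p <- tissue_params("av_leaflet")
  lam <- 1.03
  s33 <- function(l3) mhgo_cauchy_stress(diag(c(lam, lam, l3)), p)[3, 3]
  l3 <- stats::uniroot(s33, c(0.5, 1.2), tol = 1e-14)$root
  sig <- mhgo_cauchy_stress(diag(c(lam, lam, l3)), p)
  expect_lt(abs(sig[1, 2]), 1e-10 * abs(sig[1, 1]))
  # and the numeric oracle agrees with that state too
  s_num <- oracle_mhgo_stress(diag(c(lam, lam, l3)), p)
  expect_lt(norm(sig - s_num, "F") / norm(s_num, "F"), 1e-5)
})

test_that("element inversion is fatal", {
  p <- tissue_params("av_leaflet")
  expect_error(mhgo_cauchy_stress(diag(c(-1, 1, 1)), p), "inversion")
  expect_error(mhgo_strain_energy(diag(c(1, -1, 1)), p), "inversion")
})

test_that("Ogden truss tension matches numeric differentiation of the energy", {
  for (tissue in table1_ogden) {
    p <- tissue_params(tissue)
    area <- 4e-7
    for (lam in c(1.005, 1.02, 1.05)) {
      hh <- 1e-7
      fnum <- 1000 * area *
        (oracle_ogden_energy(lam + hh, p) -
           oracle_ogden_energy(lam - hh, p)) / (2 * hh)
      expect_equal(ogden_fiber_tension(lam, p, area), fnum,
                   tolerance = 1e-5)
    }
    expect_equal(ogden_fiber_tension(1, p, area), 0)
    # monotone tension on (1, 1.1); slack below 1 by default
    lams <- seq(1.001, 1.1, length.out = 40)
    expect_true(all(diff(ogden_fiber_tension(lams, p, area)) > 0))
    expect_equal(ogden_fiber_tension(0.95, p, area), 0)
    expect_gt(abs(ogden_fiber_tension(0.95, p, area, slack = FALSE)), 0)
    expect_error(ogden_fiber_tension(-0.1, p, area), "corrupted")
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(mhgo_params(1, 1, 1, 1, 0, 0.5), "kappa")
  expect_error(mhgo_params(-1, 1, 1, 1, 0, 0.1), "c1")
  expect_error(mhgo_params(1, 1, 1, -1, 0, 0.1), "k2")
  expect_error(mhgo_params(1, 1, 1, 1, 0, 0.1, D = 0), "D")
  expect_error(ogden_params(c(-5, -5, -5), c(2, 2, 2)), "stiffness")
  expect_silent(ogden_params(c(1, 1, 1), c(2, 2, 2)))
})

make_patch <- function(stretch = NULL, material = tissue_params("av_leaflet")) {
  nodes <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0),
                 c(0.01, 0.01, 0))
  mesh <- structural_mesh(nodes,
                          triangles = rbind(c(1, 2, 3), c(2, 4, 3)),
                          thickness = 4e-4,
                          fiber_dir = rbind(c(1, 0, 0), c(1, 0, 0)),
                          tri_material = "m",
                          materials = list(m = material))
  mesh
}

test_that("membrane forces vanish for the reference state and rigid motion", {
  mesh <- make_patch()
  expect_equal(max(abs(membrane_internal_forces(mesh, matrix(0, 4, 3)))), 0)
  set.seed(3)
  for (i in 1:5) {
    Q <- random_rotation()
    shift <- rnorm(3, 0, 0.01)
    u <- mesh$nodes %*% t(Q) +
      matrix(shift, 4, 3, byrow = TRUE) - mesh$nodes
    f <- membrane_internal_forces(mesh, u)
    expect_lt(max(abs(f)), 1e-9)
  }
})

test_that("membrane nodal forces equal the energy gradient under biaxial tension", {
  mesh <- make_patch()
  # biaxial tension keeps both principal stretches taut (away from the
  # wrinkling switch), where the response is smooth
  u <- mesh$nodes %*% diag(c(1.05, 1.02, 1)) - mesh$nodes
  f <- membrane_internal_forces(mesh, u)
  expect_lt(max(abs(colSums(f))), 1e-12) # self-equilibrated
  hh <- 1e-8
  fnum <- matrix(0, 4, 3)
  for (i in 1:4) for (d in 1:3) {
    up <- u; up[i, d] <- up[i, d] + hh
    um <- u; um[i, d] <- um[i, d] - hh
    fnum[i, d] <- -(membrane_strain_energy(mesh, up) -
                      membrane_strain_energy(mesh, um)) / (2 * hh)
  }
  expect_lt(max(abs(f - fnum)) / max(abs(f)), 1e-5)
})

test_that("uniaxially stretched membrane transmits the plane-stress resultant", {
  mesh <- make_patch()
  lam <- 1.05
  u <- mesh$nodes %*% diag(c(lam, 1, 1)) - mesh$nodes
  f <- membrane_internal_forces(mesh, u)
  p <- tissue_params("av_leaflet")
  s33 <- function(l3) mhgo_cauchy_stress(diag(c(lam, 1, l3)), p)[3, 3]
  l3 <- stats::uniroot(s33, c(0.5, 1.2), tol = 1e-14)$root
  sig11 <- mhgo_cauchy_stress(diag(c(lam, 1, l3)), p)[1, 1]
  # total tension across the cut = Cauchy stress x current thickness x
  # width; internal forces pull the x = 0 edge nodes toward the center
  expect_equal(sum(f[c(1, 3), 1]), 1000 * sig11 * 4e-4 * l3 * 0.01,
               tolerance = 0.01)
})

test_that("wrinkled membranes carry no compressive stress", {
  mesh <- make_patch()
  u <- mesh$nodes %*% diag(c(0.95, 1.02, 1)) - mesh$nodes
  f <- membrane_internal_forces(mesh, u)
  # forces on the compressed (x) faces vanish; tension remains in y
  expect_lt(max(abs(f[, 1])), 1e-6 * max(abs(f[, 2])))
  expect_gt(max(abs(f[, 2])), 0)
  # fully slack state: zero forces and energy
  u2 <- mesh$nodes %*% diag(c(0.97, 0.98, 1)) - mesh$nodes
  expect_lt(max(abs(membrane_internal_forces(mesh, u2))), 1e-9)
  expect_equal(membrane_strain_energy(mesh, u2), 0)
})

test_that("truss assembly pulls nodes together in tension and respects forks", {
  # fork-shaped insertion: two branches sharing node 3
  nodes <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0.005, 0.008, 0))
  mesh <- structural_mesh(nodes, trusses = rbind(c(1, 3), c(2, 3)),
                          truss_area = 4e-7,
                          materials = list(chordae =
                                             tissue_params("marginal_chordae")))
  u <- matrix(0, 3, 3); u[3, 2] <- 0.001 # stretch both branches
  f <- truss_internal_forces(mesh, u)
  expect_lt(f[3, 2], 0) # insertion node pulled back
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-15)
  tens <- truss_tensions(mesh, u)
  expect_length(tens, 2)
  expect_true(all(tens > 0))
  # compression leaves a slack chordae force-free
  u2 <- matrix(0, 3, 3); u2[3, 2] <- -0.001
  expect_equal(max(abs(truss_internal_forces(mesh, u2))), 0)
})

test_that("explicit structural step obeys prescribed nodes and stays put unloaded", {
  mesh <- make_patch()
  st <- structure_state(mesh)
  presc <- list(idx = 1:2, u = matrix(c(0, 0, 0, 0, 0, 1e-4), 2, 3))
  out <- step_structure(mesh, st, NULL, 1e-6, prescribed = presc)
  expect_equal(out$u[1:2, ], presc$u)
  # zero external force, undeformed start: unconstrained nodes unchanged
  out2 <- step_structure(mesh, structure_state(mesh), NULL, 1e-6)
  expect_equal(max(abs(out2$u)), 0)
})

test_that("pre-tensioned drum oscillator period matches the linearized stiffness", {
  drum <- drum_mesh()
  st <- structure_state(drum$mesh)
  st$u <- drum$pretension_u
  pin <- list(idx = 1:4, u = drum$pretension_u[1:4, ])
  # displace the center node out of plane and release
  z0 <- 1.5e-4
  st$u[5, 3] <- st$u[5, 3] + z0
  hh <- 1e-8
  fz <- function(z) membrane_internal_forces(
    drum$mesh, `[<-`(st$u, 5, 3, z))[5, 3]
  kz <- -(fz(st$u[5, 3] + hh) - fz(st$u[5, 3] - hh)) / (2 * hh)
  t_exp <- 2 * pi * sqrt(drum$mesh$mass[5] / kz)
  dt <- t_exp / 400
  zs <- numeric(1400)
  for (i in seq_along(zs)) {
    st <- step_structure(drum$mesh, st, NULL, dt, prescribed = pin)
    zs[i] <- st$u[5, 3]
  }
  zc <- zs - mean(zs)
  cross <- which(zc[-1] < 0 & zc[-length(zc)] >= 0)
  expect_gte(length(cross), 2)
  t_meas <- (cross[2] - cross[1]) * dt
  expect_equal(t_meas, t_exp, tolerance = 0.05)
})

test_that("free vibration conserves total energy within 1% over 10 periods", {
  drum <- drum_mesh()
  st <- structure_state(drum$mesh)
  st$u <- drum$pretension_u
  pin <- list(idx = 1:4, u = drum$pretension_u[1:4, ])
  e_base <- membrane_strain_energy(drum$mesh, st$u)
  z0 <- 1.5e-4
  st$u[5, 3] <- st$u[5, 3] + z0
  hh <- 1e-8
  fz <- function(z) membrane_internal_forces(
    drum$mesh, `[<-`(st$u, 5, 3, z))[5, 3]
  kz <- -(fz(st$u[5, 3] + hh) - fz(st$u[5, 3] - hh)) / (2 * hh)
  t_per <- 2 * pi * sqrt(drum$mesh$mass[5] / kz)
  dt <- t_per / 1200
  e0 <- membrane_strain_energy(drum$mesh, st$u) - e_base
  emax <- -Inf; emin <- Inf
  nsteps <- round(10 * t_per / dt)
  for (i in seq_len(nsteps)) {
    st <- step_structure(drum$mesh, st, NULL, dt, prescribed = pin)
    e <- membrane_strain_energy(drum$mesh, st$u) - e_base +
      structure_kinetic_energy(drum$mesh, st)
    emax <- max(emax, e); emin <- min(emin, e)
  }
  expect_lt((emax - emin) / e0, 0.01)
})

test_that("mesh constructor validates connectivity, thickness and fiber frames", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(structural_mesh(nodes, triangles = rbind(c(1, 2, 9))),
               "invalid nodes")
  expect_error(structural_mesh(nodes, triangles = rbind(c(1, 2, 3)),
                               thickness = 0), "thickness")
  m <- structural_mesh(nodes, triangles = rbind(c(1, 2, 3)),
                       fiber_dir = rbind(c(1, 1, 0)),
                       materials = list(default = tissue_params("av_leaflet")))
  # fiber frame unit length, orthogonal, in-plane
  expect_equal(sum(m$fiber_e1^2), 1, tolerance = 1e-12)
  expect_equal(sum(m$fiber_e2^2), 1, tolerance = 1e-12)
  expect_equal(sum(m$fiber_e1 * m$fiber_e2), 0, tolerance = 1e-12)
  expect_equal(abs(m$fiber_e1[3]), 0, tolerance = 1e-12)
})

test_that("mesh volume via the divergence theorem is exact for a tetrahedron", {
  a <- 0.013
  nodes <- rbind(c(0, 0, 0), c(a, 0, 0), c(0, a, 0), c(0, 0, a))
  faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  expect_equal(mesh_volume(nodes, faces), a^3 / 6, tolerance = 1e-12)
  # reversing the orientation flips the sign
  expect_equal(mesh_volume(nodes, faces[, c(1, 3, 2)]), -a^3 / 6,
               tolerance = 1e-12)
})
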
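test_that("cubic spline kernel has compact support, symmetry and unit mass", {
  h <- 0.7
  # outside support and at the origin
  expect_equal(cubic_spline_kernel(c(2.5 * h, 0, 0), h)$W, 0)
  expect_equal(cubic_spline_kernel(c(2.5 * h, 0, 0), h)$gradW,
               matrix(0, 1, 3))
  expect_equal(cubic_spline_kernel(c(0, 0, 0), h)$gradW, matrix(0, 1, 3))
  expect_gt(cubic_spline_kernel(c(0.5 * h, 0, 0), h)$W, 0)
  # gradient antisymmetry under r -> -r
  r <- c(0.3 * h, -0.7 * h, 0.2 * h)
  expect_equal(cubic_spline_kernel(r, h)$gradW,
               -cubic_spline_kernel(-r, h)$gradW, tolerance = 1e-14)
  # unit normalization by high-order radial quadrature, 3D and 2D
  w3 <- function(r) vapply(r, function(ri)
    cubic_spline_kernel(c(ri, 0, 0), h, 3)$W, 0)
  int3 <- stats::integrate(function(r) 4 * pi * r^2 * w3(r), 0, 2 * h,
                           rel.tol = 1e-10)$value
  expect_equal(int3, 1, tolerance = 1e-6)
  w2 <- function(r) vapply(r, function(ri)
    cubic_spline_kernel(c(ri, 0), h, 2)$W, 0)
  int2 <- stats::integrate(function(r) 2 * pi * r * w2(r), 0, 2 * h,
                           rel.tol = 1e-10)$value
  expect_equal(int2, 1, tolerance = 1e-6)
  # gradient is the analytic derivative of W (central difference check)
  num <- (cubic_spline_kernel(r + c(1e-7, 0, 0), h)$W -
            cubic_spline_kernel(r - c(1e-7, 0, 0), h)$W) / 2e-7
  expect_equal(cubic_spline_kernel(r, h)$gradW[1], num, tolerance = 1e-5)
  expect_error(kernel_spec(-1), "h must be > 0")
  expect_error(cubic_spline_kernel(r, 0), "h must be > 0")
})

test_that("kernel interpolation reproduces constants and identities", {
  # dense uniform lattice: interior interpolation of a constant field
  dx <- 0.001
  g <- as.matrix(expand.grid(x = seq(0, 0.02, dx), y = seq(0, 0.02, dx),
                             z = seq(0, 0.02, dx)))
  n <- nrow(g)
  st <- fluid_state(g, matrix(0, n, 3), rep(1000, n), rep(1000 * dx^3, n))
  kr <- kernel_spec(1.3 * dx)
  val <- kernel_interpolate(rep(7.5, n), st, c(0.01, 0.01, 0.01), kr)
  expect_equal(val, 7.5, tolerance = 0.02)
  # A_b = rho_b gives the summation density
  nb <- neighbor_search(st$positions, kr$support_radius)
  # interpolating rho at a particle's own position includes its self
  # term, exactly the summation density
  vr <- kernel_interpolate(st$densities, st, st$positions[5000, ], kr)
  sd <- summation_density(st, nb, kr)[5000]
  expect_equal(vr, sd, tolerance = 1e-9)
  # evaluation beyond 2h of a single particle returns 0
  st1 <- fluid_state(matrix(0, 1, 3), matrix(0, 1, 3), 1000, 1e-6)
  expect_equal(kernel_interpolate(5, st1, c(1, 0, 0), kr), 0)
})

test_that("neighbor search equals the brute-force all-pairs scan", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 100 + seed * 40
    pos <- matrix(runif(n * 3, 0, 0.05), n, 3)
    cutoff <- 0.007
    nb <- neighbor_search(pos, cutoff)
    d <- as.matrix(dist(pos))
    diag(d) <- Inf
    expect_equal(length(nb$i), sum(d < cutoff) / 2)
    key <- paste(pmin(nb$i, nb$j), pmax(nb$i, nb$j))
    ref <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
    refkey <- paste(pmin(ref[, 1], ref[, 2]), pmax(ref[, 1], ref[, 2]))
    expect_setequal(key, refkey)
  }
  # distant pair and single particle give empty sets
  expect_length(neighbor_search(rbind(c(0, 0, 0), c(0.0021, 0, 0)),
                                0.002)$i, 0)
  expect_length(neighbor_search(matrix(0, 1, 3), 1)$i, 0)
})

test_that("continuity rate vanishes for rigid motion and matches a hand-evaluated pair", {
  st <- random_fluid_state(60)
  st$velocities <- matrix(rep(c(0.3, -0.1, 0.2), each = 60), 60, 3)
  kr <- kernel_spec(0.004)
  nb <- neighbor_search(st$positions, kr$support_radius)
  expect_equal(max(abs(density_rate(st, nb, kr))), 0)
  # isolated particle
  st1 <- fluid_state(matrix(0, 1, 3), matrix(1, 1, 3), 1000, 1e-6)
  expect_equal(density_rate(st1, neighbor_search(st1$positions, 0.01), kr), 0)
  # two particles approaching head-on: drho/dt = m * 2u * dW/dx
  h <- 0.004; d <- 0.005; u <- 0.2; m <- 1e-6
  st2 <- fluid_state(rbind(c(0, 0, 0), c(d, 0, 0)),
                     rbind(c(u, 0, 0), c(-u, 0, 0)),
                     c(1000, 1000), c(m, m))
  nb2 <- neighbor_search(st2$positions, 2 * h)
  got <- density_rate(st2, nb2, kernel_spec(h))
  # drho_1/dt = m v_12 . gradW(r_1 - r_2): approaching particles compress
  dwdx <- cubic_spline_kernel(c(-d, 0, 0), h)$gradW[1]
  expect_equal(got[1], m * 2 * u * dwdx, tolerance = 1e-12)
  expect_gt(got[1], 0)
  expect_equal(got[1], got[2])
})

test_that("momentum rate conserves momentum, opposes relative motion, guards r = 0", {
  kr <- kernel_spec(0.004)
  # pairwise momentum balance on an arbitrary two-particle state
  st2 <- fluid_state(rbind(c(0, 0, 0), c(0.003, 0.001, -0.002)),
                     rbind(c(0.2, 0, 0.1), c(-0.1, 0.3, 0)),
                     c(1050, 1070), c(1e-6, 2e-6), c(120, 340))
  nb2 <- neighbor_search(st2$positions, kr$support_radius)
  acc <- momentum_rate(st2, nb2, kr)
  expect_lt(max(abs(colSums(acc * st2$masses))), 1e-18)
  # cloud momentum conservation
  st <- random_fluid_state(150)
  nb <- neighbor_search(st$positions, kr$support_radius)
  acc <- momentum_rate(st, nb, kr)
  ptot <- colSums(acc * st$masses)
  scale <- sum(abs(acc) * st$masses)
  expect_lt(max(abs(ptot)) / scale, 1e-12)
  # viscous term opposes relative motion at zero pressure
  stv <- fluid_state(rbind(c(0, 0, 0), c(0.003, 0, 0)),
                     rbind(c(0.5, 0, 0), c(-0.5, 0, 0)),
                     c(1056, 1056), c(1e-6, 1e-6), c(0, 0), mu = 0.01)
  accv <- momentum_rate(stv, neighbor_search(stv$positions, 0.008), kr)
  expect_lt(accv[1, 1], 0)
  expect_gt(accv[2, 1], 0)
  # coincident pair: zero contribution plus a warning
  stc <- fluid_state(rbind(c(0, 0, 0), c(0, 0, 0)), matrix(0, 2, 3),
                     c(1000, 1000), c(1e-6, 1e-6))
  nbc <- list(i = 1L, j = 2L, dx = matrix(0, 1, 3), r = 0)
  expect_warning(accc <- momentum_rate(stc, nbc, kr), "coincident")
  expect_equal(max(abs(accc)), 0)
  # single particle: zero acceleration
  st1 <- fluid_state(matrix(0, 1, 3), matrix(0, 1, 3), 1000, 1e-6)
  expect_equal(momentum_rate(st1, neighbor_search(st1$positions, 0.01),
                             kr), matrix(0, 1, 3))
})

test_that("equations of state vanish at the reference density and increase", {
  for (eos in list(eos_linear(1056, 10), eos_tait(1056, 10))) {
    expect_equal(eos_pressure(1056, eos), 0)
    expect_equal(eos_pressure(1056 * 1.01, eos_linear(1056, 10)),
                 0.01 * 1056 * 100)
    r <- seq(900, 1300, by = 10)
    expect_true(all(diff(eos_pressure(r, eos)) > 0))
  }
  # linearized stiffness c0^2 at rho0 for the Tait form
  e <- eos_tait(1056, 10)
  expect_equal((eos_pressure(1056 + 1e-4, e) - eos_pressure(1056 - 1e-4, e))
               / 2e-4, 100, tolerance = 1e-4)
  expect_error(eos_pressure(-1, eos_linear(1000, 10)), "non-positive")
  expect_error(eos_linear(1000, -5), "c0 must be > 0")
})

test_that("explicit fluid step advects, conserves mass and enforces CFL", {
  kr <- kernel_spec(0.004)
  eos <- eos_linear(1056, 10)
  st <- random_fluid_state(80)
  st$densities <- rep(1056, 80)
  st$pressures <- rep(0, 80)
  m0 <- sum(st$masses)
  # zero-force pure advection: far-apart particles just drift
  stf <- fluid_state(rbind(c(0, 0, 0), c(1, 0, 0)),
                     rbind(c(0.1, 0, 0), c(0, -0.2, 0)),
                     c(1056, 1056), c(1e-6, 1e-6))
  out <- step_fluid(stf, kr, eos, dt = 5e-5)
  expect_equal(out$positions,
               stf$positions + 5e-5 * stf$velocities, tolerance = 1e-12)
  # masses never change
  out2 <- step_fluid(st, kr, eos, dt = 5e-5)
  expect_identical(out2$masses, st$masses)
  expect_equal(sum(out2$masses), m0)
  # CFL violation is a configuration error
  expect_error(step_fluid(st, kr, eos, dt = 1), "CFL")
})

test_that("momentum drift of an isolated cloud stays below 1e-10 per step", {
  kr <- kernel_spec(0.0035)
  eos <- eos_linear(1056, 8)
  st <- random_fluid_state(120, seed = 7)
  st$pressures <- eos_pressure(st$densities, eos)
  p0 <- colSums(st$velocities * st$masses)
  pref <- sum(abs(st$velocities) * st$masses)
  for (i in 1:10) st <- step_fluid(st, kr, eos, dt = 2e-5)
  p1 <- colSums(st$velocities * st$masses)
  expect_lt(max(abs(p1 - p0)) / pref, 1e-10)
})

test_that("shepard-filtered summation density reproduces the bulk reference density", {
  dx <- 0.001
  g <- as.matrix(expand.grid(x = seq(0, 0.016, dx), y = seq(0, 0.016, dx),
                             z = seq(0, 0.016, dx)))
  n <- nrow(g)
  st <- fluid_state(g, matrix(0, n, 3), rep(1000, n), rep(1000 * dx^3, n))
  kr <- kernel_spec(1.3 * dx)
  nb <- neighbor_search(st$positions, kr$support_radius)
  rho <- summation_density(st, nb, kr)
  interior <- rowSums((g - 0.008)^2) < 0.004^2
  expect_equal(mean(rho[interior]), 1000, tolerance = 0.01)
})
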
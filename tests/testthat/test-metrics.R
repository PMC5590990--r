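test_that("stroke volume and ejection fraction follow their definitions", {
  out <- stroke_volume_ef(112, 47)
  expect_equal(out$sv, 65)
  expect_equal(round(out$ef), 58)
  expect_equal(stroke_volume_ef(100, 0), list(sv = 100, ef = 100))
  expect_lt(stroke_volume_ef(100, 100 - 1e-9)$ef, 1e-8)
  expect_error(stroke_volume_ef(50, 60), "invalid volumes")
  expect_equal(cycle_duration(75), 0.8)
})

test_that("effective orifice area formulas normalize and invert correctly", {
  expect_equal(eoa_av(51.6, 1), 1)
  expect_equal(eoa_av(2 * 51.6, 1), 2)
  expect_equal(eoa_mv(31, 1), 1)
  expect_equal(eoa_mv(62, 4), 1)
  # round trips through the mean-gradient anchors
  msf <- 1.6 * 51.6 * sqrt(11.1)
  expect_equal(eoa_av(msf, 11.1), 1.6, tolerance = 1e-12)
  mdf <- 3.8 * 31 * sqrt(2.0)
  expect_equal(eoa_mv(mdf, 2.0), 3.8, tolerance = 1e-12)
  expect_error(eoa_av(100, 0), "gradient")
  expect_error(eoa_mv(100, -1), "gradient")
})

test_that("regurgitant volume integrates only the backward flow", {
  t <- seq(0, 1, by = 0.001)
  expect_equal(regurgitant_volume(t, rep(5, length(t))), 0)
  # rectangle: -10 ml/s for 0.1 s = 1 ml
  q <- ifelse(t >= 0.4 & t <= 0.5, -10, 0)
  expect_equal(regurgitant_volume(t, q), 1, tolerance = 0.02)
  # sinusoid lobe: analytic area 2 A T / pi
  A <- 8; T <- 0.2
  q2 <- ifelse(t <= T, -A * sin(pi * t / T), 3)
  expect_equal(regurgitant_volume(t, q2), 2 * A * T / pi,
               tolerance = 0.005)
  # invariant to adding positive flow elsewhere
  expect_equal(regurgitant_volume(t, q2 + ifelse(t > 0.5, 100, 0)),
               regurgitant_volume(t, q2))
  expect_error(regurgitant_volume(numeric(0), numeric(0)), "empty")
})

test_that("regurgitant fraction reproduces the reported clinical ratios", {
  expect_equal(round(regurgitant_fraction(4.8, 65), 1), 7.4)
  expect_equal(round(regurgitant_fraction(9.8, 65)), 15)
  expect_equal(regurgitant_fraction(0, 65), 0)
  expect_error(regurgitant_fraction(1, 0), "SV")
})

test_that("plane-crossing flux counts signed particle volumes through the disk", {
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1), radius = 0.01)
  m <- rep(1056e-9, 3); rho <- rep(1056, 3)
  before <- rbind(c(0, 0, -1e-4), c(0.005, 0, 1e-4), c(0.02, 0, -1e-4))
  after <- rbind(c(0, 0, 1e-4), c(0.005, 0, -1e-4), c(0.02, 0, 1e-4))
  # one up, one down inside the disk, one crossing outside the radius
  q <- flow_rate_through_plane(before, after, m, rho, plane, 0.001)
  expect_equal(q, 0)
  q2 <- flow_rate_through_plane(before[1, , drop = FALSE],
                                after[1, , drop = FALSE], m[1], rho[1],
                                plane, 0.001)
  expect_equal(q2, 1e-9 * 1e6 / 0.001)
  # no crossings at all
  expect_equal(flow_rate_through_plane(after, after, m, rho, plane,
                                       0.001), 0)
})

test_that("uniform flow through a disk recovers Q = u A", {
  # kinematic oracle: a block of lattice particles advected at speed u
  dx <- 0.001
  g <- as.matrix(expand.grid(x = seq(-0.015, 0.015, dx),
                             y = seq(-0.015, 0.015, dx),
                             z = seq(-0.004, 0.004, dx)))
  u <- 0.3; dt <- 1e-3
  plane <- list(origin = c(0, 0, 1.6e-4), normal = c(0, 0, 1),
                radius = 0.01)
  m <- rep(1000 * dx^3, nrow(g)); rho <- rep(1000, nrow(g))
  qsum <- 0
  pos <- g
  for (i in 1:10) {
    newpos <- pos + matrix(c(0, 0, u * dt), nrow(g), 3, byrow = TRUE)
    qsum <- qsum + flow_rate_through_plane(pos, newpos, m, rho, plane, dt)
    pos <- newpos
  }
  qbar <- qsum / 10
  expect_equal(qbar, 1e6 * u * pi * 0.01^2, tolerance = 0.05)
})

test_that("transvalvular probe drop reproduces hydrostatics and antisymmetry", {
  # controlled lattice state carrying the exact hydrostatic field
  dx <- 0.001
  g <- as.matrix(expand.grid(x = seq(0, 0.04, dx), y = seq(0, 0.06, dx)))
  n <- nrow(g)
  st <- fluid_state(g, matrix(0, n, 2), rep(1056, n), rep(1056 * dx^2, n),
                    pressures = 1056 * 9.81 * (0.06 - g[, 2]))
  kr <- kernel_spec(1.3 * dx, 2)
  up <- c(0.02, 0.01); down <- c(0.02, 0.035)
  dp <- transvalvular_pressure_drop(st, up, down, kr)
  expected <- pa_to_mmhg(1056 * 9.81 * 0.025)
  expect_equal(dp, expected, tolerance = 0.01)
  expect_equal(transvalvular_pressure_drop(st, down, up, kr), -dp)
  dp0 <- transvalvular_pressure_drop(st, c(0.015, 0.02), c(0.025, 0.02), kr)
  expect_lt(abs(dp0), 0.01 * expected)
  # and on the settled SPH tank, via time-averaged probe traces
  fix <- hydro_fixture()
  nr <- nrow(fix$result$probe_p)
  pm <- colMeans(fix$result$probe_p[max(1, floor(0.75 * nr)):nr, ])
  dz <- fix$scene$probes[8, 2] - fix$scene$probes[1, 2]
  dp_sph <- pa_to_mmhg(pm[1] - pm[8])
  expect_equal(dp_sph, pa_to_mmhg(1056 * 9.81 * dz), tolerance = 0.05)
})
test_that("axial hydrodynamic force projects contact reactions with sign", {
  nf <- rbind(c(0, 0, 1.5), c(0.2, 0, 0.5), c(-0.2, 0, -0.4))
  expect_equal(hydrodynamic_axial_force(nf, c(0, 0, 1)), 1.6)
  expect_equal(hydrodynamic_axial_force(nf, c(0, 0, -1)), -1.6)
  expect_equal(hydrodynamic_axial_force(matrix(0, 3, 3), c(0, 0, 1)), 0)
})

test_that("E/A detection orders the diastolic peaks correctly", {
  t <- seq(0, 0.8, by = 0.001)
  gauss <- function(mu, amp, sd = 0.03) amp * exp(-(t - mu)^2 / (2 * sd^2))
  # E wave 0.8 m/s then A wave 0.4 m/s -> E/A = 2
  expect_equal(e_over_a(t, gauss(0.45, 0.8) + gauss(0.68, 0.4)), 2,
               tolerance = 0.01)
  # two equal peaks -> 1
  expect_equal(e_over_a(t, gauss(0.45, 0.6) + gauss(0.68, 0.6)), 1,
               tolerance = 0.01)
  # reversed order (A taller) -> ratio below 1
  expect_equal(e_over_a(t, gauss(0.45, 0.4) + gauss(0.68, 0.8)), 0.5,
               tolerance = 0.01)
  expect_error(e_over_a(t, gauss(0.45, 0.8)), "A wave not found")
})

test_that("slope tracts recover constructed opening and closing ramps", {
  t <- seq(0, 0.5, by = 0.001)
  trap <- function(t) {
    v <- numeric(length(t))
    v[t >= 0.1 & t < 0.13] <- (t[t >= 0.1 & t < 0.13] - 0.1) / 0.03
    v[t >= 0.13 & t < 0.32] <- 1
    v[t >= 0.32 & t < 0.37] <- 1 - (t[t >= 0.32 & t < 0.37] - 0.32) / 0.05
    v
  }
  out <- detect_rvot_rvct_et(t, trap(t))
  expect_equal(out$rvot, 30, tolerance = 3)
  expect_equal(out$rvct, 50, tolerance = 3)
  expect_equal(out$et, 270, tolerance = 5)
  # time reversal swaps opening and closing tracts
  rev <- detect_rvot_rvct_et(t, rev(trap(t)))
  expect_equal(rev$rvot, 50, tolerance = 3)
  expect_equal(rev$rvct, 30, tolerance = 3)
  expect_error(detect_rvot_rvct_et(t, rep(1, length(t))), "flat")
})

test_that("opening angle measures the hinge-to-tip chord against the annulus plane", {
  hinge <- c(0.01, 0, 0)
  expect_equal(opening_angle(hinge, hinge + c(-0.005, 0, 0), c(0, 0, 1)), 0)
  expect_equal(opening_angle(hinge, hinge + c(0, 0, 0.007), c(0, 0, 1)), 90)
  for (th in c(10, 30, 62.5)) {
    tip <- hinge + 0.008 * c(-cos(th * pi / 180), 0, sin(th * pi / 180))
    expect_equal(opening_angle(hinge, tip, c(0, 0, 1)), th,
                 tolerance = 1e-9)
  }
})

test_that("valve orifice area is near zero closed and positive for an open loop", {
  # closed Y-configuration collapses to (almost) zero area
  sc <- make_tube_valve()
  nodes0 <- sc$structures[[1]]$mesh$nodes[sc$meta$free_edge, ]
  expect_lt(1e4 * valve_orifice_area(nodes0), 1e-10)
  # a regular polygon loop recovers its area
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- cbind(0.01 * cos(ang), 0.01 * sin(ang), 0.05)
  expect_equal(valve_orifice_area(circ), pi * 0.01^2, tolerance = 0.02)
})

test_that("rms window helper matches a closed form", {
  t <- seq(0, 1, by = 1e-4)
  q <- sin(2 * pi * t)
  expect_equal(rms_over_window(t, q, 0, 1), sqrt(0.5), tolerance = 1e-3)
  expect_error(rms_over_window(t, q, 2, 3), "empty")
})
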
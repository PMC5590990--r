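test_that("keyframe tracks reproduce keyframes exactly and wrap periodically", {
  times <- seq(0, 0.72, by = 0.08)
  set.seed(2)
  disp <- array(rnorm(5 * 3 * 10, 0, 0.002), c(5, 3, 10))
  tr <- motion_track(times, disp, periodic = TRUE, period = 0.8)
  for (k in c(1, 4, 10))
    expect_equal(interpolate_track(tr, times[k]), disp[, , k],
                 tolerance = 1e-12)
  # periodic continuity of value and first derivative across the cycle
  expect_equal(interpolate_track(tr, 0), interpolate_track(tr, 0.8),
               tolerance = 1e-9)
  expect_equal(interpolate_track(tr, 0, deriv = 1),
               interpolate_track(tr, 0.8 - 1e-9, deriv = 1),
               tolerance = 1e-5)
  # constant keyframes give constant output
  disp2 <- array(rep(disp[, , 1], 10), c(5, 3, 10))
  tr2 <- motion_track(times, disp2, periodic = TRUE, period = 0.8)
  expect_equal(interpolate_track(tr2, 0.1234), disp2[, , 1],
               tolerance = 1e-12)
  # non-periodic tracks reject out-of-range times
  tr3 <- motion_track(times, disp, periodic = FALSE)
  expect_error(interpolate_track(tr3, 0.79), "out of range")
  expect_error(motion_track(c(0, 0.1, 0.1), disp[, , 1:3]),
               "strictly increasing")
})

test_that("chordal origins pass through both papillary anchors with a cosine ramp", {
  pd <- c(0, 0, 0); ps <- c(0.01, 0.004, -0.002)
  ts <- 0.16; td <- 0.56; per <- 0.8
  expect_equal(chordal_origin_position(td, pd, ps, ts, td, per), pd)
  expect_equal(chordal_origin_position(ts, pd, ps, ts, td, per), ps)
  # midpoint of the diastole->systole transition under the cosine ramp
  tmid <- td + ((ts - td) %% per) / 2
  expect_equal(chordal_origin_position(tmid, pd, ps, ts, td, per),
               (pd + ps) / 2, tolerance = 1e-12)
  # linear law hits the same midpoint; trajectory is periodic
  expect_equal(chordal_origin_position(tmid, pd, ps, ts, td, per,
                                       law = "linear"), (pd + ps) / 2)
  expect_equal(chordal_origin_position(0.1, pd, ps, ts, td, per),
               chordal_origin_position(0.1 + per, pd, ps, ts, td, per))
})

test_that("pressure boundaries convert mmHg, interpolate tables and check ranges", {
  pb <- pressure_boundary(c(0, 0, 0), c(0, 0, 1), 0.01, 20)
  expect_equal(boundary_pressure(pb, 0.37), 20 * 133.322)
  expect_equal(piston_pressure_force(pb, 0),
               20 * 133.322 * pi * 0.01^2 * c(0, 0, 1), tolerance = 1e-9)
  wf <- data.frame(time = c(0, 0.1, 0.2), mmhg = c(10, 30, 10))
  pbw <- pressure_boundary(c(0, 0, 0), c(0, 0, 1), 0.01, wf)
  expect_equal(boundary_pressure(pbw, 0.05), mmhg_to_pa(20))
  expect_error(boundary_pressure(pbw, 0.5), "outside table range")
  pbp <- pressure_boundary(c(0, 0, 0), c(0, 0, 1), 0.01, wf,
                           periodic = TRUE)
  expect_equal(boundary_pressure(pbp, 0.25), boundary_pressure(pbp, 0.05))
  expect_error(pressure_boundary(c(0, 0, 0), c(0, 0, 1), 0.01,
                                 data.frame(time = c(0, 0), mmhg = c(1, 2))),
               "strictly increasing")
  # zero target pressure exerts no force
  expect_equal(piston_pressure_force(
    pressure_boundary(c(0, 0, 0), c(0, 0, 1), 0.01, 0), 0), c(0, 0, 0))
})

test_that("unit conversions are exact round trips", {
  expect_equal(mmhg_to_pa(20), 2666.44)
  expect_equal(pa_to_mmhg(mmhg_to_pa(73.2)), 73.2)
  expect_equal(m3_to_ml(ml_to_m3(112)), 112)
})

test_that("the LV wall track reproduces the cavity-volume waveform at keyframes", {
  sc <- make_idealized_lv()
  m <- sc$meta
  cm1 <- lv_cavity_mesh(m$a, m$c, m$zb, s = 1)
  for (k in seq_along(m$s_k)) {
    vk <- m3_to_ml(mesh_volume(
      lv_cavity_mesh(m$a, m$c, m$zb, s = m$s_k[k])$nodes, cm1$tris))
    expect_equal(vk, m$waveform$ml[k], tolerance = 0.02)
  }
  # stroke volume encoded by the track equals EDV - ESV = 65 ml
  expect_equal(max(m$waveform$ml) - min(m$waveform$ml), 65)
  # constant waveform gives zero wall velocity
  scc <- make_idealized_lv(waveform = data.frame(
    time = seq(0, 0.72, by = 0.08), ml = rep(112, 10)))
  v <- interpolate_track(scc$meta$track, 0.3, deriv = 1)
  expect_lt(max(abs(v)), 1e-12)
})

test_that("piston characteristic control balances a static pressurized column", {
  # sealed tube with one piston at the top; no gravity: the interior
  # pressure converges to the piston target
  dx <- 0.002; r <- 0.007; L <- 0.024
  target <- 15 # mmHg
  fl <- NULL
  for (z in seq(dx / 2, L - dx, by = dx))
    fl <- rbind(fl, sphvalve:::disk_points(r - 0.4 * dx, dx, z = z))
  wall <- rbind(sphvalve:::tube_shell_points(r, 0, L + 4 * dx, dx),
                sphvalve:::disk_points(r + 2.5 * dx, dx, z = -dx / 2),
                sphvalve:::disk_points(r + 2.5 * dx, dx, z = -3 * dx / 2))
  plate <- rbind(sphvalve:::disk_points(r + 0.4 * dx, dx, z = L + dx / 2),
                 sphvalve:::disk_points(r + 0.4 * dx, dx, z = L + 3 * dx / 2))
  pos <- rbind(fl, wall, plate)
  n <- nrow(pos)
  type <- c(rep(0L, nrow(fl)), rep(1L, nrow(wall)), rep(100L, nrow(plate)))
  bc <- pressure_boundary(c(0, 0, L + dx / 2), c(0, 0, -1), r, target)
  sc <- fsi_scene(dim = 3, dx = dx, pos = pos, vel = matrix(0, n, 3),
                  rho = rep(1056 * (1 + mmhg_to_pa(target) / 105600), n),
                  mass = rep(1056 * dx^3, n),
                  type = type, eos = eos_linear(1056, 10), mu = 0.0035,
                  pistons = list(list(boundary = bc,
                                      rows = which(type == 100L),
                                      update_every = 2L, relax = 0.15,
                                      vmax = 0.5)),
                  alpha = 0.1, delta = 0.1,
                  settle_time = 0.25, settle_damping = 40,
                  vmax_est = 0.5, meta = list())
  res <- run_scene(sc, duration = 0.02, trace_every = 100)
  flm <- res$final$type == 0L
  P <- eos_pressure(res$final$rho[flm], sc$eos)
  interior <- res$final$pos[flm, 3] > 4 * dx &
    res$final$pos[flm, 3] < L - 4 * dx
  expect_equal(mean(P[interior]), mmhg_to_pa(target), tolerance = 0.05)
})
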
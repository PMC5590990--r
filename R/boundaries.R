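#' Unit conversions at the configuration boundary
#'
#' The solver works in SI units internally; configuration files and
#' reports use the clinical units mmHg and ml. 1 mmHg = 133.322 Pa.
#'
#' @param x Numeric value(s).
#' @return Converted value(s).
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' @rdname mmhg_to_pa
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname mmhg_to_pa
#' @export
m3_to_ml <- function(x) x * 1e6

# --- keyframe motion tracks -------------------------------------------------

# Cubic spline in second-derivative form for a matrix of dofs sharing one
# knot vector.  Periodic tracks use the cyclic tridiagonal system (C2
# across the cycle boundary); non-periodic tracks use natural end
# conditions.
spline_coefficients <- function(times, Y, periodic, period = NULL) {
  K <- length(times)
  if (K < 2) stop("keyframe count must be >= 2")
  if (any(diff(times) <= 0)) stop("keyframe times must be strictly increasing")
  Y <- as.matrix(Y)
  if (periodic) {
    if (is.null(period) || period <= times[K])
      stop("periodic track needs a period beyond the last keyframe")
    tt <- c(times, times[1] + period)
    YY <- rbind(Y, Y[1, , drop = FALSE])
    n <- K # unknown second derivatives M_1..M_K, M_{K+1} = M_1
    h <- diff(tt)
    A <- matrix(0, n, n)
    B <- matrix(0, n, ncol(Y))
    for (i in seq_len(n)) {
      hm <- if (i == 1) h[K] else h[i - 1]
      hp <- h[i]
      im <- if (i == 1) K else i - 1
      ip <- if (i == n) 1 else i + 1
      A[i, im] <- A[i, im] + hm / 6
      A[i, i] <- A[i, i] + (hm + hp) / 3
      A[i, ip] <- A[i, ip] + hp / 6
      ym <- if (i == 1) Y[K, ] else Y[i - 1, ]
      yp <- if (i == n) Y[1, ] else Y[i + 1, ]
      B[i, ] <- (yp - Y[i, ]) / hp - (Y[i, ] - ym) / hm
    }
    M <- solve(A, B)
    M <- rbind(M, M[1, , drop = FALSE])
    list(t = tt, Y = YY, M = M)
  } else {
    h <- diff(times)
    M <- matrix(0, K, ncol(Y))
    if (K > 2) {
      n <- K - 2
      A <- matrix(0, n, n)
      B <- matrix(0, n, ncol(Y))
      for (i in seq_len(n)) {
        A[i, i] <- (h[i] + h[i + 1]) / 3
        if (i > 1) A[i, i - 1] <- h[i] / 6
        if (i < n) A[i, i + 1] <- h[i + 1] / 6
        B[i, ] <- (Y[i + 2, ] - Y[i + 1, ]) / h[i + 1] -
          (Y[i + 1, ] - Y[i, ]) / h[i]
      }
      M[2:(K - 1), ] <- solve(A, B)
    }
    list(t = times, Y = Y, M = M)
  }
}

spline_eval <- function(sp, t, deriv = 0) {
  tt <- sp$t
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(tt) - 1L)
  h <- tt[i + 1] - tt[i]
  a <- (tt[i + 1] - t) / h
  b <- (t - tt[i]) / h
  y0 <- sp$Y[i, ]; y1 <- sp$Y[i + 1, ]
  m0 <- sp$M[i, ]; m1 <- sp$M[i + 1, ]
  if (deriv == 0) {
    a * y0 + b * y1 +
      ((a^3 - a) * m0 + (b^3 - b) * m1) * h^2 / 6
  } else {
    (y1 - y0) / h + ((3 * b^2 - 1) * m1 - (3 * a^2 - 1) * m0) * h / 6
  }
}

#' Prescribed-motion keyframe track
#'
#' A cubic-spline track of per-node displacements through a set of
#' keyframes (for the cardiac wall, 10 phases over one 0.8 s cycle).
#' Periodic tracks use periodic spline end conditions and are C2 across
#' the cycle boundary; non-periodic tracks use natural end conditions and
#' reject times outside their range.
#'
#' @param times Strictly increasing keyframe times (s). For a periodic
#'   track the first keyframe is taken at phase 0 and the cycle wraps at
#'   `period`.
#' @param displacements Array `n_nodes x 3 x K` (or `K x ndof` matrix) of
#'   displacement keyframes (m).
#' @param periodic Logical.
#' @param period Cycle length (s), required for periodic tracks.
#' @return An object of class `motion_track`.
#' @export
motion_track <- function(times, displacements, periodic = TRUE,
                         period = NULL) {
  if (length(dim(displacements)) == 3) {
    d <- dim(displacements)
    Y <- t(matrix(displacements, d[1] * d[2], d[3]))
    shape <- d[1:2]
  } else {
    Y <- as.matrix(displacements)
    shape <- NULL
  }
  if (nrow(Y) != length(times))
    stop("one displacement keyframe per time required")
  sp <- spline_coefficients(times, Y, periodic, period)
  structure(list(spline = sp, periodic = periodic, period = period,
                 range = range(times), shape = shape),
            class = "motion_track")
}

#' Evaluate a motion track
#'
#' Cubic-spline displacement (or velocity with `deriv = 1`) of every node
#' at time `t`. Keyframes are reproduced exactly. Periodic tracks accept
#' any `t` (wrapped); non-periodic tracks reject out-of-range times.
#'
#' @param track A [motion_track()].
#' @param t Time (s), scalar.
#' @param deriv 0 for displacement, 1 for velocity.
#' @return `n_nodes x 3` matrix (if the track was built from an array),
#'   else a vector of dof values.
#' @export
interpolate_track <- function(track, t, deriv = 0) {
  if (track$periodic) {
    t <- track$spline$t[1] + (t - track$spline$t[1]) %% track$period
  } else if (t < track$range[1] - 1e-12 || t > track$range[2] + 1e-12) {
    stop("t out of range for non-periodic track")
  }
  v <- spline_eval(track$spline, t, deriv)
  if (!is.null(track$shape)) matrix(v, track$shape[1], track$shape[2]) else v
}

#' Chordal-origin trajectory between papillary-muscle anchor positions
#'
#' Chordal origins are displaced between two spatial anchors representing
#' the papillary-muscle tips at mid-diastole and mid-systole. The default
#' interpolation is a smooth cosine ramp between the anchors synchronized
#' to the systole/diastole transitions (`law = "cosine"`); a linear ramp
#' is selectable.
#'
#' @param t Time (s).
#' @param pos_middiastole,pos_midsystole Anchor positions (length-3, m).
#' @param t_midsystole,t_middiastole Anchor phases (s) within the cycle.
#' @param period Cycle length (s).
#' @param law `"cosine"` (default) or `"linear"`.
#' @return Position (length-3, m).
#' @export
chordal_origin_position <- function(t, pos_middiastole, pos_midsystole,
                                    t_midsystole, t_middiastole, period,
                                    law = c("cosine", "linear")) {
  law <- match.arg(law)
  tw <- t %% period
  ts <- t_midsystole %% period
  td <- t_middiastole %% period
  # fraction of the way from mid-diastole anchor to mid-systole anchor
  seg <- function(tq, t0, t1) {
    len <- (t1 - t0) %% period
    if (len == 0) return(0)
    ((tq - t0) %% period) / len
  }
  if (((tw - td) %% period) <= ((ts - td) %% period)) {
    tau <- seg(tw, td, ts) # diastole -> systole leg
    s <- if (law == "cosine") (1 - cos(pi * tau)) / 2 else tau
  } else {
    tau <- seg(tw, ts, td) # systole -> diastole leg
    sfrac <- if (law == "cosine") (1 - cos(pi * tau)) / 2 else tau
    s <- 1 - sfrac
  }
  (1 - s) * pos_middiastole + s * pos_midsystole
}

# --- pressure boundaries ----------------------------------------------------

#' Piston pressure boundary
#'
#' A rigid plate closing a tube cross-section that imposes a pressure
#' waveform on the adjacent fluid column. The plate is velocity-
#' controlled (massless): each step its normal velocity is set from the
#' acoustic characteristic relation
#' `v_p . n = v_f . n - (P_f - P_target) / (rho0 c0)`,
#' with `v_f`, `P_f` kernel-interpolated just inside the fluid and `n`
#' the inward (into-fluid) unit normal, which imposes the target pressure
#' while letting outgoing waves leave.
#'
#' @param origin Plate center (length-3, m).
#' @param normal Inward unit normal (from plate into the fluid column).
#' @param radius Plate extent (m).
#' @param waveform Constant pressure (mmHg scalar) or a data frame with
#'   columns `time` (s) and `mmhg`.
#' @param periodic Wrap waveform lookups at the table's last time.
#' @return An object of class `pressure_boundary`.
#' @export
pressure_boundary <- function(origin, normal, radius, waveform,
                              periodic = FALSE) {
  normal <- normal / sqrt(sum(normal^2))
  if (is.data.frame(waveform)) {
    if (!all(c("time", "mmhg") %in% names(waveform)))
      stop("waveform table needs columns time, mmhg")
    if (any(diff(waveform$time) <= 0))
      stop("waveform times must be strictly increasing")
  }
  structure(list(origin = origin, normal = normal, radius = radius,
                 waveform = waveform, periodic = periodic),
            class = "pressure_boundary")
}

#' Boundary pressure at a given time
#'
#' @param boundary A [pressure_boundary()].
#' @param t Time (s).
#' @return Pressure (Pa).
#' @export
boundary_pressure <- function(boundary, t) {
  wf <- boundary$waveform
  if (!is.data.frame(wf)) return(mmhg_to_pa(wf))
  if (boundary$periodic) {
    t <- wf$time[1] + (t - wf$time[1]) %% (wf$time[nrow(wf)] - wf$time[1])
  } else if (t < wf$time[1] - 1e-12 || t > wf$time[nrow(wf)] + 1e-12) {
    stop("waveform lookup outside table range")
  }
  mmhg_to_pa(stats::approx(wf$time, wf$mmhg, xout = t, rule = 2)$y)
}

#' Pressure force carried by a piston plate
#'
#' @param boundary A [pressure_boundary()].
#' @param t Time (s).
#' @return Force vector (N) = P(t) x plate area along the inward normal.
#' @export
piston_pressure_force <- function(boundary, t) {
  boundary_pressure(boundary, t) * pi * boundary$radius^2 * boundary$normal
}

#' Piston velocity update (characteristic pressure control)
#'
#' Computes the new plate normal velocity for a piston given the current
#' fluid state (see [pressure_boundary()] for the relation). Sample
#' points are taken one kernel support inside the fluid across the plate
#' face.
#'
#' @param boundary A [pressure_boundary()].
#' @param t Time (s).
#' @param state A [fluid_state()] (fluid particles only).
#' @param kernel A [kernel_spec()].
#' @param eos The fluid [eos_linear()]/[eos_tait()].
#' @return Velocity vector (length 3, m/s) for the plate.
#' @export
apply_piston <- function(boundary, t, state, kernel, eos) {
  n <- boundary$normal
  # ring + center sample points just inside the fluid
  rr <- boundary$radius * 0.5
  b1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- b1 - sum(b1 * n) * n; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n[2] * b1[3] - n[3] * b1[2], n[3] * b1[1] - n[1] * b1[3],
          n[1] * b1[2] - n[2] * b1[1])
  ang <- seq(0, 2 * pi, length.out = 5)[-5]
  pts <- rbind(boundary$origin,
               t(sapply(ang, function(a)
                 boundary$origin + rr * (cos(a) * b1 + sin(a) * b2))))
  pts <- pts + matrix(2 * kernel$h * n, nrow(pts), 3, byrow = TRUE)
  fields <- cbind(state$pressures, state$velocities)
  vals <- cpp_interpolate(pts, state$positions, fields, state$densities,
                          state$masses, kernel$h, kernel$dim, TRUE)
  Pf <- mean(vals[, 1])
  vf <- colMeans(vals[, 2:4, drop = FALSE])
  Pt <- boundary_pressure(boundary, t)
  vn <- sum(vf * n) - (Pf - Pt) / (eos$rho0 * eos$c0)
  vn * n
}

# --- reference waveforms ----------------------------------------------------

#' Parametric physiological aortic pressure waveform
#'
#' A two-phase waveform: a systolic pulse rising from the diastolic level
#' to the systolic peak during ejection, followed by an exponential
#' diastolic decay back to the diastolic level. Any time-value table can
#' replace it in a scene configuration.
#'
#' @param period Cycle length (s), default 0.8 (75 bpm).
#' @param diastolic,systolic Pressure levels (mmHg), defaults 80 and 120.
#' @param t_sys_start,t_sys_end Ejection window (s).
#' @param dt Sample spacing (s).
#' @return Data frame with columns `time`, `mmhg`.
#' @export
aortic_pressure_waveform <- function(period = 0.8, diastolic = 80,
                                     systolic = 120, t_sys_start = 0.05,
                                     t_sys_end = 0.35, dt = 0.002) {
  t <- seq(0, period, by = dt)
  p <- numeric(length(t))
  dicrotic <- diastolic + 0.35 * (systolic - diastolic)
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti < t_sys_start) {
      p[i] <- diastolic * 1.0
    } else if (ti <= t_sys_end) {
      tau <- (ti - t_sys_start) / (t_sys_end - t_sys_start)
      p[i] <- diastolic + (systolic - diastolic) * sin(pi * tau^0.8)
    } else {
      tau <- (ti - t_sys_end) / (period - t_sys_end)
      p[i] <- diastolic + (dicrotic - diastolic) * exp(-3 * tau)
    }
  }
  data.frame(time = t, mmhg = p)
}

#' Default left-ventricular cavity volume waveform
#'
#' Ten keyframes over one 0.8 s cycle beginning at early systole:
#' end-diastolic volume 112 ml, end-systolic volume 47 ml (stroke volume
#' 65 ml, ejection fraction 58%), with an E-wave filling phase, diastasis
#' and an A-wave (atrial kick).
#'
#' @param edv,esv End-diastolic and end-systolic volumes (ml).
#' @param period Cycle length (s).
#' @return Data frame with columns `time` (s) and `ml`, one row per
#'   keyframe phase.
#' @export
lv_volume_waveform <- function(edv = 112, esv = 47, period = 0.8) {
  frac <- c(1.0, 0.738, 0.323, 0.046, 0.0, 0.231, 0.585, 0.692, 0.769, 0.923)
  data.frame(time = seq(0, by = period / 10, length.out = 10),
             ml = esv + frac * (edv - esv))
}
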
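#' Stroke volume and ejection fraction
#'
#' `SV = EDV - ESV` (ml) and `EF = 100 SV / EDV` (%).
#'
#' @param edv End-diastolic volume (ml).
#' @param esv End-systolic volume (ml), with `edv > esv >= 0`.
#' @return List with `sv` (ml) and `ef` (%).
#' @export
stroke_volume_ef <- function(edv, esv) {
  if (!(edv > esv && esv >= 0)) stop("invalid volumes: need EDV > ESV >= 0")
  sv <- edv - esv
  list(sv = sv, ef = 100 * sv / edv)
}

#' Cardiac cycle duration from heart rate
#'
#' @param bpm Heart rate (beats per minute).
#' @return Cycle duration (s); 75 bpm gives 0.8 s.
#' @export
cycle_duration <- function(bpm) 60 / bpm

#' Effective orifice area of the aortic valve
#'
#' `EOA_AV (cm^2) = MSF / (51.6 sqrt(dP))` with MSF the root-mean-square
#' systolic flow rate (ml/s) and dP the mean systolic pressure gradient
#' (mmHg).
#'
#' @param msf Root-mean-square systolic flow rate (ml/s).
#' @param dp Mean systolic transvalvular pressure gradient (mmHg), > 0.
#' @return EOA (cm^2).
#' @export
eoa_av <- function(msf, dp) {
  if (dp <= 0) stop("pressure gradient must be > 0")
  msf / (51.6 * sqrt(dp))
}

#' Effective orifice area of the mitral valve
#'
#' `EOA_MV (cm^2) = MDF / (31 sqrt(dP))` with MDF the root-mean-square
#' diastolic flow rate (ml/s) and dP the mean diastolic gradient (mmHg).
#'
#' @param mdf Root-mean-square diastolic flow rate (ml/s).
#' @param dp Mean diastolic transvalvular pressure gradient (mmHg), > 0.
#' @return EOA (cm^2).
#' @export
eoa_mv <- function(mdf, dp) {
  if (dp <= 0) stop("pressure gradient must be > 0")
  mdf / (31 * sqrt(dp))
}

#' Regurgitant volume from a flow-rate trace
#'
#' Integrates the negative part of the flow rate in time (trapezoidal
#' rule): `RV = -int min(Q, 0) dt`. The sum of closing and leakage
#' volumes over the window.
#'
#' @param time Sample times (s).
#' @param q Flow rate (ml/s), positive forward.
#' @return Regurgitant volume (ml), non-negative.
#' @export
regurgitant_volume <- function(time, q) {
  if (length(time) == 0) stop("empty trace")
  qn <- pmin(q, 0)
  -trapz_int(time, qn)
}

trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Regurgitant fraction
#'
#' `RF = 100 RV / SV` (%).
#'
#' @param rv Regurgitant volume (ml).
#' @param sv Stroke volume (ml), > 0.
#' @return RF (%).
#' @export
regurgitant_fraction <- function(rv, sv) {
  if (sv <= 0) stop("SV must be > 0")
  100 * rv / sv
}

#' Flow-rate contribution of particle crossings through a plane disk
#'
#' Signed particle-crossing flux over one step: each particle whose
#' trajectory segment crosses the disk contributes its volume `m/rho`
#' divided by `dt`, with the sign of the crossing direction relative to
#' the disk normal.
#'
#' @param pos_before,pos_after n x 3 positions at the start and end of the
#'   step (m).
#' @param masses,densities Per-particle mass (kg) and density (kg/m^3).
#' @param plane List with `origin`, `normal` (unit) and `radius` (m).
#' @param dt Step duration (s).
#' @return Flow rate (ml/s) for this step.
#' @export
flow_rate_through_plane <- function(pos_before, pos_after, masses,
                                    densities, plane, dt) {
  n <- plane$normal
  d0 <- (pos_before - matrix(plane$origin, nrow(pos_before), 3,
                             byrow = TRUE)) %*% n
  d1 <- (pos_after - matrix(plane$origin, nrow(pos_after), 3,
                            byrow = TRUE)) %*% n
  crossed <- (d0 <= 0 & d1 > 0) | (d0 > 0 & d1 <= 0)
  if (!any(crossed)) return(0)
  idx <- which(crossed)
  # crossing point within the disk?
  tt <- d0[idx] / (d0[idx] - d1[idx])
  pc <- pos_before[idx, , drop = FALSE] +
    tt * (pos_after[idx, , drop = FALSE] - pos_before[idx, , drop = FALSE])
  rel <- pc - matrix(plane$origin, length(idx), 3, byrow = TRUE)
  rel <- rel - (rel %*% n) %*% t(n)
  inside <- rowSums(rel^2) <= plane$radius^2
  idx <- idx[inside]
  if (length(idx) == 0) return(0)
  sgn <- ifelse(d1[idx] > 0, 1, -1)
  m3_to_ml(sum(sgn * masses[idx] / densities[idx])) / dt
}

#' Transvalvular pressure drop between two probes
#'
#' SPH-interpolates the pressure field at an upstream and a downstream
#' probe (placed one diameter upstream and three diameters downstream of
#' the valve annulus in the cardiac scenes) and returns the drop
#' upstream minus downstream in mmHg.
#'
#' @param state A [fluid_state()].
#' @param probe_up,probe_down Probe positions (length-3, m).
#' @param kernel A [kernel_spec()].
#' @param shepard Shepard-normalize the interpolation (default `TRUE` for
#'   robustness near boundaries).
#' @return Pressure drop (mmHg).
#' @export
transvalvular_pressure_drop <- function(state, probe_up, probe_down,
                                        kernel, shepard = TRUE) {
  p <- kernel_interpolate(state$pressures, state,
                          rbind(probe_up, probe_down), kernel,
                          shepard = shepard)
  pa_to_mmhg(p[1] - p[2])
}

#' Axial hydrodynamic force on a leaflet surface
#'
#' Vector addition of the contact reactions on the named surface,
#' projected on the valve axis. Positive values are opening forces.
#'
#' @param nodal_forces Nodal contact reaction forces on the surface
#'   (n x 3, N), e.g. from [penalty_forces()].
#' @param axis Unit vector of the valve axis, oriented so that opening
#'   forces are positive.
#' @return Axial force (N).
#' @export
hydrodynamic_axial_force <- function(nodal_forces, axis) {
  axis <- axis / sqrt(sum(axis^2))
  sum(nodal_forces %*% axis)
}

#' E/A ratio of a diastolic inflow velocity trace
#'
#' Finds the two largest diastolic velocity peaks in temporal order (the
#' early E wave first, the atrial A wave second) by prominence-based peak
#' detection with a minimum separation of 100 ms, and returns their
#' ratio E/A.
#'
#' @param time Sample times (s).
#' @param v Velocity trace (m/s).
#' @param min_separation Minimum peak separation (s), default 0.1.
#' @return E/A ratio.
#' @export
e_over_a <- function(time, v, min_separation = 0.1) {
  dtm <- stats::median(diff(time))
  mpd <- max(1, round(min_separation / dtm))
  pk <- pracma::findpeaks(v, minpeakdistance = mpd,
                          minpeakheight = 0.05 * max(v), npeaks = 0,
                          sortstr = FALSE)
  if (is.null(pk) || nrow(pk) < 2) stop("A wave not found")
  ord <- order(pk[, 2])
  pk <- pk[ord, , drop = FALSE]
  heights <- pk[, 1]
  top2 <- sort(order(heights, decreasing = TRUE)[1:2])
  heights[top2[1]] / heights[top2[2]]
}

#' Rapid valve opening/closing times and ejection time
#'
#' Detects on a leaflet-belly radial velocity trace: the rapid valve
#' opening time (RVOT) as the duration of the contiguous high-positive-
#' slope tract at opening, the rapid valve closing time (RVCT) as the
#' contiguous high-negative-slope tract at closure, and the ejection time
#' (ET) from first opening to complete closure. "High" slope means
#' exceeding `threshold` times the peak slope magnitude (default 0.2).
#'
#' @param time Sample times (s) covering one cycle.
#' @param v Belly radial velocity (m/s), positive during opening.
#' @param threshold Slope threshold as a fraction of the peak |slope|.
#' @return List with `rvot`, `rvct`, `et` in ms.
#' @export
detect_rvot_rvct_et <- function(time, v, threshold = 0.2) {
  n <- length(v)
  if (n < 3) stop("trace too short")
  slope <- c((v[2] - v[1]) / (time[2] - time[1]),
             (v[3:n] - v[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)]),
             (v[n] - v[n - 1]) / (time[n] - time[n - 1]))
  smax <- max(abs(slope))
  if (smax <= 1e-12 || max(v) - min(v) < 1e-12)
    stop("no valve events: trace is flat")
  thr <- threshold * smax
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    cbind(starts[keep], ends[keep])
  }
  pos <- runs(slope > thr)
  neg <- runs(slope < -thr)
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("no valve events: trace is flat")
  open_tract <- pos[1, ] # opening = first rapid-positive tract
  close_tract <- neg[nrow(neg), ] # closure = last rapid-negative tract
  rvot <- (time[open_tract[2]] - time[open_tract[1]]) * 1000
  rvct <- (time[close_tract[2]] - time[close_tract[1]]) * 1000
  et <- (time[close_tract[2]] - time[open_tract[1]]) * 1000
  list(rvot = rvot, rvct = rvct, et = et)
}

#' Leaflet opening angle
#'
#' Angle between the annulus plane and the chord from the annular hinge
#' to the leaflet tip marker.
#'
#' @param hinge,tip Points (length-3, m).
#' @param annulus_normal Unit normal of the annulus plane.
#' @return Angle (degrees) in `[0, 90]`.
#' @export
opening_angle <- function(hinge, tip, annulus_normal) {
  chord <- tip - hinge
  nn <- annulus_normal / sqrt(sum(annulus_normal^2))
  s <- abs(sum(chord * nn)) / sqrt(sum(chord^2))
  asin(pmin(1, s)) * 180 / pi
}

#' Root-mean-square of a trace over a window
#'
#' Helper for MSF/MDF: RMS of `q` over samples with `time` inside
#' `[t0, t1]`.
#'
#' @param time Sample times (s).
#' @param q Trace values.
#' @param t0,t1 Window bounds (s).
#' @return RMS value.
#' @export
rms_over_window <- function(time, q, t0, t1) {
  sel <- time >= t0 & time <= t1
  if (!any(sel)) stop("empty window")
  sqrt(mean(q[sel]^2))
}
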
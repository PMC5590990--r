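# Constant-strain membrane triangles with plane-stress MHGO response.
#
# Each triangle carries a 2x2 in-plane deformation gradient measured in
# its material (fiber) frame; the through-thickness stretch lambda3 is
# solved per element so the normal 2nd Piola-Kirchhoff stress vanishes
# (plane stress), with the volumetric penalty (1/D)(J-1)^2 keeping J
# near 1.

# Vectorized plane-stress MHGO evaluation for one material group.
# C2 components c11, c12, c22 and detF2 are vectors over elements.
# Returns S2 components (kPa), lambda3, and energy density (kPa).
#
# Tension-field (wrinkling) treatment: a membrane has no bending
# stiffness, so in-plane compression makes constant-strain triangles
# crumple. Principal squared stretches below 1 are treated as slack
# (reset to 1 before the constitutive evaluation) and the returned
# stress is projected onto the taut principal direction, the standard
# wrinkling model for thin biological membranes.
mhgo_plane_stress <- function(c11, c12, c22, detF2, params) {
  th <- params$theta * pi / 180
  a1c <- cos(th); a2s <- sin(th)
  kap <- params$kappa; onek <- 1 - 3 * kap
  # principal decomposition of C2
  trC <- (c11 + c22) / 2
  disc <- sqrt(pmax(((c11 - c22) / 2)^2 + c12^2, 0))
  mu1 <- trC + disc
  mu2 <- trC - disc
  phi <- 0.5 * atan2(2 * c12, c11 - c22) # angle of the major direction
  cp <- cos(phi); sp <- sin(phi)
  wrinkled <- mu2 < 1
  slack <- mu1 < 1
  if (any(wrinkled)) {
    m1 <- pmax(mu1, 1)
    m2 <- pmax(mu2, 1)
    c11 <- ifelse(wrinkled, m1 * cp^2 + m2 * sp^2, c11)
    c22 <- ifelse(wrinkled, m1 * sp^2 + m2 * cp^2, c22)
    c12 <- ifelse(wrinkled, (m1 - m2) * cp * sp, c12)
    detF2 <- ifelse(wrinkled, sqrt(m1 * m2), detF2)
  }
  detC2 <- c11 * c22 - c12 * c12
  # fiber invariants in-plane (independent of lambda3 except through J)
  I4p <- c11 * a1c^2 + 2 * c12 * a1c * a2s + c22 * a2s^2
  I4m <- c11 * a1c^2 - 2 * c12 * a1c * a2s + c22 * a2s^2
  i11 <- c22 / detC2; i12 <- -c12 / detC2; i22 <- c11 / detC2

  s33 <- function(l3) {
    J <- l3 * detF2
    Jm23 <- J^(-2 / 3)
    I1 <- c11 + c22 + l3^2
    I1b <- Jm23 * I1
    Ep <- kap * I1b + onek * Jm23 * I4p - 1
    Em <- kap * I1b + onek * Jm23 * I4m - 1
    psip <- ifelse(Ep > 0, params$k1 * Ep * exp(pmin(params$k2 * Ep^2, 60)), 0)
    psim <- ifelse(Em > 0, params$k1 * Em * exp(pmin(params$k2 * Em^2, 60)), 0)
    W1 <- params$c1 * params$c2 * exp(pmin(params$c2 * (I1b - 3), 60)) +
      (psip + psim) * kap
    vol <- (2 / params$D) * (J - 1) * J
    # fibers are in-plane (zero normal component), so they enter S33 only
    # through the -I4/3 C^-1 isochoric projection
    2 * W1 * Jm23 * (1 - I1 / (3 * l3^2)) -
      2 * onek * Jm23 / (3 * l3^2) * (psip * I4p + psim * I4m) +
      vol / l3^2
  }

  # secant iteration from the incompressible guess
  l0 <- 1 / sqrt(pmax(detC2, 1e-12))
  l1 <- l0 * 1.001
  f0 <- s33(l0); f1 <- s33(l1)
  tol <- 1e-7 * (2 / params$D)
  for (it in 1:80) {
    if (all(abs(f1) < tol)) break
    den <- f1 - f0
    den[abs(den) < 1e-300] <- 1e-300
    step <- f1 * (l1 - l0) / den
    step <- pmax(pmin(step, 0.2 * l1), -0.2 * l1)
    l2 <- pmax(l1 - step, 0.05)
    l0 <- l1; f0 <- f1
    l1 <- l2; f1 <- s33(l1)
  }
  if (any(abs(f1) > 1e4 * tol) || any(!is.finite(f1))) {
    # bisection fallback for elements where the exponential stiffening
    # defeats the secant (s33 -> -Inf as l3 -> 0+, +Inf for large l3)
    bad <- which(abs(f1) > 1e4 * tol | !is.finite(f1))
    lo <- rep(0.02, length(f1)); hi <- rep(4, length(f1))
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      fm <- s33(mid)
      up <- fm < 0
      lo <- ifelse(up, mid, lo)
      hi <- ifelse(up, hi, mid)
    }
    l1[bad] <- ((lo + hi) / 2)[bad]
    f1 <- s33(l1)
    if (any(!is.finite(f1)))
      stop(sprintf(paste0("plane-stress root-solve did not converge ",
                          "(material/parameter error): C11=%.4g C12=%.4g ",
                          "C22=%.4g detF2=%.4g"),
                   c11[bad[1]], c12[bad[1]], c22[bad[1]], detF2[bad[1]]))
  }
  l3 <- l1
  J <- l3 * detF2
  Jm23 <- J^(-2 / 3)
  I1 <- c11 + c22 + l3^2
  I1b <- Jm23 * I1
  Ep <- kap * I1b + onek * Jm23 * I4p - 1
  Em <- kap * I1b + onek * Jm23 * I4m - 1
  psip <- ifelse(Ep > 0, params$k1 * Ep * exp(pmin(params$k2 * Ep^2, 60)), 0)
  psim <- ifelse(Em > 0, params$k1 * Em * exp(pmin(params$k2 * Em^2, 60)), 0)
  W1 <- params$c1 * params$c2 * exp(pmin(params$c2 * (I1b - 3), 60)) +
    (psip + psim) * kap
  vol <- (2 / params$D) * (J - 1) * J
  f4 <- 2 * onek * Jm23
  S11 <- 2 * W1 * Jm23 * (1 - I1 / 3 * i11) +
    f4 * (psip * (a1c^2 - I4p / 3 * i11) + psim * (a1c^2 - I4m / 3 * i11)) +
    vol * i11
  S12 <- 2 * W1 * Jm23 * (-I1 / 3 * i12) +
    f4 * (psip * (a1c * a2s - I4p / 3 * i12) +
            psim * (-a1c * a2s - I4m / 3 * i12)) +
    vol * i12
  S22 <- 2 * W1 * Jm23 * (1 - I1 / 3 * i22) +
    f4 * (psip * (a2s^2 - I4p / 3 * i22) + psim * (a2s^2 - I4m / 3 * i22)) +
    vol * i22
  Wfib <- ifelse(Ep > 0, params$k1 / (2 * params$k2) *
                   (exp(pmin(params$k2 * Ep^2, 60)) - 1), 0) +
    ifelse(Em > 0, params$k1 / (2 * params$k2) *
             (exp(pmin(params$k2 * Em^2, 60)) - 1), 0)
  Wd <- params$c1 * (exp(pmin(params$c2 * (I1b - 3), 60)) - 1) + Wfib +
    (1 / params$D) * (J - 1)^2
  if (any(wrinkled)) {
    # keep only the stress along the taut principal direction
    sn <- S11 * cp^2 + 2 * S12 * cp * sp + S22 * sp^2
    S11 <- ifelse(wrinkled, sn * cp^2, S11)
    S12 <- ifelse(wrinkled, sn * cp * sp, S12)
    S22 <- ifelse(wrinkled, sn * sp^2, S22)
    S11[slack] <- 0; S12[slack] <- 0; S22[slack] <- 0
    Wd[slack] <- 0
  }
  list(S11 = S11, S12 = S12, S22 = S22, lambda3 = l3, W = Wd)
}

# In-plane kinematics shared by force and energy evaluation.
membrane_kinematics <- function(mesh, displacements) {
  tri <- mesh$triangles
  P <- mesh$nodes + displacements
  p1 <- P[tri[, 1], , drop = FALSE]
  p2 <- P[tri[, 2], , drop = FALSE]
  p3 <- P[tri[, 3], , drop = FALSE]
  u1 <- p2 - p1; u2 <- p3 - p1
  nrm <- row_cross(u1, u2)
  a2 <- sqrt(rowSums(nrm^2))
  if (any(a2 < 1e-18)) stop("element inversion: degenerate current triangle")
  nrm <- nrm / a2
  e1c <- u1 / sqrt(rowSums(u1^2))
  e2c <- row_cross(nrm, e1c)
  d11 <- rowSums(u1 * e1c); d12 <- rowSums(u2 * e1c)
  d21 <- rowSums(u1 * e2c); d22 <- rowSums(u2 * e2c)
  G <- mesh$G
  F11 <- d11 * G[, "g11"] + d12 * G[, "g21"]
  F12 <- d11 * G[, "g12"] + d12 * G[, "g22"]
  F21 <- d21 * G[, "g11"] + d22 * G[, "g21"]
  F22 <- d21 * G[, "g12"] + d22 * G[, "g22"]
  detF2 <- F11 * F22 - F12 * F21
  if (any(detF2 <= 0)) stop("element inversion: det(F) <= 0")
  list(e1c = e1c, e2c = e2c, F11 = F11, F12 = F12, F21 = F21, F22 = F22,
       detF2 = detF2,
       C11 = F11^2 + F21^2, C12 = F11 * F12 + F21 * F22,
       C22 = F12^2 + F22^2)
}

#' Internal nodal forces of the membrane elements
#'
#' Computes the elastic nodal forces (N) of all membrane triangles from
#' the nodal displacement field: the in-plane deformation gradient is
#' measured in each element's fiber frame, the through-thickness stretch
#' is solved for zero normal stress (plane stress), and the resulting
#' first Piola-Kirchhoff stress is integrated over reference area and
#' thickness. Rigid-body motion produces zero force.
#'
#' @param mesh A [structural_mesh()] with membrane triangles.
#' @param displacements n x 3 nodal displacement matrix (m).
#' @return n x 3 matrix of nodal forces (N) exerted by the elements.
#' @export
membrane_internal_forces <- function(mesh, displacements) {
  n <- nrow(mesh$nodes)
  forces <- matrix(0, n, 3)
  if (is.null(mesh$triangles)) return(forces)
  kin <- membrane_kinematics(mesh, displacements)
  t <- nrow(mesh$triangles)
  S11 <- S12 <- S22 <- numeric(t)
  for (matname in unique(mesh$tri_material)) {
    sel <- mesh$tri_material == matname
    params <- mesh$materials[[matname]]
    if (is.null(params)) stop("no material bound to name: ", matname)
    ps <- mhgo_plane_stress(kin$C11[sel], kin$C12[sel], kin$C22[sel],
                            kin$detF2[sel], params)
    S11[sel] <- ps$S11; S12[sel] <- ps$S12; S22[sel] <- ps$S22
  }
  # P2 = F2 S2 (kPa); H2 = A0 t0 P2 G^T (kN -> x1000 N)
  P11 <- kin$F11 * S11 + kin$F12 * S12
  P12 <- kin$F11 * S12 + kin$F12 * S22
  P21 <- kin$F21 * S11 + kin$F22 * S12
  P22 <- kin$F21 * S12 + kin$F22 * S22
  G <- mesh$G
  at <- 1000 * mesh$area0 * mesh$thickness
  H11 <- at * (P11 * G[, "g11"] + P12 * G[, "g12"])
  H12 <- at * (P11 * G[, "g21"] + P12 * G[, "g22"])
  H21 <- at * (P21 * G[, "g11"] + P22 * G[, "g12"])
  H22 <- at * (P21 * G[, "g21"] + P22 * G[, "g22"])
  # back to 3D: column k of H (3-vector) = e1c * H1k + e2c * H2k
  hcol1 <- kin$e1c * H11 + kin$e2c * H21
  hcol2 <- kin$e1c * H12 + kin$e2c * H22
  tri <- mesh$triangles
  for (k in 1:3) {
    fk <- switch(k, hcol1 + hcol2, -hcol1, -hcol2)
    acc <- rowsum(fk, tri[, k])
    idx <- as.integer(rownames(acc))
    forces[idx, ] <- forces[idx, ] + acc
  }
  forces
}

#' Stable explicit time increment of the membrane mesh
#'
#' Estimates the element-wise critical time step `0.5 min(l) / c` from
#' the current tangent stiffness of the MHGO response (the exponential
#' fiber term stiffens sharply with strain, so the stable increment
#' shrinks as the leaflets load up).
#'
#' @inheritParams membrane_internal_forces
#' @return Stable time increment (s).
#' @export
membrane_stable_dt <- function(mesh, displacements) {
  if (is.null(mesh$triangles)) return(Inf)
  kin <- membrane_kinematics(mesh, displacements)
  t <- nrow(mesh$triangles)
  Et <- numeric(t) # tangent modulus estimate (kPa)
  for (matname in unique(mesh$tri_material)) {
    sel <- mesh$tri_material == matname
    pm <- mesh$materials[[matname]]
    th <- pm$theta * pi / 180
    a1c <- cos(th); a2s <- sin(th)
    kap <- pm$kappa; onek <- 1 - 3 * kap
    c11 <- kin$C11[sel]; c12 <- kin$C12[sel]; c22 <- kin$C22[sel]
    I1 <- c11 + c22 + 1 / pmax(c11 * c22 - c12^2, 1e-6)
    I4p <- c11 * a1c^2 + 2 * c12 * a1c * a2s + c22 * a2s^2
    I4m <- c11 * a1c^2 - 2 * c12 * a1c * a2s + c22 * a2s^2
    Ep <- pmax(kap * I1 + onek * I4p - 1, 0)
    Em <- pmax(kap * I1 + onek * I4m - 1, 0)
    dpsi <- function(E) pm$k1 * (1 + 2 * pm$k2 * E^2) *
      exp(pmin(pm$k2 * E^2, 16))
    # worst-case strain-to-exponent gain ~ 2(1 - 2 kappa); factor 4 from
    # the quadratic invariant kinematics
    Et[sel] <- 8 * pm$c1 * pm$c2 * exp(pmin(pm$c2 * (I1 - 3), 60)) +
      4 * (dpsi(Ep) + dpsi(Em)) * (1 - 2 * kap)^2
  }
  cw <- sqrt(1000 * Et / mesh$density) # m/s
  min(0.25 * mesh$ell / pmax(cw, 1e-6))
}

#' Total membrane strain energy
#'
#' @inheritParams membrane_internal_forces
#' @return Strain energy (J).
#' @export
membrane_strain_energy <- function(mesh, displacements) {
  if (is.null(mesh$triangles)) return(0)
  kin <- membrane_kinematics(mesh, displacements)
  W <- numeric(nrow(mesh$triangles))
  for (matname in unique(mesh$tri_material)) {
    sel <- mesh$tri_material == matname
    ps <- mhgo_plane_stress(kin$C11[sel], kin$C12[sel], kin$C22[sel],
                            kin$detF2[sel], mesh$materials[[matname]])
    W[sel] <- ps$W
  }
  sum(1000 * W * mesh$area0 * mesh$thickness)
}

#' Internal nodal forces of the chordae trusses
#'
#' Ogden trusses, slack in compression by default.
#'
#' @inheritParams membrane_internal_forces
#' @param slack Passed to [ogden_fiber_tension()].
#' @return n x 3 matrix of nodal forces (N).
#' @export
truss_internal_forces <- function(mesh, displacements, slack = TRUE) {
  n <- nrow(mesh$nodes)
  forces <- matrix(0, n, 3)
  if (is.null(mesh$trusses)) return(forces)
  P <- mesh$nodes + displacements
  tr <- mesh$trusses
  dvec <- P[tr[, 2], , drop = FALSE] - P[tr[, 1], , drop = FALSE]
  L <- sqrt(rowSums(dvec^2))
  if (any(L <= 0)) stop("corrupted kinematics: zero-length truss")
  lambda <- L / mesh$truss_L0
  tension <- numeric(nrow(tr))
  for (matname in unique(mesh$truss_material)) {
    sel <- mesh$truss_material == matname
    tension[sel] <- ogden_fiber_tension(lambda[sel],
                                        mesh$materials[[matname]],
                                        mesh$truss_area[sel], slack = slack)
  }
  unit <- dvec / L
  fv <- unit * tension
  acc <- rowsum(fv, tr[, 1])
  idx <- as.integer(rownames(acc))
  forces[idx, ] <- forces[idx, ] + acc
  acc <- rowsum(-fv, tr[, 2])
  idx <- as.integer(rownames(acc))
  forces[idx, ] <- forces[idx, ] + acc
  forces
}

#' Current tension in each truss element
#'
#' @inheritParams truss_internal_forces
#' @return Numeric vector of axial forces (N), one per truss.
#' @export
truss_tensions <- function(mesh, displacements, slack = TRUE) {
  if (is.null(mesh$trusses)) return(numeric(0))
  P <- mesh$nodes + displacements
  tr <- mesh$trusses
  dvec <- P[tr[, 2], , drop = FALSE] - P[tr[, 1], , drop = FALSE]
  lambda <- sqrt(rowSums(dvec^2)) / mesh$truss_L0
  tension <- numeric(nrow(tr))
  for (matname in unique(mesh$truss_material)) {
    sel <- mesh$truss_material == matname
    tension[sel] <- ogden_fiber_tension(lambda[sel],
                                        mesh$materials[[matname]],
                                        mesh$truss_area[sel], slack = slack)
  }
  tension
}
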
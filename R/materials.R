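#' MHGO anisotropic hyperelastic parameters
#'
#' Parameters of the modified Holzapfel-Gasser-Ogden strain energy used
#' for valve leaflets: an exponential isotropic matrix term, two dispersed
#' collagen fiber families at +/- `theta` about the circumferential axis,
#' and a volumetric penalty enforcing near-incompressibility,
#' \deqn{W = c_1\{e^{c_2(\bar I_1 - 3)} - 1\}
#'   + \frac{k_1}{2k_2}\sum_{i=1,2}\left[e^{k_2[\kappa \bar I_1 +
#'     (1-3\kappa)\bar I_{4i} - 1]^2} - 1\right] + \frac{1}{D}(J-1)^2.}
#' A fiber family contributes only while its exponent argument
#' `kappa*I1bar + (1-3kappa)*I4bar - 1` is positive (tension-only fibers).
#'
#' @param c1,c2 Matrix stiffness (kPa) and exponent (dimensionless).
#' @param k1,k2 Fiber stiffness (kPa) and exponent (dimensionless).
#' @param theta Fiber angle from the circumferential axis (degrees).
#' @param kappa Fiber dispersion, in `[0, 1/3]` (0 = perfectly aligned,
#'   1/3 = isotropic).
#' @param D Incompressibility penalty constant (1/kPa), positive; the
#'   volumetric stiffness is `2/D`.
#' @return An object of class `mhgo_params`.
#' @export
mhgo_params <- function(c1, c2, k1, k2, theta, kappa, D = 1e-5) {
  if (c1 <= 0) stop("c1 must be > 0")
  if (k2 <= 0) stop("k2 must be > 0")
  if (kappa < 0 || kappa > 1 / 3) stop("kappa must be in [0, 1/3]")
  if (D <= 0) stop("D must be > 0")
  structure(list(c1 = c1, c2 = c2, k1 = k1, k2 = k2, theta = theta,
                 kappa = kappa, D = D), class = "mhgo_params")
}

#' Ogden hyperelastic parameters
#'
#' Three-term isotropic Ogden model used for chordae tendineae,
#' \deqn{W = \sum_{i=1}^{3} \frac{2\mu_i}{a_i^2}
#'   (\bar\lambda_1^{a_i} + \bar\lambda_2^{a_i} + \bar\lambda_3^{a_i} - 3)}
#' with modified (isochoric) principal stretches.
#'
#' @param mu Length-3 vector of moduli (kPa).
#' @param a Length-3 vector of exponents (dimensionless).
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(mu, a) {
  if (length(mu) != length(a)) stop("mu and a must have equal length")
  if (sum(mu * a) <= 0) stop("ground-state stiffness sum(mu*a) must be > 0")
  structure(list(mu = as.numeric(mu), a = as.numeric(a)),
            class = "ogden_params")
}

#' Human valve tissue material parameters
#'
#' Returns the calibrated human tissue parameter sets used by the
#' simulator: MHGO rows for the aortic leaflets and the anterior/posterior
#' mitral leaflets, and Ogden rows for the basal, strut and marginal
#' chordae. The same table ships as CSV in
#' `system.file("extdata", "valve_materials.csv", package = "sphvalve")`.
#'
#' @return A data frame with one row per tissue.
#' @export
valve_material_table <- function() {
  path <- system.file("extdata", "valve_materials.csv", package = "sphvalve")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up a tissue's constitutive parameters
#'
#' @param tissue Row name in [valve_material_table()], e.g. `"av_leaflet"`,
#'   `"anterior_mv_leaflet"`, `"posterior_mv_leaflet"`, `"basal_chordae"`,
#'   `"strut_chordae"`, `"marginal_chordae"`.
#' @return A [mhgo_params()] or [ogden_params()] object.
#' @export
tissue_params <- function(tissue) {
  tab <- valve_material_table()
  row <- tab[tab$tissue == tissue, ]
  if (nrow(row) != 1) stop("unknown tissue: ", tissue)
  if (row$model == "mhgo") {
    mhgo_params(row$c1, row$c2, row$k1, row$k2, row$theta, row$kappa, row$D)
  } else {
    ogden_params(c(row$mu1, row$mu2, row$mu3), c(row$a1, row$a2, row$a3))
  }
}

# isochoric invariants of C = t(F) %*% F with in-plane fiber directions
mhgo_fiber_dirs <- function(params) {
  th <- params$theta * pi / 180
  list(c(cos(th), sin(th), 0), c(cos(th), -sin(th), 0))
}

#' MHGO strain energy density
#'
#' Evaluates the strain energy (kPa) at a deformation gradient `F`
#' expressed in the local material frame (axis 1 = circumferential,
#' axis 2 = radial, axis 3 = normal). Fiber families under compression
#' (exponent argument <= 0) are excluded.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param params A [mhgo_params()].
#' @return Energy density (kPa, i.e. kJ/m^3).
#' @export
mhgo_strain_energy <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  C <- crossprod(F)
  Cb <- J^(-2 / 3) * C
  I1b <- sum(diag(Cb))
  dirs <- mhgo_fiber_dirs(params)
  Wf <- 0
  for (a in dirs) {
    I4b <- drop(a %*% Cb %*% a)
    E <- params$kappa * I1b + (1 - 3 * params$kappa) * I4b - 1
    if (E > 0)
      Wf <- Wf + params$k1 / (2 * params$k2) *
        (exp(params$k2 * E^2) - 1)
  }
  params$c1 * (exp(params$c2 * (I1b - 3)) - 1) + Wf +
    (1 / params$D) * (J - 1)^2
}

#' MHGO Cauchy stress
#'
#' Closed-form Cauchy stress of the MHGO strain energy at a deformation
#' gradient `F` in the local material frame:
#' `sigma = (2/J) dev[ W1 Bbar + sum_i W4i fbar_i (x) fbar_i ] + (2/D)(J-1) I`
#' with `Bbar` the isochoric left Cauchy-Green tensor and `fbar_i` the
#' pushed-forward (isochoric) fiber directions. Tension-only fiber switch
#' as in [mhgo_strain_energy()].
#'
#' @inheritParams mhgo_strain_energy
#' @return 3x3 symmetric Cauchy stress (kPa).
#' @export
mhgo_cauchy_stress <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  Fb <- J^(-1 / 3) * F
  Bb <- tcrossprod(Fb)
  I1b <- sum(diag(Bb))
  W1 <- params$c1 * params$c2 * exp(params$c2 * (I1b - 3))
  S <- W1 * Bb
  dirs <- mhgo_fiber_dirs(params)
  for (a in dirs) {
    fb <- drop(Fb %*% a)
    I4b <- sum(fb^2)
    E <- params$kappa * I1b + (1 - 3 * params$kappa) * I4b - 1
    if (E > 0) {
      psi <- params$k1 * E * exp(params$k2 * E^2)
      S <- S + psi * params$kappa * Bb
      S <- S + psi * (1 - 3 * params$kappa) * tcrossprod(fb)
    }
  }
  dev <- S - sum(diag(S)) / 3 * diag(3)
  (2 / J) * dev + (2 / params$D) * (J - 1) * diag(3)
}

#' Ogden strain energy under incompressible uniaxial stretch
#'
#' @param lambda Axial stretch, positive.
#' @param params An [ogden_params()].
#' @return Energy density (kPa).
#' @export
ogden_uniaxial_energy <- function(lambda, params) {
  lt <- 1 / sqrt(lambda)
  W <- 0
  for (i in seq_along(params$mu)) {
    ai <- params$a[i]
    W <- W + 2 * params$mu[i] / ai^2 * (lambda^ai + 2 * lt^ai - 3)
  }
  W
}

#' Axial force in an Ogden chordae truss
#'
#' Uniaxial tension of an incompressible Ogden truss: the axial force is
#' the reference cross-section area times the nominal stress `dW/dlambda`
#' (equivalently, Cauchy stress times the current area). By default
#' chordae are slack in compression (`lambda < 1` gives zero force); set
#' `slack = FALSE` to allow a compressive response for debugging.
#'
#' @param lambda Stretch (current length / reference length), positive.
#' @param params An [ogden_params()] (moduli in kPa).
#' @param area Reference cross-section area (m^2).
#' @param slack Logical; chordae carry no compression when `TRUE`
#'   (default).
#' @return Axial force (N), positive in tension.
#' @export
ogden_fiber_tension <- function(lambda, params, area, slack = TRUE) {
  if (any(lambda <= 0)) stop("corrupted kinematics: lambda must be > 0")
  dW <- numeric(length(lambda))
  for (i in seq_along(params$mu)) {
    ai <- params$a[i]
    dW <- dW + 2 * params$mu[i] / ai *
      (lambda^(ai - 1) - lambda^(-ai / 2 - 1))
  }
  f <- 1000 * area * dW # kPa -> Pa
  if (slack) f[lambda < 1] <- 0
  f
}
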
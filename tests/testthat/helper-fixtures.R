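# Shared fixtures. Heavy scene runs are computed once per test session
# and reused by the unit and acceptance tests.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]]))
    fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

hydro_fixture <- function() fixture("hydro", function() {
  sc <- make_hydrostatic_tank()
  # short undamped window: the final state is then still quiescent for
  # snapshot-based probe checks (undamped acoustics slosh at the few-%
  # level on longer horizons)
  list(scene = sc, result = run_scene(sc, duration = 0.005))
})

poiseuille_fixture <- function() fixture("pois", function() {
  sc <- make_poiseuille_channel()
  list(scene = sc, result = run_scene(sc, duration = 2.0,
                                      trace_every = 1e6))
})

gate_fixture <- function() fixture("gate", function() {
  sc <- make_elastic_gate()
  list(scene = sc, result = run_scene(sc, duration = 0.05,
                                      trace_every = 100))
})

valve_fixture <- function() fixture("valve", function() {
  sc <- make_tube_valve()
  list(scene = sc, result = run_scene(sc, duration = 0.13,
                                      trace_every = 60))
})

lv_fixture <- function() fixture("lv", function() {
  sc <- make_idealized_lv()
  list(scene = sc, result = run_scene(sc, duration = 0.12,
                                      trace_every = 100))
})

# independent scalar MHGO strain energy used as the differentiation
# oracle for stress checks (implemented directly from the printed law,
# separately from the package's vectorized code paths)
oracle_mhgo_energy <- function(F, p) {
  J <- det(F)
  C <- t(F) %*% F
  Cb <- J^(-2 / 3) * C
  I1b <- sum(diag(Cb))
  th <- p$theta * pi / 180
  W <- p$c1 * (exp(p$c2 * (I1b - 3)) - 1) + (1 / p$D) * (J - 1)^2
  for (sgn in c(1, -1)) {
    a <- c(cos(th), sgn * sin(th), 0)
    I4 <- drop(a %*% Cb %*% a)
    E <- p$kappa * I1b + (1 - 3 * p$kappa) * I4 - 1
    if (E > 0) W <- W + p$k1 / (2 * p$k2) * (exp(p$k2 * E^2) - 1)
  }
  W
}

oracle_mhgo_stress <- function(F, p, step = 1e-6) {
  P1 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + step
    Fm <- F; Fm[i, j] <- Fm[i, j] - step
    P1[i, j] <- (oracle_mhgo_energy(Fp, p) - oracle_mhgo_energy(Fm, p)) /
      (2 * step)
  }
  P1 %*% t(F) / det(F)
}

oracle_ogden_energy <- function(lambda, p) {
  lt <- 1 / sqrt(lambda)
  sum(2 * p$mu / p$a^2 * (lambda^p$a + 2 * lt^p$a - 3))
}

# random admissible deformation gradient with both fiber families
# clearly in tension (away from the tension-switch kink)
random_tension_F <- function(p) {
  stretch <- diag(c(1 + runif(1, 0.01, 0.04), 1 + runif(1, 0.005, 0.03),
                    1 - runif(1, 0, 0.02)))
  pert <- matrix(rnorm(9, 0, 0.005), 3, 3)
  F <- stretch + pert
  if (det(F) <= 0) F <- stretch
  F
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_fluid_state <- function(n, dim = 3, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(n * dim, 0, 0.02), n, dim)
  vel <- matrix(rnorm(n * dim, 0, 0.3), n, dim)
  fluid_state(pos, vel, densities = 1056 * (1 + rnorm(n, 0, 0.005)),
              masses = rep(1056 * 2e-3^dim, n),
              pressures = rnorm(n, 0, 50))
}

# soft isotropic membrane material for structural dynamics checks
gate_stub_material <- function(c1_kpa = 100) {
  mhgo_params(c1 = c1_kpa, c2 = 0.5, k1 = 1e-8, k2 = 1, theta = 0,
              kappa = 1 / 3, D = 1e-5)
}

# pre-tensioned square drum (4 pinned corners, center node): symmetric,
# so the center node oscillates purely out of plane
drum_mesh <- function(pre = 1.03) {
  L <- 0.01
  nodes <- rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0), c(0, L, 0),
                 c(L / 2, L / 2, 0))
  mesh <- structural_mesh(nodes,
                          triangles = rbind(c(1, 2, 5), c(2, 3, 5),
                                            c(3, 4, 5), c(4, 1, 5)),
                          thickness = 4e-4,
                          fiber_dir = matrix(rep(c(1, 0, 0), 4), 4, 3,
                                             byrow = TRUE),
                          materials = list(default = gate_stub_material()))
  u <- nodes %*% diag(c(pre, pre, 1)) - nodes
  list(mesh = mesh, pretension_u = u)
}
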
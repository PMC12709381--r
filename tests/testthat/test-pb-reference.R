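# The numerical PB solver is itself the oracle for the weak-overlap model,
# so its own tests lean on closed forms: the Gouy-Chapman profile, the
# Debye-Hueckel limit, linear superposition and the contact-value theorem.

spec_1mM <- kcl_solution(0.001)
kap <- 1 / debye_length(spec_1mM)

test_that("isolated-surface profile matches Gouy-Chapman and Grahame", {
  # zero charge -> zero potential everywhere
  iso0 <- solve_isolated(spec_1mM, sigma = 0)
  expect_true(all(iso0$potential == 0))

  # Debye-Hueckel limit: simple exponential decay
  iso <- solve_isolated(spec_1mM, psi0 = 5e-3)
  ref <- 5e-3 * exp(-kap * iso$grid)
  expect_lt(max(abs(iso$potential - ref) / 5e-3), 5e-3)

  # sigma <-> psi0 roundtrip consistent with the full Grahame relation
  iso50 <- solve_isolated(spec_1mM, psi0 = 50e-3)
  back <- solve_isolated(spec_1mM, sigma = iso50$sigma)
  expect_rel(back$psi0, 50e-3, 1e-6)
  expect_equal(iso50$sigma,
               grahame_sigma(50e-3, spec_1mM, "full")$sigma_C_m2)
})

test_that("two-plate solution obeys superposition and decoupling limits", {
  # weak overlap, small potential: midplane ~ superposed isolated tails
  sol <- solve_two_plate(pb_problem(5 / kap, spec_1mM, 10e-3,
                                    inner_capacitance = 0))
  expect_rel(sol$midplane_potential, 2 * 10e-3 * exp(-2.5), 0.02)

  # large separation at constant charge: wall potential ~ isolated value
  far <- solve_two_plate(pb_problem(12 / kap, spec_1mM, 20e-3,
                                    inner_capacitance = 0))
  expect_rel(far$psi_wall, 20e-3, 5e-3)

  # pressure grows monotonically as constant-charge plates approach
  p_seq <- vapply(c(4, 2, 1) / kap, function(D) {
    solve_two_plate(pb_problem(D, spec_1mM, 20e-3, 0))$pressure
  }, 0)
  expect_false(is.unsorted(p_seq))
  expect_true(all(p_seq >= 0))
})

test_that("disjoining pressure is plane-independent and matches DH expansion", {
  pr <- solve_two_plate(pb_problem(4 / kap, spec_1mM, 25e-3,
                                   inner_capacitance = 1e-3))
  expect_rel(disjoining_pressure(pr, "wall"),
             disjoining_pressure(pr, "midplane"), 5e-3)

  # small midplane potential: cosh expansion P ~ eps0 eps kappa^2 psi_m^2 / 2
  # per ... = 2 c0 kB T (y_m^2 / 2) with kappa^2 = 2 c0 e^2 / (eps0 eps kB T)
  small <- solve_two_plate(pb_problem(8 / kap, spec_1mM, 5e-3, 0))
  vt <- thermal_voltage(298.15)
  y_m <- small$midplane_potential / vt
  eps <- 78.3
  dh <- 8.8541878128e-12 * eps * kap^2 * small$midplane_potential^2 / 2
  expect_rel(small$pressure, dh, 0.01)

  # grid refinement: halving the spacing changes the pressure < 0.1%
  a <- solve_two_plate(pb_problem(4 / kap, spec_1mM, 25e-3, 0),
                       n_start = 400)
  b <- solve_two_plate(pb_problem(4 / kap, spec_1mM, 25e-3, 0),
                       n_start = 800)
  expect_rel(a$pressure, b$pressure, 1e-3)
})

test_that("pressure integration reproduces analytic energies", {
  D <- seq(1, 22, by = 0.05) * 1e-9
  # null case
  z <- energy_from_pressure(D, rep(0, length(D)))
  expect_true(all(z$energy == 0))
  # exponential pressure: W = (P0/kappa) exp(-kappa D)
  k <- 1 / 2e-9
  P <- 1e3 * exp(-k * D)
  w <- expect_no_warning(energy_from_pressure(D, P))
  ref <- (1e3 / k) * (exp(-k * D) - exp(-k * max(D)))
  expect_lt(max(abs(w$energy - ref)) / max(ref), 5e-3)
  # truncation warning when the tail has not decayed
  expect_warning(energy_from_pressure(D[1:40], P[1:40]), "tail")
})

test_that("numerical PB validates the weak-overlap regulation model to 5%", {
  vt <- thermal_voltage(298.15)
  eps <- relative_permittivity(spec_1mM)
  for (psi_mV in c(10, 25)) {
    for (p in c(0.3, 0.9)) {
      psi <- psi_mV * 1e-3
      psi_eff <- 4 * vt * tanh(psi / (4 * vt))  # far-field amplitude
      D <- c(3, 4, 5) / kap
      w_pb <- pb_edl_energy(spec_1mM, psi, p, D)
      w_model <- edl_energy(D, dlvo_params(psi_eff, kap, p, 0), eps)
      expect_lt(max(abs(w_pb - w_model) / w_model), 0.05)
    }
  }
})

test_that("boundary-condition ordering holds at fixed isolated state", {
  D <- 3.5 / kap
  w_cc <- pb_edl_energy(spec_1mM, 20e-3, 1, D, step = 0.25)
  w_reg <- pb_edl_energy(spec_1mM, 20e-3, 0.5, D, step = 0.25)
  w_cp <- pb_edl_energy(spec_1mM, 20e-3, 0, D, step = 0.25)
  expect_gte(w_cc, w_reg)
  expect_gte(w_reg, w_cp)
})

test_that("regulation parameter maps to inner capacitance and back", {
  for (p in c(0.25, 0.5, 0.9)) {
    ci <- inner_capacitance_for_p(p, kap)
    expect_equal(regulation_p(ci, kap), p)
  }
  expect_equal(regulation_p(0, kap), 1)           # constant charge
  expect_equal(regulation_p(Inf, kap), 0)         # constant potential
  expect_identical(inner_capacitance_for_p(0, kap), Inf)
  # multivalent electrolytes are rejected
  bad <- solution_spec(list(species_spec("Ca2+", 0.01, 2L, 40),
                            species_spec("Cl-", 0.02, -1L, 35.45)))
  expect_error(pb_problem(1e-9, bad, 10e-3), "1:1")
})
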
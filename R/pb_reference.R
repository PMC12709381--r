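#' Map between the regulation parameter and an inner-layer capacitance
#'
#' The constant regulation approximation identifies
#' `p = C_D / (C_D + C_inner)` with `C_D = eps0 eps_e kappa` the linearized
#' diffuse-layer capacitance. `regulation_p()` computes p from a capacitance;
#' `inner_capacitance_for_p()` inverts it (`p = 1` -> 0 F/m^2, constant
#' charge; `p = 0` -> `Inf`, constant potential).
#'
#' @param inner_capacitance inner (Stern) layer capacitance in F/m^2 (>= 0;
#'   `Inf` allowed).
#' @param p regulation parameter in `[0, 1]`.
#' @param kappa inverse Debye length, 1/m.
#' @param eps_e relative permittivity.
#' @return dimensionless p, respectively a capacitance in F/m^2.
#' @export
regulation_p <- function(inner_capacitance, kappa,
                         eps_e = .default_eps_water) {
  .check_positive(kappa, "kappa")
  if (inner_capacitance < 0) stop("`inner_capacitance` must be >= 0",
                                  call. = FALSE)
  cd <- .const$eps0 * eps_e * kappa
  if (is.infinite(inner_capacitance)) return(0)
  cd / (cd + inner_capacitance)
}

#' @rdname regulation_p
#' @export
inner_capacitance_for_p <- function(p, kappa, eps_e = .default_eps_water) {
  .check_positive(kappa, "kappa")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  cd <- .const$eps0 * eps_e * kappa
  if (p == 0) return(Inf)
  cd * (1 - p) / p
}

#' Define a two-plate Poisson-Boltzmann problem
#'
#' Two identical charge-regulating plates at separation `D` across a 1:1
#' electrolyte. The wall boundary condition is the linear regulation closure
#' `sigma(psi_s) = sigma_inf + C_inner (psi_inf - psi_s)`, where `sigma_inf`
#' and `psi_inf` are the isolated-surface (infinite separation) charge and
#' diffuse-layer potential, related by the full Grahame equation.
#'
#' @param separation plate separation in m (> 0).
#' @param spec a [solution_spec()]; must be a 1:1 electrolyte with positive
#'   ionic strength.
#' @param isolated_potential diffuse-layer potential of an isolated surface,
#'   V.
#' @param inner_capacitance F/m^2; 0 for constant charge, `Inf` for constant
#'   potential, finite positive for regulation (see [regulation_p()]).
#' @return object of class `pb_problem`.
#' @export
pb_problem <- function(separation, spec, isolated_potential,
                       inner_capacitance = 0) {
  .check_positive(separation, "separation")
  stopifnot(inherits(spec, "solution_spec"))
  z <- vapply(spec$species, `[[`, 0L, "valence")
  if (any(abs(z) > 1)) {
    stop("PB solver supports 1:1 electrolytes only", call. = FALSE)
  }
  if (ionic_strength(spec) <= 0) {
    stop("PB solver requires positive ionic strength", call. = FALSE)
  }
  if (inner_capacitance < 0) stop("`inner_capacitance` must be >= 0",
                                  call. = FALSE)
  structure(
    list(separation = separation, spec = spec,
         isolated_potential = isolated_potential,
         inner_capacitance = inner_capacitance),
    class = "pb_problem"
  )
}

#' Analytic Gouy-Chapman profile of an isolated surface
#'
#' Closed-form solution of the nonlinear Poisson-Boltzmann equation for a
#' single charged plate in a 1:1 electrolyte,
#' `y(x) = 4 artanh(gamma exp(-kappa x))` with `gamma = tanh(y0/4)` in
#' thermal units. Supply either the surface potential or the surface charge
#' (converted through the full Grahame relation).
#'
#' @param spec a [solution_spec()] (1:1, positive ionic strength).
#' @param psi0 surface potential in V, or `NULL` if `sigma` is given.
#' @param sigma surface charge density in C/m^2, or `NULL` if `psi0` given.
#' @param x_max profile extent in units of the Debye length (default 10).
#' @param n number of grid points.
#' @return list with `grid` (m), `potential` (V), `psi0` (V), `sigma`
#'   (C/m^2), `kappa` (1/m).
#' @export
solve_isolated <- function(spec, psi0 = NULL, sigma = NULL, x_max = 10,
                           n = 400) {
  stopifnot(inherits(spec, "solution_spec"))
  z <- vapply(spec$species, `[[`, 0L, "valence")
  if (any(abs(z) > 1)) {
    stop("isolated-surface solver supports 1:1 electrolytes only",
         call. = FALSE)
  }
  kappa <- 1 / debye_length(spec)
  eps_e <- relative_permittivity(spec)
  vt <- thermal_voltage(spec$temperature)
  if (is.null(psi0) && is.null(sigma)) {
    stop("supply `psi0` or `sigma`", call. = FALSE)
  }
  if (is.null(psi0)) {
    # dimensionless Grahame inverse: s = 2 sinh(y0/2)
    s <- sigma / (.const$eps0 * eps_e * kappa * vt)
    y0 <- 2 * asinh(s / 2)
    psi0 <- y0 * vt
  } else {
    sigma <- grahame_sigma(psi0, kappa = kappa, eps_e = eps_e,
                           temperature = spec$temperature,
                           variant = "full")$sigma_C_m2
  }
  y0 <- psi0 / vt
  gam <- tanh(y0 / 4)
  x <- seq(0, x_max / kappa, length.out = n)
  y <- 4 * atanh(gam * exp(-kappa * x))
  list(grid = x, potential = y * vt, psi0 = psi0, sigma = sigma,
       kappa = kappa)
}

# internal: damped Newton solve of the dimensionless PB equation on the
# half-domain [0, kappa*D/2] with regulation wall BC and symmetry at the
# midplane. Returns dimensionless potential at n+1 nodes.
.pb_newton <- function(L, y_inf, c_hat, n, y_init = NULL, max_iter = 60) {
  h <- L / n
  xs <- seq(0, L, length.out = n + 1)
  s_inf <- 2 * sinh(y_inf / 2)
  dirichlet <- is.infinite(c_hat)  # constant potential
  if (is.null(y_init)) {
    gam <- tanh(y_inf / 4)
    y <- 4 * atanh(pmin(0.999999,
                        gam * (exp(-xs) + exp(-(2 * L - xs)))))
  } else {
    y <- y_init
  }
  residual <- function(y) {
    r <- numeric(n + 1)
    if (dirichlet) {
      r[1] <- y[1] - y_inf
    } else {
      r[1] <- 2 * y[2] - 2 * y[1] +
        2 * h * (s_inf + c_hat * (y_inf - y[1])) - h^2 * sinh(y[1])
    }
    i <- 2:n
    r[i] <- y[i - 1] - 2 * y[i] + y[i + 1] - h^2 * sinh(y[i])
    r[n + 1] <- 2 * y[n] - 2 * y[n + 1] - h^2 * sinh(y[n + 1])
    r
  }
  r <- residual(y)
  for (iter in seq_len(max_iter)) {
    diag_main <- c(
      if (dirichlet) 1 else -2 - 2 * h * c_hat - h^2 * cosh(y[1]),
      -2 - h^2 * cosh(y[2:n]),
      -2 - h^2 * cosh(y[n + 1])
    )
    diag_up <- c(if (dirichlet) 0 else 2, rep(1, n - 1))
    diag_lo <- c(rep(1, n - 1), 2)
    J <- Matrix::bandSparse(n + 1, n + 1, k = c(-1, 0, 1),
                            diagonals = list(diag_lo, diag_main, diag_up))
    delta <- as.numeric(Matrix::solve(J, -r))
    # damped update: halve the step until the residual norm decreases
    lambda <- 1
    nr <- sum(r^2)
    repeat {
      y_new <- y + lambda * delta
      r_new <- residual(y_new)
      if (sum(r_new^2) <= nr || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    y <- y_new
    r <- r_new
    if (max(abs(lambda * delta)) < 1e-12) {
      return(list(y = y, grid = xs, converged = TRUE, iterations = iter,
                  residual = max(abs(r))))
    }
  }
  list(y = y, grid = xs, converged = FALSE, iterations = max_iter,
       residual = max(abs(r)))
}

#' Solve the two-plate Poisson-Boltzmann problem
#'
#' Nonlinear PB equation `y'' = sinh(y)` (thermal units, lengths in Debye
#' lengths) on the symmetry half-domain `[0, D/2]`, with the linear
#' regulation wall condition and zero-gradient midplane condition.
#' Second-order finite differences with damped Newton iteration, initial
#' guess from superposed isolated (Gouy-Chapman) profiles; the grid is
#' refined by doubling until the disjoining pressure changes by less than
#' 0.1%.
#'
#' @param problem a [pb_problem()].
#' @param n_start initial number of intervals (doubled on refinement).
#' @param reltol relative pressure change at which refinement stops.
#' @return object of class `pb_solution_profile`: `grid` (m, wall at 0),
#'   `potential` (V), `midplane_potential` (V), `pressure` (Pa, midplane
#'   evaluation), `sigma_wall` (C/m^2), `psi_wall` (V), `n_grid`,
#'   `converged`, plus the embedded `problem`.
#' @export
solve_two_plate <- function(problem, n_start = 200, reltol = 1e-3) {
  stopifnot(inherits(problem, "pb_problem"))
  spec <- problem$spec
  kappa <- 1 / debye_length(spec)
  eps_e <- relative_permittivity(spec)
  vt <- thermal_voltage(spec$temperature)
  cd <- .const$eps0 * eps_e * kappa
  c_hat <- problem$inner_capacitance / cd
  y_inf <- problem$isolated_potential / vt
  L <- kappa * problem$separation / 2

  n <- n_start
  last_p <- NULL
  sol <- NULL
  repeat {
    init <- if (is.null(sol)) NULL else {
      stats::approx(sol$grid, sol$y, xout = seq(0, L, length.out = n + 1))$y
    }
    sol <- .pb_newton(L, y_inf, c_hat, n, y_init = init)
    if (!sol$converged) {
      stop(sprintf(
        "PB solve did not converge (n = %d, max residual %.3g)",
        n, sol$residual), call. = FALSE)
    }
    p_now <- .pb_pressure_from_ym(sol$y[length(sol$y)], spec)
    if (!is.null(last_p)) {
      denom <- max(abs(last_p), .Machine$double.xmin)
      if (abs(p_now - last_p) / denom < reltol || n >= 12800) break
    }
    last_p <- p_now
    n <- n * 2
  }

  y <- sol$y
  h <- L / n
  # one-sided second-order derivative at the wall -> surface charge
  dy0 <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  sigma_wall <- -cd * vt * dy0
  structure(
    list(grid = sol$grid / kappa, potential = y * vt,
         midplane_potential = y[length(y)] * vt,
         pressure = p_now, sigma_wall = sigma_wall, psi_wall = y[1] * vt,
         n_grid = n, converged = TRUE, problem = problem),
    class = "pb_solution_profile"
  )
}

# internal: midplane osmotic pressure from dimensionless midplane potential
.pb_pressure_from_ym <- function(y_m, spec) {
  c0 <- ionic_strength(spec) * 1000 * .const$N_A  # ions per m^3 of each sign
  2 * c0 * .const$kB * spec$temperature * (cosh(y_m) - 1)
}

#' Disjoining pressure of a solved two-plate profile
#'
#' Midplane evaluation `P = 2 c0 kB T (cosh(y_m) - 1)` (excess osmotic
#' pressure; the electrostatic stress vanishes at the symmetry plane). The
#' wall evaluation `P = 2 c0 kB T (cosh(y_s) - 1) - sigma^2 / (2 eps0 eps_e)`
#' is provided as a contact-value-theorem cross-check: both must agree for a
#' converged profile.
#'
#' @param profile a `pb_solution_profile` from [solve_two_plate()].
#' @param at `"midplane"` (default) or `"wall"`.
#' @return pressure in Pa (>= 0 for identical like-charged plates).
#' @export
disjoining_pressure <- function(profile, at = c("midplane", "wall")) {
  stopifnot(inherits(profile, "pb_solution_profile"))
  at <- match.arg(at)
  spec <- profile$problem$spec
  if (at == "midplane") return(profile$pressure)
  vt <- thermal_voltage(spec$temperature)
  eps_e <- relative_permittivity(spec)
  c0 <- ionic_strength(spec) * 1000 * .const$N_A
  2 * c0 * .const$kB * spec$temperature * (cosh(profile$psi_wall / vt) - 1) -
    profile$sigma_wall^2 / (2 * .const$eps0 * eps_e)
}

#' Integrate a pressure-distance curve to an energy profile
#'
#' `W(D) = integral_D^inf P(D') dD'` by trapezoidal integration from the far
#' field inward, with `W` at the largest sampled separation set to zero.
#' Warns when the pressure tail has not decayed below 1e-4 of its maximum
#' magnitude (truncation error).
#'
#' @param separations strictly increasing separations in m.
#' @param pressures pressures in Pa at those separations.
#' @return an `energy_profile` (list of `separations`, `energy` in J/m^2).
#' @export
energy_from_pressure <- function(separations, pressures) {
  stopifnot(length(separations) == length(pressures), length(separations) >= 2)
  if (is.unsorted(separations, strictly = TRUE)) {
    stop("`separations` must be strictly increasing", call. = FALSE)
  }
  n <- length(pressures)
  if (abs(pressures[n]) > 1e-4 * max(abs(pressures))) {
    warning("pressure tail not decayed below 1e-4 of its maximum; ",
            "energy profile is truncated", call. = FALSE)
  }
  dx <- diff(separations)
  seg <- dx * (pressures[-1] + pressures[-n]) / 2
  W <- rev(c(0, cumsum(rev(seg))))
  structure(list(separations = separations, energy = W),
            class = "energy_profile")
}

#' Double-layer energy from the numerical PB solver
#'
#' Full pipeline used as the independent oracle for the weak-overlap
#' constant-regulation model: solve the two-plate PB problem on a separation
#' grid extending ~10 Debye lengths beyond the largest requested separation,
#' integrate the disjoining pressure, and interpolate the energy at the
#' requested separations.
#'
#' @param spec a [solution_spec()] (1:1, positive ionic strength).
#' @param isolated_potential diffuse-layer potential of the isolated surface,
#'   V.
#' @param p regulation parameter in `[0, 1]`.
#' @param separations separations in m at which the energy is wanted.
#' @param step grid step for the pressure integration, in Debye lengths.
#' @param tail extension beyond `max(separations)`, in Debye lengths.
#' @return numeric vector of energies per unit area, J/m^2.
#' @export
pb_edl_energy <- function(spec, isolated_potential, p, separations,
                          step = 0.2, tail = 10) {
  kappa <- 1 / debye_length(spec)
  c_inner <- inner_capacitance_for_p(p, kappa, relative_permittivity(spec))
  d_grid <- seq(min(separations),
                max(separations) + tail / kappa,
                by = step / kappa)
  pressures <- vapply(d_grid, function(D) {
    solve_two_plate(pb_problem(D, spec, isolated_potential, c_inner))$pressure
  }, 0)
  prof <- energy_from_pressure(d_grid, pressures)
  stats::approx(prof$separations, prof$energy, xout = separations)$y
}
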
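#' DLVO parameter vector with charge regulation
#'
#' Parameters of the interaction free energy per unit area between two
#' identical charged plates across a 1:1 electrolyte,
#'
#' \deqn{W(D) = -\frac{A}{12 \pi D^2} +
#'   \frac{2 \epsilon_0 \epsilon_e \kappa \psi_{eff}^2 e^{-\kappa D}}
#'        {1 + (1 - 2p) e^{-\kappa D}}}
#'
#' where `p` is the constant-regulation parameter: `p = 0` constant potential,
#' `p = 1` constant charge, intermediate values linear regulation between the
#' two boundary conditions.
#'
#' @param psi_eff effective surface potential magnitude, V (the sign of the
#'   surface charge does not enter the symmetric interaction).
#' @param kappa inverse Debye length, 1/m (> 0).
#' @param p regulation parameter in `[0, 1]`.
#' @param hamaker Hamaker constant, J (>= 0). Default 2.2e-20 J, a literature
#'   value for mica-water-mica; always configurable.
#' @return object of class `dlvo_params`.
#' @export
dlvo_params <- function(psi_eff, kappa, p = 0.5, hamaker = 2.2e-20) {
  .check_positive(kappa, "kappa")
  if (!is.finite(p) || p < 0 || p > 1) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(hamaker) || hamaker < 0) {
    stop("`hamaker` must be >= 0", call. = FALSE)
  }
  structure(
    list(psi_eff = abs(psi_eff), kappa = kappa, p = p, hamaker = hamaker),
    class = "dlvo_params"
  )
}

#' @export
print.dlvo_params <- function(x, ...) {
  cat(sprintf(
    "<dlvo_params> psi_eff = %.3g mV, kappa^-1 = %.3g nm, p = %.3g, A = %.3g J\n",
    x$psi_eff * 1e3, 1e9 / x$kappa, x$p, x$hamaker))
  invisible(x)
}

#' Van der Waals interaction energy per unit area
#'
#' Non-retarded Hamaker form `-A / (12 pi D^2)` for two half-spaces; always
#' attractive (<= 0).
#'
#' @param D separation in m (> 0); vectorized.
#' @param hamaker Hamaker constant in J (>= 0).
#' @return energy per unit area in J/m^2.
#' @export
vdw_energy <- function(D, hamaker) {
  if (any(!is.finite(D)) || any(D <= 0)) stop("`D` must be > 0", call. = FALSE)
  if (hamaker < 0) stop("`hamaker` must be >= 0", call. = FALSE)
  -hamaker / (12 * pi * D^2)
}

#' Electric double-layer interaction energy with constant regulation
#'
#' `2 eps0 eps_e kappa psi_eff^2 exp(-kappa D) / (1 + (1 - 2p) exp(-kappa D))`.
#' For `p > 0.5` the denominator can approach zero as `D -> 0` (constant-charge
#' divergence); evaluation refuses separations where it falls below 1e-6
#' rather than returning huge numbers.
#'
#' @param D separation in m (> 0); vectorized.
#' @param params a [dlvo_params()].
#' @param eps_e relative permittivity of the electrolyte.
#' @return energy per unit area in J/m^2 (>= 0).
#' @export
edl_energy <- function(D, params, eps_e = .default_eps_water) {
  stopifnot(inherits(params, "dlvo_params"))
  if (any(!is.finite(D)) || any(D <= 0)) stop("`D` must be > 0", call. = FALSE)
  u <- exp(-params$kappa * D)
  denom <- 1 + (1 - 2 * params$p) * u
  if (any(denom < 1e-6)) {
    stop("regulation denominator below 1e-6 (constant-charge divergence); ",
         "restrict the evaluation window to larger D", call. = FALSE)
  }
  2 * .const$eps0 * eps_e * params$kappa * params$psi_eff^2 * u / denom
}

#' Total DLVO interaction energy per unit area
#'
#' Sum of [vdw_energy()] and [edl_energy()]; repulsion positive.
#'
#' @inheritParams edl_energy
#' @return energy per unit area in J/m^2.
#' @examples
#' pars <- dlvo_params(psi_eff = 63e-3, kappa = 1 / 40e-9, p = 0.9)
#' total_energy(seq(5, 100, by = 5) * 1e-9, pars)
#' @export
total_energy <- function(D, params, eps_e = .default_eps_water) {
  vdw_energy(D, params$hamaker) + edl_energy(D, params, eps_e)
}

#' Evaluate a DLVO energy profile on a separation grid
#'
#' @param separations strictly increasing separations in m.
#' @inheritParams edl_energy
#' @return an `energy_profile`: list with `separations` (m) and `energy`
#'   (J/m^2).
#' @export
energy_profile <- function(separations, params, eps_e = .default_eps_water) {
  if (is.unsorted(separations, strictly = TRUE)) {
    stop("`separations` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(separations = separations,
         energy = total_energy(separations, params, eps_e)),
    class = "energy_profile"
  )
}

#' Grahame relation between surface charge and potential
#'
#' Diffuse-layer charge density of an isolated surface in a 1:1 electrolyte:
#' full form `sigma = (2 eps0 eps_e kappa kB T / e) sinh(e psi / 2 kB T)`,
#' linearized form `sigma = eps0 eps_e kappa psi`. Both variants are exposed;
#' they agree to 0.2% for `psi` below ~5 mV.
#'
#' @param psi surface potential in V.
#' @param spec a [solution_spec()] with non-zero ionic strength, used for
#'   kappa, permittivity and temperature. Alternatively supply `kappa`,
#'   `eps_e`, `temperature` directly.
#' @param variant `"full"` or `"linearized"`.
#' @param kappa,eps_e,temperature override the solution-derived values.
#' @return list with `sigma_C_m2` (C/m^2) and `sigma_e_nm2` (e/nm^2).
#' @examples
#' grahame_sigma(63e-3, kappa = 1 / 40e-9, variant = "full")
#' @export
grahame_sigma <- function(psi, spec = NULL, variant = c("full", "linearized"),
                          kappa = NULL, eps_e = .default_eps_water,
                          temperature = .default_temperature) {
  variant <- match.arg(variant)
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "solution_spec"))
    if (variant == "full") {
      z <- vapply(spec$species, `[[`, 0L, "valence")
      if (any(abs(z) > 1)) {
        stop("full Grahame variant supports 1:1 electrolytes only",
             call. = FALSE)
      }
    }
    kappa <- 1 / debye_length(spec)  # errors on zero ionic strength
    eps_e <- relative_permittivity(spec)
    temperature <- spec$temperature
  }
  if (is.null(kappa)) stop("supply `spec` or `kappa`", call. = FALSE)
  .check_positive(kappa, "kappa")
  vt <- thermal_voltage(temperature)
  sigma <- switch(variant,
    full = 2 * .const$eps0 * eps_e * kappa * vt * sinh(psi / (2 * vt)),
    linearized = .const$eps0 * eps_e * kappa * psi
  )
  list(sigma_C_m2 = sigma, sigma_e_nm2 = sigma / .const$e_per_nm2)
}

#' Derjaguin conversion between plate energy and crossed-cylinder force
#'
#' For crossed cylinders (equivalently sphere-plane) of radius `R` with
#' `R >> D`, the measured force relates to the parallel-plate interaction
#' free energy per unit area by `F = 2 pi R W`.
#'
#' @param W energy per unit area in J/m^2.
#' @param F force in N.
#' @param R lens radius in m (> 0).
#' @return force in N (`energy_to_force`), energy in J/m^2
#'   (`force_to_energy`).
#' @export
energy_to_force <- function(W, R) {
  .check_positive(R, "R")
  2 * pi * R * W
}

#' @rdname energy_to_force
#' @export
force_to_energy <- function(F, R) {
  .check_positive(R, "R")
  F / (2 * pi * R)
}
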
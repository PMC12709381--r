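#' Specify a dissolved species
#'
#' One solute in a [solution_spec()]: an ion (valence +/-1, ...) or a neutral
#' zwitterion such as proline (valence 0). Concentrations are molal
#' (mol per kg of water), the unit in which SFB solutions are prepared.
#'
#' @param name species label, e.g. `"K+"`, `"Cl-"`, `"proline"`.
#' @param molality mol per kg water, >= 0.
#' @param valence integer charge number; 0 for zwitterions/neutrals.
#' @param molar_mass g/mol, > 0.
#' @param dielectric_increment change of relative permittivity per mol/L of
#'   this species (default 0; positive for strongly dipolar zwitterions).
#' @param partial_molar_volume cm^3/mol, used by the solution volume model
#'   when converting molality to molarity; `NA` means "neglect the solute
#'   volume".
#' @return an object of class `species_spec`.
#' @seealso [solution_spec()]
#' @export
species_spec <- function(name, molality, valence = 0L, molar_mass = 100,
                         dielectric_increment = 0,
                         partial_molar_volume = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(molality) || !is.finite(molality) || molality < 0) {
    stop("`molality` must be finite and >= 0", call. = FALSE)
  }
  .check_positive(molar_mass, "molar_mass")
  stopifnot(valence == round(valence))
  structure(
    list(
      name = name, molality = as.numeric(molality),
      valence = as.integer(valence), molar_mass = as.numeric(molar_mass),
      dielectric_increment = as.numeric(dielectric_increment),
      partial_molar_volume = as.numeric(partial_molar_volume)
    ),
    class = "species_spec"
  )
}

#' Specify a solution
#'
#' Composition, temperature and base permittivity of an aqueous solution.
#' Charged species must be electroneutral overall; zwitterions (valence 0)
#' may be present at any concentration.
#'
#' @param species list of [species_spec()] objects.
#' @param temperature K, within 273-373 (range of the water density model).
#' @param base_relative_permittivity relative permittivity of the pure
#'   solvent; default 78.3 (water near 298 K).
#' @return an object of class `solution_spec`.
#' @examples
#' kcl_solution(0.01)
#' solution_spec(list(species_spec("proline", 0.9, 0L, 115.13)))
#' @export
solution_spec <- function(species = list(),
                          temperature = .default_temperature,
                          base_relative_permittivity = .default_eps_water) {
  stopifnot(is.list(species))
  if (length(species) && !all(vapply(species, inherits, TRUE, "species_spec"))) {
    stop("`species` must be a list of species_spec objects", call. = FALSE)
  }
  .check_positive(temperature, "temperature")
  if (temperature < 273 || temperature > 373) {
    stop("`temperature` must lie in [273, 373] K", call. = FALSE)
  }
  if (base_relative_permittivity <= 1) {
    stop("`base_relative_permittivity` must be > 1", call. = FALSE)
  }
  net <- sum(vapply(species, function(s) s$valence * s$molality, 0))
  if (abs(net) > 1e-12) {
    stop("solution is not electroneutral: sum(valence * molality) != 0",
         call. = FALSE)
  }
  structure(
    list(species = species, temperature = temperature,
         base_relative_permittivity = base_relative_permittivity),
    class = "solution_spec"
  )
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> T = %.2f K, eps_base = %.1f\n",
              x$temperature, x$base_relative_permittivity))
  for (s in x$species) {
    cat(sprintf("  %-10s %.4g m  z = %+d\n", s$name, s$molality, s$valence))
  }
  invisible(x)
}

#' Convenience constructors for common solutions
#'
#' `kcl_solution()` builds a KCl solution (fully dissociated K+ and Cl-);
#' `proline_solution()` a zwitterionic proline solution with optional added
#' KCl, matching the compositions studied by SFB.
#'
#' @param molality_kcl,molality_pro mol per kg water.
#' @param temperature K.
#' @param proline_dielectric_increment per mol/L (default 0; the package does
#'   not guess an increment).
#' @param proline_partial_molar_volume cm^3/mol (default `NA`).
#' @return a [solution_spec()].
#' @export
kcl_solution <- function(molality_kcl, temperature = .default_temperature) {
  solution_spec(
    list(
      species_spec("K+", molality_kcl, +1L, 39.098),
      species_spec("Cl-", molality_kcl, -1L, 35.453)
    ),
    temperature = temperature
  )
}

#' @rdname kcl_solution
#' @export
proline_solution <- function(molality_pro, molality_kcl = 0,
                             temperature = .default_temperature,
                             proline_dielectric_increment = 0,
                             proline_partial_molar_volume = NA_real_) {
  sp <- list(
    species_spec("proline", molality_pro, 0L, 115.13,
                 dielectric_increment = proline_dielectric_increment,
                 partial_molar_volume = proline_partial_molar_volume)
  )
  if (molality_kcl > 0) {
    sp <- c(sp, list(
      species_spec("K+", molality_kcl, +1L, 39.098),
      species_spec("Cl-", molality_kcl, -1L, 35.453)
    ))
  }
  solution_spec(sp, temperature = temperature)
}

#' Convert molal composition to molar concentrations
#'
#' Default volume model: one kg of water occupies `1/rho_w(T)` litres; species
#' with a `partial_molar_volume` additionally contribute
#' `molality * V_bar / 1000` litres to the solution volume. With all partial
#' molar volumes `NA` this reduces to `c_M = molality * rho_w(T)`.
#'
#' @param spec a [solution_spec()].
#' @return named numeric vector of concentrations in mol/L, one per species.
#' @examples
#' molal_to_molar(kcl_solution(0.01))  # ~0.00997 M each ion at 298.15 K
#' @export
molal_to_molar <- function(spec) {
  stopifnot(inherits(spec, "solution_spec"))
  if (!length(spec$species)) return(numeric(0))
  vol <- 1 / water_density(spec$temperature)  # L per kg water
  for (s in spec$species) {
    if (is.finite(s$partial_molar_volume)) {
      vol <- vol + s$molality * s$partial_molar_volume / 1000
    }
  }
  conc <- vapply(spec$species, function(s) s$molality / vol, 0)
  names(conc) <- vapply(spec$species, `[[`, "", "name")
  conc
}

#' Ionic strength of a solution
#'
#' `I = 1/2 * sum(c_i z_i^2)` over molar concentrations; zwitterions
#' (valence 0) contribute nothing.
#'
#' @param spec a [solution_spec()].
#' @return ionic strength in mol/L.
#' @export
ionic_strength <- function(spec) {
  stopifnot(inherits(spec, "solution_spec"))
  conc <- molal_to_molar(spec)
  z <- vapply(spec$species, `[[`, 0L, "valence")
  if (!length(conc)) return(0)
  0.5 * sum(conc * z^2)
}

#' Relative permittivity of a solution
#'
#' Linear dielectric-increment model:
#' `eps = eps_base + sum(delta_i * c_i)` with `c_i` in mol/L.
#'
#' @param spec a [solution_spec()].
#' @return dimensionless relative permittivity (> 1).
#' @export
relative_permittivity <- function(spec) {
  stopifnot(inherits(spec, "solution_spec"))
  conc <- molal_to_molar(spec)
  delta <- vapply(spec$species, `[[`, 0, "dielectric_increment")
  eps <- spec$base_relative_permittivity + sum(delta * conc)
  if (eps <= 1) stop("relative permittivity <= 1; check dielectric increments",
                     call. = FALSE)
  eps
}

#' Debye screening length
#'
#' `kappa^-1 = sqrt(eps0 eps_e kB T / (2 NA e^2 I))` with the ionic strength
#' in mol/m^3. Pure water or zwitterion-only solutions carry no predicted
#' screening length: `debye_length()` then errors and the screening length
#' must be a free fit parameter downstream.
#'
#' @param spec a [solution_spec()].
#' @return Debye length in m.
#' @examples
#' debye_length(kcl_solution(0.01)) * 1e9  # ~3.04 nm
#' @export
debye_length <- function(spec) {
  stopifnot(inherits(spec, "solution_spec"))
  I <- ionic_strength(spec)
  if (I <= 0) {
    stop("no predicted screening length: ionic strength is zero ",
         "(zwitterion-only or pure water); treat kappa as a free fit parameter",
         call. = FALSE)
  }
  eps <- relative_permittivity(spec)
  .debye_length_raw(I, spec$temperature, eps)
}

.debye_length_raw <- function(I_molar, temperature, eps_e) {
  I_m3 <- I_molar * 1000
  sqrt(.const$eps0 * eps_e * .const$kB * temperature /
         (2 * .const$N_A * .const$e^2 * I_m3))
}

#' Ionic strength implied by a measured Debye length
#'
#' Exact algebraic inverse of [debye_length()]: the free-ion concentration of
#' a 1:1 electrolyte that would screen with the given decay length. Used to
#' infer the residual ion content of nominally salt-free solutions from the
#' fitted screening length.
#'
#' @param kappa_inv Debye length in m (> 0).
#' @param temperature K.
#' @param eps_e relative permittivity.
#' @return ionic strength in mol/L.
#' @examples
#' ionic_strength_from_kappa(40e-9)  # ~5.8e-5 M
#' @export
ionic_strength_from_kappa <- function(kappa_inv,
                                      temperature = .default_temperature,
                                      eps_e = .default_eps_water) {
  .check_positive(kappa_inv, "kappa_inv")
  .check_positive(temperature, "temperature")
  I_m3 <- .const$eps0 * eps_e * .const$kB * temperature /
    (2 * .const$N_A * .const$e^2 * kappa_inv^2)
  I_m3 / 1000
}

#' Thermal voltage and potentials in thermal units
#'
#' `thermal_voltage()` returns `kB T / e` (about 25.7 mV at 298.15 K);
#' `potential_in_thermal_units()` expresses a potential as a multiple of it.
#'
#' @param temperature K (> 0).
#' @param psi potential in V.
#' @return volts, respectively a dimensionless multiple of `kB T / e`.
#' @examples
#' potential_in_thermal_units(0.038)  # ~1.5
#' @export
thermal_voltage <- function(temperature = .default_temperature) {
  .check_positive(temperature, "temperature")
  .const$kB * temperature / .const$e
}

#' @rdname thermal_voltage
#' @export
potential_in_thermal_units <- function(psi,
                                       temperature = .default_temperature) {
  psi / thermal_voltage(temperature)
}

#' Ideal (van't Hoff) osmotic pressure
#'
#' `Pi = R T * sum(c_i)` over all dissolved species in mol/m^3: each ion
#' counts separately, a zwitterion counts once. Ideal-dilute estimate only;
#' activity corrections are out of scope.
#'
#' @param spec a [solution_spec()].
#' @return osmotic pressure in Pa.
#' @examples
#' osmotic_pressure_vant_hoff(proline_solution(0.90)) / 1e6  # ~2.2 MPa
#' @export
osmotic_pressure_vant_hoff <- function(spec) {
  stopifnot(inherits(spec, "solution_spec"))
  conc <- molal_to_molar(spec)
  if (!length(conc)) return(0)
  .const$Rgas * spec$temperature * sum(conc) * 1000
}
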
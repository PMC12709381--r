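# Physical constants (CODATA 2018, exact where the SI defines them)

.const <- list(
  e      = 1.602176634e-19,   # elementary charge, C
  kB     = 1.380649e-23,      # Boltzmann constant, J/K
  N_A    = 6.02214076e23,     # Avogadro constant, 1/mol
  eps0   = 8.8541878128e-12,  # vacuum permittivity, F/m
  Rgas   = 8.31446261815324   # molar gas constant, J/(mol K)
)

# 1 e/nm^2 in C/m^2 (e / 1e-18 m^2)
.const$e_per_nm2 <- .const$e * 1e18

#' Default relative permittivity of water
#'
#' Fixed at 78.3 (pure water near 298 K); the package deliberately uses a
#' constant rather than a temperature correlation, so that 2-significant-figure
#' Debye-length predictions are reproducible.
#' @keywords internal
.default_eps_water <- 78.3

#' Default measurement temperature (K)
#' @keywords internal
.default_temperature <- 298.15
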
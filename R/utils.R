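#' Round to significant figures with half-up tie-breaking
#'
#' Base [signif()] rounds half to even; reported parameter tables in this
#' field conventionally round half up (2 significant figures). `NA` passes
#' through; zero returns zero.
#'
#' @param x numeric vector.
#' @param digits number of significant figures (default 2).
#' @return numeric vector rounded to `digits` significant figures.
#' @examples
#' signif_half_up(0.125, 2)  # 0.13, where signif() gives 0.12
#' @export
signif_half_up <- function(x, digits = 2) {
  stopifnot(digits >= 1)
  out <- x
  idx <- which(is.finite(x) & x != 0)
  if (length(idx)) {
    v <- x[idx]
    mag <- floor(log10(abs(v)))
    s <- 10^(digits - 1 - mag)
    # nudge by a few ulp so values stored as 0.1249999... from decimal
    # literals like 0.125 still round half-up
    out[idx] <- sign(v) * floor(abs(v) * s + 0.5 + 1e-9) / s
  }
  out
}

#' Density of pure water
#'
#' Kell (1975) correlation for air-free water at atmospheric pressure,
#' valid 0-100 degrees C. Used by the default molality-to-molarity volume
#' model.
#'
#' @param temperature temperature in K.
#' @return density in kg/L.
#' @examples
#' water_density(298.15)  # ~0.99705 kg/L
#' @export
water_density <- function(temperature) {
  stopifnot(all(temperature >= 273), all(temperature <= 373))
  t <- temperature - 273.15
  num <- 999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
    46.170461e-6 * t^3 + 105.56302e-9 * t^4 - 280.54253e-12 * t^5
  (num / (1 + 16.879850e-3 * t)) / 1000
}

# internal: scalar positivity check with a clear message
.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

# internal: format numbers at full interchange precision (9 significant digits)
.fmt9 <- function(x) formatC(x, digits = 9, format = "g")
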
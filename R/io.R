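#' Read and write force-curve files
#'
#' Curve files are plain CSV with `#`-prefixed header lines declaring the
#' instrument metadata and, mandatorily, the signal units
#' (`signal_kind: W_mJ_per_m2` or `F_over_R_mN_per_m`), followed by a
#' `separation_nm,signal` column header and the data. Values are written at
#' 9 significant digits, so a write/read roundtrip is lossless at that
#' precision. Force-over-radius signals are converted to energy per unit
#' area on read through the Derjaguin relation `W = (F/R) / (2 pi)`, using
#' the radius declared in the header; the conversion is recorded in the
#' returned object.
#'
#' @param path file path.
#' @param curve a [force_curve()].
#' @param signal_kind units to write: `"W_mJ_per_m2"` (default) or
#'   `"F_over_R_mN_per_m"`.
#' @return `read_curve()` returns a [force_curve()] (signal always in J/m^2
#'   internally); `write_curve()` returns `path` invisibly.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx))) {
    stop("header lines ('#') must precede the data", call. = FALSE)
  }
  meta <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  if (is.null(meta$signal_kind)) {
    stop(sprintf("%s: missing units declaration ('# signal_kind: ...') in ",
                 path), "header (lines 1-", max(c(hdr_idx, 1)), ")",
         call. = FALSE)
  }
  if (!meta$signal_kind %in% c("W_mJ_per_m2", "F_over_R_mN_per_m")) {
    stop("unknown signal_kind: ", meta$signal_kind, call. = FALSE)
  }
  if (is.null(meta$direction) ||
      !meta$direction %in% c("approach", "retract")) {
    stop("header must declare 'direction: approach|retract'", call. = FALSE)
  }
  body <- lines[-hdr_idx]
  if (!length(body) || !grepl("^separation_nm\\s*,", body[1])) {
    stop("expected column header 'separation_nm,signal'", call. = FALSE)
  }
  data_lines <- body[-1]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop(sprintf("%s: malformed data line %d (expected 2 columns, got %d)",
                 path, length(hdr_idx) + 1 + bad, nf[bad]), call. = FALSE)
  }
  sep_nm <- as.numeric(vapply(fields, `[[`, "", 1))
  sig <- as.numeric(vapply(fields, `[[`, "", 2))
  if (any(is.na(sep_nm)) || any(is.na(sig))) {
    stop("non-numeric values in data block", call. = FALSE)
  }
  d <- diff(sep_nm)
  if (meta$direction == "approach" && any(d > 0) ||
      meta$direction == "retract" && any(d < 0)) {
    stop("separation not monotone for declared direction", call. = FALSE)
  }
  num <- function(key, default) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  inst <- instrument_spec(
    radius = num("radius_m", 10e-3),
    spring_constant = num("spring_constant_N_per_m", 150),
    sampling_step = num("sampling_step_m", 0.05e-9),
    noise_sigma = num("noise_sigma_J_per_m2", 0),
    seed = if (is.null(meta$seed) || meta$seed == "NA") NULL else
      as.integer(meta$seed)
  )
  W <- if (meta$signal_kind == "W_mJ_per_m2") sig * 1e-3 else
    sig * 1e-3 / (2 * pi)
  out <- force_curve(sep_nm * 1e-9, W, meta$direction, inst,
                     ground_truth_id = meta$solution_id)
  attr(out, "converted_from") <- meta$signal_kind
  out
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path, signal_kind = "W_mJ_per_m2") {
  stopifnot(inherits(curve, "force_curve"))
  signal_kind <- match.arg(signal_kind, c("W_mJ_per_m2", "F_over_R_mN_per_m"))
  inst <- curve$instrument
  sig <- switch(signal_kind,
    W_mJ_per_m2 = curve$signal * 1e3,
    F_over_R_mN_per_m = curve$signal * 2 * pi * 1e3)
  hdr <- c(
    "# dlvoreg curve v1",
    paste0("# direction: ", curve$direction),
    paste0("# signal_kind: ", signal_kind),
    paste0("# radius_m: ", .fmt9(inst$radius)),
    paste0("# spring_constant_N_per_m: ", .fmt9(inst$spring_constant)),
    paste0("# sampling_step_m: ", .fmt9(inst$sampling_step)),
    paste0("# noise_sigma_J_per_m2: ", .fmt9(inst$noise_sigma)),
    paste0("# seed: ", if (is.null(inst$seed)) "NA" else inst$seed),
    if (!is.null(curve$ground_truth_id)) {
      paste0("# solution_id: ", curve$ground_truth_id)
    }
  )
  lines <- c(hdr, "separation_nm,signal",
             paste(.fmt9(curve$separation * 1e9), .fmt9(sig), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a solution specification
#'
#' Solutions round-trip through a YAML file with fixed units: molality in
#' mol/kg water, temperature in K, dielectric increments per mol/L, partial
#' molar volumes in cm^3/mol.
#'
#' @param spec a [solution_spec()].
#' @param path file path.
#' @return `read_solution_spec()` returns a [solution_spec()];
#'   `write_solution_spec()` returns `path` invisibly.
#' @export
write_solution_spec <- function(spec, path) {
  stopifnot(inherits(spec, "solution_spec"))
  obj <- list(
    temperature_K = spec$temperature,
    base_relative_permittivity = spec$base_relative_permittivity,
    species = lapply(spec$species, function(s) {
      list(name = s$name, molality_mol_per_kg = s$molality,
           valence = s$valence, molar_mass_g_per_mol = s$molar_mass,
           dielectric_increment_per_M = s$dielectric_increment,
           partial_molar_volume_cm3_per_mol =
             if (is.finite(s$partial_molar_volume)) s$partial_molar_volume
             else NULL)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_solution_spec
#' @export
read_solution_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$temperature_K)) {
    stop("solution file must declare temperature_K", call. = FALSE)
  }
  species <- lapply(obj$species, function(s) {
    species_spec(
      name = s$name, molality = s$molality_mol_per_kg,
      valence = s$valence %||% 0L,
      molar_mass = s$molar_mass_g_per_mol %||% 100,
      dielectric_increment = s$dielectric_increment_per_M %||% 0,
      partial_molar_volume = s$partial_molar_volume_cm3_per_mol %||% NA_real_
    )
  })
  solution_spec(species, temperature = obj$temperature_K,
                base_relative_permittivity =
                  obj$base_relative_permittivity %||% .default_eps_water)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
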
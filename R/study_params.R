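#' Reference DLVO fit parameters for proline/KCl solutions
#'
#' Published DLVO fit parameters for SFB measurements between mica surfaces
#' across aqueous proline and KCl solutions: effective surface potential,
#' fitted Debye screening length, charge regulation parameter (with 1-sigma
#' uncertainties) and, where salt is present, the screening length predicted
#' from the 1:1 electrolyte concentration. These parameter sets drive the
#' synthetic-data generator as ground truths and anchor the recovery tests.
#'
#' @return a tibble with one row per solution: `solution_id`,
#'   `c_pro_molal`, `c_kcl_molal`, `psi_eff_mV` (+`_sd`), `kappa_inv_nm`
#'   (+`_sd`), `p` (+`_sd`), `kappa_pred_nm` (`NA` for salt-free solutions,
#'   where no screening length can be predicted).
#' @examples
#' proline_study_params()
#' @export
proline_study_params <- function() {
  tibble::tibble(
    solution_id   = c("water", "pro007", "pro035", "pro090",
                      "pro046_kcl001", "kcl001"),
    c_pro_molal   = c(0, 0.07, 0.35, 0.90, 0.46, 0),
    c_kcl_molal   = c(0, 0, 0, 0, 0.01, 0.01),
    psi_eff_mV    = c(38, 63, 55, 49, 49, 29),
    psi_eff_sd_mV = c(14, 5, 2, 2, 3, 1),
    kappa_inv_nm  = c(265, 40, 34, 30, 3.0, 3.8),
    kappa_inv_sd_nm = c(21, 2, 7, 5, 0.2, 0.8),
    p             = c(0.88, 0.90, 0.92, 0.92, 0.61, 1.0),
    p_sd          = c(0.10, 0.03, 0.02, 0.03, 0.08, 0.0),
    kappa_pred_nm = c(NA, NA, NA, NA, 3.34, 3.1)
  )
}

#' Ground-truth DLVO parameters for a reference solution
#'
#' Convenience lookup turning a row of [proline_study_params()] into a
#' [dlvo_params()] object.
#'
#' @param solution_id one of the ids in [proline_study_params()].
#' @param hamaker Hamaker constant in J (default 2.2e-20).
#' @return a [dlvo_params()].
#' @export
study_dlvo_params <- function(solution_id, hamaker = 2.2e-20) {
  tab <- proline_study_params()
  row <- tab[tab$solution_id == solution_id, ]
  if (nrow(row) != 1) {
    stop("unknown solution_id; see proline_study_params()", call. = FALSE)
  }
  dlvo_params(psi_eff = row$psi_eff_mV * 1e-3,
              kappa = 1 / (row$kappa_inv_nm * 1e-9),
              p = row$p, hamaker = hamaker)
}
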
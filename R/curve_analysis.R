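#' Fit configuration
#'
#' Controls the windowed nonlinear least-squares fit of the charge-regulated
#' DLVO model to a force curve.
#'
#' @param window `c(D_min, D_max)` in m; the fit uses samples inside it and
#'   must contain at least 10 of them. Choose the lower edge above the
#'   jump-in/structural region.
#' @param free character subset of
#'   `c("psi_eff", "kappa", "p", "hamaker", "offset")`; at least one.
#' @param fixed named list of values for the non-free parameters. Defaults:
#'   `hamaker = 2.2e-20` J, `offset = 0` m; `psi_eff`, `kappa`, `p` have no
#'   default and must be fixed explicitly when not free.
#' @param weighting `"uniform"`, or a numeric vector of per-point weights
#'   (applied as `sqrt(w) * residual`, i.e. inverse-variance weights).
#' @param bootstrap_replicates residual-bootstrap replicates for
#'   uncertainties (0 = Jacobian covariance only).
#' @param seed integer seed for the bootstrap.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(window, free = c("psi_eff", "kappa", "p"),
                       fixed = list(), weighting = "uniform",
                       bootstrap_replicates = 0, seed = NULL) {
  stopifnot(length(window) == 2, window[1] < window[2])
  all_par <- c("psi_eff", "kappa", "p", "hamaker", "offset")
  free <- match.arg(free, all_par, several.ok = TRUE)
  if (!length(free)) stop("at least one free parameter", call. = FALSE)
  defaults <- list(hamaker = 2.2e-20, offset = 0)
  fixed <- utils::modifyList(defaults, fixed)
  missing <- setdiff(setdiff(all_par, free), names(fixed))
  if (length(missing)) {
    stop("fixed values required for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(window = window, free = free, fixed = fixed, weighting = weighting,
         bootstrap_replicates = bootstrap_replicates,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "fit_config"
  )
}

# transforms keeping psi/kappa/hamaker positive and p inside [0, 1]
# (p = sin^2(theta) reaches both boundaries at finite theta)
.to_trans <- function(name, value) {
  switch(name,
    psi_eff = log(value), kappa = log(value), hamaker = log(value),
    p = asin(sqrt(min(max(value, 0), 1))), offset = value)
}
.from_trans <- function(name, value) {
  switch(name,
    psi_eff = exp(value), kappa = exp(value), hamaker = exp(value),
    p = sin(value)^2, offset = value)
}
# |d(natural)/d(transformed)| at the optimum, for the delta method
.dnat_dtrans <- function(name, natural, trans) {
  switch(name,
    psi_eff = natural, kappa = natural, hamaker = natural,
    p = abs(sin(2 * trans)), offset = 1)
}

# internal: evaluate the model at natural parameters
.dlvo_model_W <- function(D, pars, eps_e) {
  Ds <- D + pars[["offset"]]
  u <- exp(-pars[["kappa"]] * Ds)
  denom <- 1 + (1 - 2 * pars[["p"]]) * u
  denom[denom < 1e-6] <- NA_real_
  -pars[["hamaker"]] / (12 * pi * Ds^2) +
    2 * .const$eps0 * eps_e * pars[["kappa"]] * pars[["psi_eff"]]^2 * u / denom
}

# internal: one nls.lm run from a transformed start; returns fit + deviance
.lm_run <- function(start_t, free, fixed, D, W, wts, eps_e) {
  resid_fn <- function(theta) {
    pars <- fixed
    for (i in seq_along(free)) pars[[free[i]]] <- .from_trans(free[i], theta[i])
    r <- sqrt(wts) * (.dlvo_model_W(D, pars, eps_e) - W)
    r[!is.finite(r)] <- 1e6  # divergence guard: push the optimizer away
    r
  }
  fit <- minpack.lm::nls.lm(par = start_t, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  list(fit = fit, deviance = fit$deviance, resid_fn = resid_fn)
}

# forward-difference Jacobian of the residual function
.num_jacobian <- function(fn, theta) {
  r0 <- fn(theta)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- max(1e-7, 1e-7 * abs(theta[j]))
    tp <- theta
    tp[j] <- tp[j] + h
    J[, j] <- (fn(tp) - r0) / h
  }
  J
}

#' Fit the charge-regulated DLVO model to a force curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of the total
#' interaction energy to the windowed samples. Positivity of `psi_eff`,
#' `kappa`, `hamaker` is enforced by log-parameterization and `p` is kept in
#' `[0, 1]` by the smooth map `p = sin^2(theta)` (which attains both
#' boundaries). When `p` is free the optimizer is multi-started from
#' `p = 0.1, 0.5, 0.9` and the lowest-residual solution kept (ties broken by
#' smaller `p`). Uncertainties come from the Jacobian covariance, or from a
#' seeded residual bootstrap when `bootstrap_replicates > 0`. `p` estimates
#' within 1e-3 of a boundary are reported at the boundary.
#'
#' @param curve a [force_curve()].
#' @param spec optional [solution_spec()]; supplies the permittivity and,
#'   when its ionic strength is positive, the starting value for `kappa`.
#' @param config a [fit_config()].
#' @return object of class `fit_result`: `params` ([dlvo_params()]),
#'   `offset` (m), `uncertainties` (named, 1-sigma, natural units, free
#'   parameters only; includes `kappa_inv` alongside `kappa`),
#'   `residual_rms` (J/m^2), `window`, `n_points`, `converged`.
#' @export
fit_dlvo <- function(curve, spec = NULL, config) {
  stopifnot(inherits(curve, "force_curve"), inherits(config, "fit_config"))
  eps_e <- if (is.null(spec)) .default_eps_water else
    relative_permittivity(spec)
  sel <- curve$separation >= config$window[1] &
    curve$separation <= config$window[2]
  if (sum(sel) < 10) {
    stop("fit window contains fewer than 10 samples", call. = FALSE)
  }
  D <- curve$separation[sel]
  W <- curve$signal[sel]
  wts <- if (identical(config$weighting, "uniform")) rep(1, length(D)) else {
    stopifnot(is.numeric(config$weighting))
    config$weighting[sel]
  }

  # starting values --------------------------------------------------------
  kappa0 <- NULL
  if (!is.null(spec)) {
    kappa0 <- tryCatch(1 / debye_length(spec), error = function(e) NULL)
  }
  if (is.null(kappa0)) {
    # decay-rate estimate from the outer, positive part of the window
    pos <- W > 0 & D > stats::median(D)
    kappa0 <- if (sum(pos) >= 3) {
      max(-stats::coef(stats::lm(log(W[pos]) ~ D[pos]))[[2]],
          0.2 / diff(range(D)))
    } else 3 / diff(range(D))
  }
  Wref <- max(abs(W[W > 0]), 1e-9)
  Dref <- D[which.max(abs(W))]
  psi0 <- sqrt(Wref * exp(min(kappa0 * Dref, 50)) /
                 (2 * .const$eps0 * eps_e * kappa0))
  psi0 <- min(max(psi0, 5e-3), 0.3)
  start_nat <- list(psi_eff = psi0, kappa = kappa0, p = 0.5,
                    hamaker = 2.2e-20, offset = 0)
  for (nm in names(config$fixed)) start_nat[[nm]] <- config$fixed[[nm]]

  p_starts <- if ("p" %in% config$free) c(0.1, 0.5, 0.9) else NA
  best <- NULL
  for (p0 in p_starts) {
    sn <- start_nat
    if (!is.na(p0)) sn$p <- p0
    theta0 <- vapply(config$free, function(nm) .to_trans(nm, sn[[nm]]), 0)
    run <- .lm_run(theta0, config$free, config$fixed, D, W, wts, eps_e)
    run$p_start <- p0
    if (is.null(best) || run$deviance < best$deviance * (1 - 1e-10) ||
        (abs(run$deviance - best$deviance) <= best$deviance * 1e-10 &&
         .final_p(run, config) < .final_p(best, config))) {
      best <- run
    }
  }

  theta <- best$fit$par
  pars <- config$fixed
  for (i in seq_along(config$free)) {
    pars[[config$free[i]]] <- .from_trans(config$free[i], theta[i])
  }
  pars <- lapply(pars, unname)
  # boundary reporting for p
  if (pars$p > 1 - 1e-3) pars$p <- 1
  if (pars$p < 1e-3) pars$p <- 0

  n <- length(D)
  k <- length(theta)
  sigma2 <- best$deviance / max(n - k, 1)
  J <- .num_jacobian(best$resid_fn, theta)
  cov_t <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, k, k)
  })
  unc <- numeric(0)
  for (i in seq_along(config$free)) {
    nm <- config$free[i]
    sd_t <- sqrt(abs(cov_t[i, i]))
    unc[nm] <- .dnat_dtrans(nm, pars[[nm]], theta[i]) * sd_t
    if (nm == "kappa") unc["kappa_inv"] <- sd_t / pars$kappa
  }

  if (config$bootstrap_replicates > 0) {
    unc <- .bootstrap_unc(best, theta, config, D, W, wts, eps_e, pars)
  }

  structure(
    list(
      params = dlvo_params(pars$psi_eff, pars$kappa, pars$p, pars$hamaker),
      offset = pars$offset,
      uncertainties = unc,
      residual_rms = sqrt(mean((best$resid_fn(theta))^2)),
      window = config$window, n_points = n,
      converged = best$fit$info %in% 1:4,
      deviance = best$deviance
    ),
    class = "fit_result"
  )
}

.final_p <- function(run, config) {
  i <- match("p", config$free)
  if (is.na(i)) return(NA_real_)
  .from_trans("p", run$fit$par[i])
}

# residual bootstrap: refit to fitted + resampled residuals, sd over replicates
.bootstrap_unc <- function(best, theta, config, D, W, wts, eps_e, pars) {
  B <- config$bootstrap_replicates
  res <- best$resid_fn(theta) / sqrt(wts)
  fitted <- W + res  # model values at the optimum
  draws <- .with_seed(config$seed, {
    out <- matrix(NA_real_, B, length(theta) + 1)
    for (b in seq_len(B)) {
      Wb <- fitted - sample(res, replace = TRUE)
      run <- .lm_run(theta, config$free, config$fixed, D, Wb, wts, eps_e)
      nat <- vapply(seq_along(config$free), function(i) {
        .from_trans(config$free[i], run$fit$par[i])
      }, 0)
      ki <- match("kappa", config$free)
      out[b, ] <- c(nat, if (is.na(ki)) NA_real_ else 1 / nat[ki])
    }
    out
  })
  unc <- apply(draws, 2, stats::sd)
  names(unc) <- c(config$free, "kappa_inv")
  if (!"kappa" %in% config$free) unc <- unc[config$free]
  unc
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<fit_result> psi_eff = %.3g mV, kappa^-1 = %.3g nm, p = %.3g (%s)\n",
    p$psi_eff * 1e3, 1e9 / p$kappa, p$p,
    if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  residual RMS %.3g mJ/m^2 over %d points in [%.3g, %.3g] nm\n",
              x$residual_rms * 1e3, x$n_points,
              x$window[1] * 1e9, x$window[2] * 1e9))
  invisible(x)
}

#' Detect spring-instability jumps in a force curve
#'
#' Flags separation changes larger than `threshold` (default 3x the median
#' absolute separation step), the signature of a mechanical instability.
#' Near a fold the spring compliance diverges, so the samples immediately
#' before a jump already move super-threshold; runs of consecutive flagged
#' samples are therefore merged into one jump event, located at the largest
#' single-sample change within the run. Direction-aware: inward jumps move
#' to smaller separation.
#'
#' @param curve a [force_curve()] with at least 3 samples.
#' @param threshold jump threshold in m; the default is 3x the drive step
#'   (taken from the recorded drive positions or the instrument sampling
#'   step, falling back to the median recorded separation step).
#' @return tibble with columns `index`, `D_before`, `D_after`, `height`
#'   (all m) and `inward` (logical); zero rows when the curve is continuous.
#' @export
detect_jumps <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "force_curve"), length(curve$separation) >= 3)
  dD <- diff(curve$separation)
  if (is.null(threshold)) {
    drive_step <- if (!is.null(curve$drive)) {
      stats::median(abs(diff(curve$drive)))
    } else {
      # no drive record: estimate the regular sampling step from the far
      # field, where the branch is compliant-free (near contact the
      # recorded step collapses during wall creep)
      far <- curve$separation[-1] > stats::median(curve$separation)
      if (any(far)) stats::median(abs(dD[far])) else
        stats::median(abs(dD))
    }
    threshold <- 3 * drive_step
  }
  idx <- which(abs(dD) > threshold)
  if (!length(idx)) {
    return(tibble::tibble(index = integer(0), D_before = numeric(0),
                          D_after = numeric(0), height = numeric(0),
                          inward = logical(0)))
  }
  run <- cumsum(c(1, diff(idx) > 1))
  picked <- vapply(split(idx, run), function(ii) ii[which.max(abs(dD[ii]))],
                   0L)
  tibble::tibble(
    index = picked,
    D_before = curve$separation[picked],
    D_after = curve$separation[picked + 1],
    height = abs(dD[picked]),
    inward = dD[picked] < 0
  )
}

#' Squeeze-out step heights
#'
#' Layer-by-layer squeeze-out step sizes from the near-contact jump cascade
#' of an approach curve. Before each instability the curve climbs the steep
#' repulsive wall of the current molecular layer, so the recorded pre-jump
#' (fold) positions mark the layer walls; the spacings between successive
#' fold positions therefore measure the layer period directly, and -- unlike
#' the raw jump drops -- are not biased low by where the landing happens to
#' sit on the next wall. Spacings larger than ~1.5x the smallest one are
#' discarded as multi-layer (skipped) events, as is anything above
#' `max_step` (which removes the long DLVO jump-in). When the cascade holds
#' a single jump only, its drop height is returned as the best available
#' estimate.
#'
#' @param curve an approach [force_curve()].
#' @param near_contact only jumps starting below this separation count
#'   (default 6 nm).
#' @param max_step upper bound on a single-layer step (default 1.2 nm).
#' @param threshold passed to [detect_jumps()].
#' @return numeric vector of step heights in m (possibly empty).
#' @export
step_heights <- function(curve, near_contact = 6e-9, max_step = 1.2e-9,
                         threshold = NULL) {
  j <- detect_jumps(curve, threshold)
  j <- j[j$inward & j$D_before <= near_contact, ]
  if (nrow(j) >= 2) {
    spacing <- -diff(sort(j$D_before, decreasing = TRUE))
    spacing <- spacing[spacing <= max_step]
    if (length(spacing)) {
      return(spacing[spacing <= 1.5 * min(spacing)])
    }
  }
  # single-jump cascade: fall back to the jump drop itself
  j <- j[j$height <= max_step, ]
  j$height
}

#' Adhesion (pull-off) energy from a retraction curve
#'
#' The minimum interaction free energy recorded at the last stable point
#' before the outward jump of a retraction curve. Returns `NA` (with a
#' `reason` attribute) when no jump-out is present -- a purely repulsive
#' retraction has *no* adhesion, which is distinct from zero adhesion.
#'
#' @param retraction a retraction [force_curve()].
#' @param threshold passed to [detect_jumps()].
#' @return adhesion energy in J/m^2 (<= 0), or `NA`.
#' @export
adhesion_energy <- function(retraction, threshold = NULL) {
  stopifnot(inherits(retraction, "force_curve"))
  if (retraction$direction != "retract") {
    stop("adhesion is read from a retraction curve", call. = FALSE)
  }
  j <- detect_jumps(retraction, threshold)
  j <- j[!j$inward, ]
  if (!nrow(j)) {
    return(structure(NA_real_, reason = "no jump-out"))
  }
  i <- j$index[which.max(j$height)]
  val <- retraction$signal[i]
  if (val > 0) {
    return(structure(NA_real_, reason = "no adhesive minimum before jump-out"))
  }
  val
}

#' Default fit window for a simulated or measured approach curve
#'
#' Implements the windowing advice: start one layer thickness beyond the
#' first (outermost) inward jump -- past the jump-in/structural region --
#' and end where the signal magnitude falls below three times the noise
#' level (or at the outermost sample when noiseless).
#'
#' @param curve an approach [force_curve()].
#' @param layer_thickness margin added above the first jump, m.
#' @param noise_sigma noise level in J/m^2; default taken from the curve's
#'   instrument.
#' @return `c(D_min, D_max)` in m.
#' @export
auto_fit_window <- function(curve, layer_thickness = 0.5e-9,
                            noise_sigma = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(noise_sigma)) noise_sigma <- curve$instrument$noise_sigma
  j <- detect_jumps(curve)
  j <- j[j$inward, ]
  lo <- if (nrow(j)) max(j$D_before) + layer_thickness else
    min(curve$separation)
  hi <- max(curve$separation)
  if (noise_sigma > 0) {
    strong <- curve$separation[abs(curve$signal) >= 3 * noise_sigma]
    if (length(strong)) hi <- min(hi, max(strong))
  }
  c(lo, hi)
}

#' Tabulate fit results in reporting style
#'
#' One row per solution with compositions, fitted effective surface
#' potential, screening length and regulation parameter (each with its
#' 1-sigma uncertainty) and the predicted screening length where the
#' solution contains salt. All values rounded to 2 significant figures,
#' half-up; the predicted column is blank (`NA`) for solutions with zero
#' ionic strength.
#'
#' @param results list of `fit_result` objects.
#' @param specs list of [solution_spec()] objects, parallel to `results`.
#' @return a tibble; units are embedded in the column names.
#' @export
fit_report <- function(results, specs) {
  stopifnot(length(results) >= 1, length(results) == length(specs))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    s <- specs[[i]]
    stopifnot(inherits(r, "fit_result"), inherits(s, "solution_spec"))
    mol <- vapply(s$species, `[[`, 0, "molality")
    nms <- vapply(s$species, `[[`, "", "name")
    c_pro <- sum(mol[grepl("pro", nms, ignore.case = TRUE)])
    c_kcl <- sum(mol[nms == "K+"])
    kp <- tryCatch(debye_length(s) * 1e9, error = function(e) NA_real_)
    u <- r$uncertainties
    gv <- function(nm) if (nm %in% names(u)) u[[nm]] else NA_real_
    tibble::tibble(
      c_pro_molal = c_pro,
      c_kcl_molal = c_kcl,
      psi_eff_mV = signif_half_up(r$params$psi_eff * 1e3),
      psi_eff_sd_mV = signif_half_up(gv("psi_eff") * 1e3),
      kappa_inv_nm = signif_half_up(1e9 / r$params$kappa),
      kappa_inv_sd_nm = signif_half_up(gv("kappa_inv") * 1e9),
      p = signif_half_up(r$params$p),
      p_sd = signif_half_up(gv("p")),
      kappa_pred_nm = signif_half_up(kp),
      converged = r$converged
    )
  })
  do.call(rbind, rows)
}
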
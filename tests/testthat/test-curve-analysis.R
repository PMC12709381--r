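test_that("noiseless fits recover generating parameters exactly", {
  tab <- proline_study_params()
  for (i in seq_len(nrow(tab))) {
    pars <- study_dlvo_params(tab$solution_id[i])
    ki <- tab$kappa_inv_nm[i]
    cur <- grid_curve(pars, c(max(1.5, 0.08 * ki), 4 * ki))
    cfg <- fit_config(range(cur$separation),
                      free = c("psi_eff", "kappa", "p"))
    f <- fit_dlvo(cur, config = cfg)
    expect_true(f$converged)
    expect_rel(f$params$psi_eff, pars$psi_eff, 1e-3)
    expect_rel(f$params$kappa, pars$kappa, 1e-3)
    expect_lt(abs(f$params$p - pars$p), 1e-3)
  }
})

test_that("free regulation parameter never fits worse than a fixed one", {
  pars <- study_dlvo_params("pro046_kcl001")
  cur <- grid_curve(pars, c(1.5, 25), sigma = 5e-6, seed = 3)
  win <- c(1.5e-9, 20e-9)
  free_fit <- fit_dlvo(cur, config = fit_config(win))
  fixed_fit <- fit_dlvo(cur, config = fit_config(
    win, free = c("psi_eff", "kappa"), fixed = list(p = 0.61)))
  expect_lte(free_fit$deviance, fixed_fit$deviance * (1 + 1e-12))
})

test_that("an injected distance offset is recovered when freed", {
  pars <- study_dlvo_params("pro046_kcl001")
  D <- seq(1.5, 25, length.out = 300) * 1e-9
  off <- 0.4e-9
  cur <- force_curve(rev(D) - off, rev(total_energy(D, pars)), "approach")
  f <- fit_dlvo(cur, config = fit_config(
    c(1e-9, 25e-9), free = c("psi_eff", "kappa", "p", "offset")))
  expect_equal(f$offset, off, tolerance = 1e-3 * off)
  expect_rel(f$params$psi_eff, pars$psi_eff, 1e-3)
})

test_that("fit window and input validation behave as specified", {
  pars <- study_dlvo_params("pro007")
  cur <- grid_curve(pars, c(5, 150))
  expect_error(fit_dlvo(cur, config = fit_config(c(200e-9, 300e-9))),
               "fewer than 10")
  expect_error(fit_config(c(5e-9, 1e-9)), "window")
  expect_error(fit_config(c(1e-9, 5e-9), free = character(0)))
  # fixing everything but psi works
  f <- fit_dlvo(cur, config = fit_config(
    range(cur$separation), free = "psi_eff",
    fixed = list(kappa = pars$kappa, p = pars$p)))
  expect_rel(f$params$psi_eff, pars$psi_eff, 1e-6)
})

test_that("jump detection is direction-aware and quiet on smooth curves", {
  # continuous monotone curve -> no jumps
  cur <- grid_curve(study_dlvo_params("pro007"), c(10, 100))
  expect_equal(nrow(detect_jumps(cur)), 0)

  # synthetic curve with one inserted discontinuity
  D <- c(seq(20, 10.2, by = -0.2), seq(5, 1, by = -0.2)) * 1e-9
  cur2 <- force_curve(D, rep(0, length(D)), "approach")
  j <- detect_jumps(cur2)
  expect_equal(nrow(j), 1)
  expect_true(j$inward)
  expect_equal(j$D_before, 10.2e-9)
  expect_equal(j$D_after, 5e-9)
})

test_that("squeeze-out step analysis recovers the injected layer thickness", {
  inst <- fast_instrument()
  for (d in c(0.2e-9, 0.5e-9, 1.0e-9)) {
    cur <- simulate_quasistatic(layered_truth(d), inst, "approach",
                                drive_from = 25e-9)
    s <- step_heights(cur)
    expect_gt(length(s), 0)
    expect_rel(mean(s), d, 0.1)
  }
  # no structural term -> no molecular steps (only the DLVO jump-in)
  bare <- simulate_quasistatic(ground_truth(study_dlvo_params("pro007")),
                               fast_instrument(0.05e-9), "approach",
                               drive_from = 30e-9)
  expect_length(step_heights(bare), 0)
})

test_that("adhesion analysis distinguishes no-adhesion from zero", {
  tr <- ground_truth(dlvo_params(50e-3, 1 / 10e-9, 0.3, hamaker = 0))
  ret <- simulate_quasistatic(tr, fast_instrument(0.1e-9), "retract",
                              drive_from = 5e-9, drive_to = 60e-9)
  a <- adhesion_energy(ret)
  expect_true(is.na(a))
  expect_match(attr(a, "reason"), "no jump-out")
  expect_error(adhesion_energy(grid_curve(tr$dlvo, c(5, 50))), "retraction")
})

test_that("residuals grow when the window reaches into the structural region", {
  cur <- simulate_quasistatic(layered_truth(), fast_instrument(), "approach",
                              drive_from = 25e-9)
  clean <- fit_dlvo(cur, config = fit_config(c(5e-9, 38e-9)))
  dirty <- fit_dlvo(cur, config = fit_config(c(1.2e-9, 38e-9)))
  expect_gt(dirty$residual_rms, clean$residual_rms)
})

test_that("auto window starts above the jump-in and honours the noise floor", {
  cur <- simulate_quasistatic(ground_truth(study_dlvo_params("pro007")),
                              fast_instrument(0.05e-9), "approach",
                              drive_from = 150e-9)
  w <- auto_fit_window(cur)
  j <- detect_jumps(cur)
  expect_gt(w[1], max(j$D_before[j$inward]))
  expect_equal(w[2], max(cur$separation))
  w2 <- auto_fit_window(cur, noise_sigma = 5e-6)
  expect_lt(w2[2], w[2])  # outer bound pulled in to the 3-sigma level
})

test_that("bootstrap and Jacobian uncertainties agree in magnitude", {
  pars <- study_dlvo_params("pro046_kcl001")
  cur <- grid_curve(pars, c(1.5, 25), sigma = 5e-6, seed = 8)
  win <- c(1.5e-9, 20e-9)
  fj <- fit_dlvo(cur, config = fit_config(win))
  fb <- fit_dlvo(cur, config = fit_config(win, bootstrap_replicates = 40,
                                          seed = 12))
  for (nm in c("psi_eff", "kappa_inv", "p")) {
    expect_gt(fb$uncertainties[[nm]], 0.3 * fj$uncertainties[[nm]])
    expect_lt(fb$uncertainties[[nm]], 3 * fj$uncertainties[[nm]])
  }
  # bootstrap is seeded: identical on repeat
  fb2 <- fit_dlvo(cur, config = fit_config(win, bootstrap_replicates = 40,
                                           seed = 12))
  expect_identical(fb$uncertainties, fb2$uncertainties)
})

test_that("fit report rounds to 2 significant figures with half-up ties", {
  expect_equal(signif_half_up(3.0427), 3.0)
  expect_equal(signif_half_up(0.125, 2), 0.13)
  expect_equal(signif_half_up(265.4), 270)
  expect_equal(signif_half_up(6e-5, 1), 6e-5)

  pars <- study_dlvo_params("pro046_kcl001")
  cur <- grid_curve(pars, c(1.5, 25), sigma = 5e-6, seed = 5)
  f <- fit_dlvo(cur, config = fit_config(c(1.5e-9, 20e-9)))
  rep <- fit_report(list(f, f),
                    list(proline_solution(0.46, 0.01),
                         proline_solution(0.90)))
  expect_equal(rep$c_pro_molal, c(0.46, 0.90))
  expect_equal(rep$kappa_pred_nm[1], 3.0)   # measured and predicted distinct
  expect_true(is.na(rep$kappa_pred_nm[2]))  # zwitterion-only: no prediction
  expect_equal(rep$psi_eff_mV[1], 49)
  expect_equal(rep$p[1], 0.61, tolerance = 0.05)
})
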
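test_that("structural energy has the declared shape", {
  st <- structural_force_spec(0.5e-9, 1e-3, 0.4e-9, hard_wall = 1e-9)
  off <- structural_force_spec(0.5e-9, 0, 0.4e-9, hard_wall = 1e-9)
  D <- seq(0.8, 4, by = 0.0005) * 1e-9
  expect_true(all(structural_energy(D, off) == 0))

  # minima of the oscillatory part are spaced by the layer thickness
  W <- structural_energy(D, st)
  i <- which(diff(sign(diff(W))) == 2) + 1
  i <- i[D[i] > 1.2e-9 & D[i] < 3.5e-9]
  expect_equal(diff(D[i]), rep(0.5e-9, length(i) - 1), tolerance = 1e-2)

  # wall keeps the energy finite and strongly repulsive below D0
  expect_true(all(is.finite(structural_energy(c(0.3, 0.5, 0.7) * 1e-9, st))))
  expect_gt(structural_energy(0.7e-9, st), 50e-3)
})

test_that("pure vdW approach jumps in at the spring-instability distance", {
  tr <- ground_truth(dlvo_params(1e-9, 1 / 40e-9, 0.5, hamaker = 2.2e-20))
  inst <- instrument_spec(sampling_step = 0.01e-9)
  cur <- simulate_quasistatic(tr, inst, "approach", drive_from = 12e-9)
  j <- detect_jumps(cur)
  j <- j[j$inward & j$height > 1e-9, ]
  expect_equal(nrow(j), 1)
  d_theory <- vdw_jump_in_distance(2.2e-20, 10e-3, 150)
  expect_equal(d_theory * 1e9, 7.878, tolerance = 1e-3)
  # fold position within the compliance-limited sampling resolution
  expect_rel(j$D_before, d_theory, 0.06)
  expect_lt(j$D_after, 0.6e-9)  # lands on the hard wall
})

test_that("purely repulsive monotone interactions record no jumps", {
  tr <- ground_truth(dlvo_params(50e-3, 1 / 10e-9, 0.3, hamaker = 0))
  cur <- simulate_quasistatic(tr, fast_instrument(0.05e-9), "approach",
                              drive_from = 60e-9, drive_to = -30e-9)
  expect_equal(nrow(detect_jumps(cur)), 0)
  # the recorded branch reproduces the input energy law exactly
  expect_equal(cur$signal, total_energy(cur$separation, tr$dlvo),
               tolerance = 1e-9)
})

test_that("no recorded sample violates the spring stability criterion", {
  tr <- layered_truth()
  cur <- simulate_quasistatic(tr, fast_instrument(), "approach",
                              drive_from = 25e-9)
  D <- cur$separation
  h <- 1e-13
  Fp <- (energy_to_force(truth_energy(D + h, tr), 10e-3) -
           energy_to_force(truth_energy(D - h, tr), 10e-3)) / (2 * h)
  expect_true(all(Fp < 150 * (1 + 1e-6)))
})

test_that("approach and retraction coincide where no instability intervenes", {
  tr <- ground_truth(dlvo_params(50e-3, 1 / 10e-9, 0.3, hamaker = 0))
  inst <- fast_instrument(0.05e-9)
  app <- simulate_quasistatic(tr, inst, "approach",
                              drive_from = 50e-9, drive_to = 10e-9)
  ret <- simulate_quasistatic(tr, inst, "retract",
                              drive_from = 10e-9, drive_to = 50e-9)
  wa <- approx(app$separation, app$signal, xout = ret$separation,
               rule = 1)$y
  keep <- !is.na(wa)
  expect_lt(max(abs(wa[keep] - ret$signal[keep]) /
                  pmax(abs(ret$signal[keep]), 1e-9)), 1e-6)
})

test_that("configured adhesion minimum is pinned and read back at pull-off", {
  tr <- ground_truth(study_dlvo_params("pro007"), adhesion_minimum = -0.5e-3)
  # the energy law itself is pinned to the configured minimum
  g <- seq(0.3, 6, by = 0.0005) * 1e-9
  expect_rel(min(truth_energy(g, tr)), -0.5e-3, 2e-3)

  ret <- simulate_quasistatic(tr, instrument_spec(sampling_step = 0.25e-9),
                              "retract", drive_from = 0, drive_to = 400e-9)
  adh <- adhesion_energy(ret)
  expect_rel(adh, -0.5e-3, 0.02)
  # jump-out releases to a separation where the force is negligible
  j <- detect_jumps(ret)
  j <- j[!j$inward, ]
  i_rel <- which.max(j$height)
  F_rel <- energy_to_force(truth_energy(j$D_after[i_rel], tr), 10e-3)
  expect_lt(abs(F_rel), 0.02 * abs(energy_to_force(adh, 10e-3)))
})

test_that("noise is seeded, reproducible and has the configured magnitude", {
  tr <- ground_truth(study_dlvo_params("pro007"))
  inst <- instrument_spec(sampling_step = 0.2e-9, noise_sigma = 5e-6,
                          seed = 11)
  a <- simulate_quasistatic(tr, inst, "approach",
                            drive_from = 150e-9, drive_to = 130e-9)
  b <- simulate_quasistatic(tr, inst, "approach",
                            drive_from = 150e-9, drive_to = 130e-9)
  expect_identical(a$signal, b$signal)

  # empirical per-point noise SD over 50 replicates within 10% of sigma
  base <- simulate_quasistatic(ground_truth(study_dlvo_params("pro007")),
                               instrument_spec(sampling_step = 0.2e-9),
                               "approach", drive_from = 150e-9,
                               drive_to = 130e-9)
  mat <- vapply(1:50, function(s) {
    simulate_quasistatic(tr, inst, "approach", drive_from = 150e-9,
                         drive_to = 130e-9, seed = s)$signal
  }, numeric(length(base$signal)))
  sds <- apply(mat - base$signal, 1, sd)
  expect_rel(mean(sds), 5e-6, 0.1)

  # noisy output without any seed is refused
  expect_error(instrument_spec(noise_sigma = 1e-6), "seed")
})

test_that("generate_dataset is deterministic and rejects duplicate paths", {
  tr <- ground_truth(study_dlvo_params("pro046_kcl001"))
  inst <- instrument_spec(sampling_step = 0.2e-9, noise_sigma = 5e-6,
                          seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(list(mix = tr), inst, 25e-9, replicates = 3,
                         base_seed = 4, out_dir = d1)
  m2 <- generate_dataset(list(mix = tr), inst, 25e-9, replicates = 3,
                         base_seed = 4, out_dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # same underlying curve, distinct noise realizations
  c1 <- read_curve(file.path(d1, "mix_approach_rep01.csv"))
  c2 <- read_curve(file.path(d1, "mix_approach_rep02.csv"))
  expect_identical(c1$separation, c2$separation)
  expect_false(identical(c1$signal, c2$signal))
  expect_equal(length(m1$curves), 3)
})
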
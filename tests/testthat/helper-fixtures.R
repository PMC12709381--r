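# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# a noisy (or noiseless) synthetic curve evaluated directly on a separation
# grid from the charge-regulated DLVO law -- the analytic counterpart of the
# mechanical simulator, used where spring mechanics are not under test
grid_curve <- function(params, d_nm, n = 300, sigma = 0, seed = NULL,
                       eps_e = 78.3) {
  D <- seq(d_nm[1], d_nm[2], length.out = n) * 1e-9
  W <- total_energy(D, params, eps_e)
  if (sigma > 0) {
    stopifnot(!is.null(seed))
    set.seed(seed)
    W <- W + rnorm(n, 0, sigma)
  }
  force_curve(rev(D), rev(W), "approach")
}

# the layered structural scenario: high-concentration proline DLVO
# parameters plus an oscillatory layering term of period `d`
layered_truth <- function(d = 0.5e-9, amplitude = 1e-3, decay = 0.4e-9,
                          hard_wall = 1.0e-9, base = "pro090") {
  ground_truth(
    study_dlvo_params(base),
    structural = structural_force_spec(d, amplitude, decay,
                                       hard_wall = hard_wall)
  )
}

fast_instrument <- function(step = 0.02e-9, ...) {
  instrument_spec(sampling_step = step, ...)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
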
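#' SFB instrument specification
#'
#' Mechanical parameters of the surface force balance used by the
#' quasi-static simulator: crossed-cylinder lens radius, normal spring
#' constant, drive sampling step and additive measurement noise on the
#' energy signal.
#'
#' @param radius lens radius R in m (default 10 mm).
#' @param spring_constant normal spring constant k_N in N/m (default
#'   150 N/m).
#' @param sampling_step drive displacement per recorded sample, m.
#' @param noise_sigma standard deviation of iid Gaussian noise added to the
#'   energy signal, J/m^2 (>= 0).
#' @param seed integer seed for the noise stream; mandatory when
#'   `noise_sigma > 0`.
#' @return object of class `instrument_spec`.
#' @export
instrument_spec <- function(radius = 10e-3, spring_constant = 150,
                            sampling_step = 0.05e-9, noise_sigma = 0,
                            seed = NULL) {
  .check_positive(radius, "radius")
  .check_positive(spring_constant, "spring_constant")
  .check_positive(sampling_step, "sampling_step")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_sigma > 0 && is.null(seed)) {
    stop("a `seed` is mandatory for noisy output", call. = FALSE)
  }
  structure(
    list(radius = radius, spring_constant = spring_constant,
         sampling_step = sampling_step, noise_sigma = noise_sigma,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "instrument_spec"
  )
}

#' Structural (layering) force specification
#'
#' Oscillatory structural contribution from molecular layering near contact:
#' an exponentially decaying cosine of period equal to the layer thickness,
#' riding on a steep power-law hard wall at the closest-approach distance.
#'
#' @param layer_thickness oscillation period d in m (the squeeze-out step
#'   size).
#' @param amplitude oscillation amplitude at contact, J/m^2 (>= 0; 0 disables
#'   the structural term entirely).
#' @param decay_length envelope decay length in m.
#' @param phase_offset m, shifts the cosine phase (default 0: a maximum at
#'   the hard wall).
#' @param hard_wall closest-approach distance D0 in m.
#' @return object of class `structural_force_spec`.
#' @export
structural_force_spec <- function(layer_thickness, amplitude,
                                  decay_length, phase_offset = 0,
                                  hard_wall = 1.0e-9) {
  .check_positive(layer_thickness, "layer_thickness")
  .check_positive(decay_length, "decay_length")
  .check_positive(hard_wall, "hard_wall")
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(
    list(layer_thickness = layer_thickness, amplitude = amplitude,
         decay_length = decay_length, phase_offset = phase_offset,
         hard_wall = hard_wall),
    class = "structural_force_spec"
  )
}

#' Structural layering energy
#'
#' `amplitude * [exp(-x/decay) cos(2 pi (x - phase)/d) + (D0/D)^12]` with
#' `x = max(D - D0, 0)`; the power-12 wall dominates below the
#' closest-approach distance D0, so the energy stays finite for all `D > 0`.
#' Identically zero when `amplitude = 0`.
#'
#' @param D separations in m (> 0); vectorized.
#' @param spec a [structural_force_spec()].
#' @return energy per unit area, J/m^2.
#' @export
structural_energy <- function(D, spec) {
  stopifnot(inherits(spec, "structural_force_spec"))
  if (any(D <= 0)) stop("`D` must be > 0", call. = FALSE)
  if (spec$amplitude == 0) return(rep(0, length(D)))
  x <- pmax(D - spec$hard_wall, 0)
  osc <- exp(-x / spec$decay_length) *
    cos(2 * pi * (x - spec$phase_offset) / spec$layer_thickness)
  wall <- (spec$hard_wall / D)^12
  spec$amplitude * (osc + wall)
}

#' Ground truth driving the synthetic-curve generator
#'
#' Combines the DLVO parameters with an optional structural layering term
#' and an optional adhesion override. Without a structural term a bare
#' repulsive wall (`wall_amplitude * (wall_position / D)^12`) provides the
#' closest-approach contact so the post-jump branch is well defined. When
#' `adhesion_minimum` is given, the contact minimum of the total energy is
#' pinned to that value by an iteratively calibrated Gaussian depth
#' correction centred at the minimum.
#'
#' @param dlvo a [dlvo_params()].
#' @param structural a [structural_force_spec()] or `NULL`.
#' @param adhesion_minimum target contact-minimum energy in J/m^2 (<= 0), or
#'   `NULL` to keep the raw vdW contact minimum.
#' @param eps_e relative permittivity seen by the double-layer term.
#' @param wall_position,wall_amplitude bare hard wall used when `structural`
#'   is `NULL` (m, J/m^2).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(dlvo, structural = NULL, adhesion_minimum = NULL,
                         eps_e = .default_eps_water,
                         wall_position = 0.5e-9, wall_amplitude = 2e-3) {
  stopifnot(inherits(dlvo, "dlvo_params"))
  if (!is.null(structural)) {
    stopifnot(inherits(structural, "structural_force_spec"))
  }
  if (!is.null(adhesion_minimum) && adhesion_minimum > 0) {
    stop("`adhesion_minimum` must be <= 0", call. = FALSE)
  }
  truth <- structure(
    list(dlvo = dlvo, structural = structural,
         adhesion_minimum = adhesion_minimum, eps_e = eps_e,
         wall_position = wall_position, wall_amplitude = wall_amplitude,
         adhesion_correction = NULL),
    class = "ground_truth"
  )
  if (!is.null(adhesion_minimum)) {
    truth$adhesion_correction <- .calibrate_adhesion(truth)
  }
  truth
}

# internal: raw (uncorrected) total energy of a ground truth
.truth_energy_raw <- function(D, truth) {
  W <- total_energy(D, truth$dlvo, truth$eps_e)
  if (!is.null(truth$structural)) {
    W + structural_energy(D, truth$structural)
  } else {
    W + truth$wall_amplitude * (truth$wall_position / D)^12
  }
}

# internal: find the Gaussian correction (center, width, alpha) pinning the
# contact minimum at truth$adhesion_minimum; iterates because adding the
# correction moves the minimum slightly
.calibrate_adhesion <- function(truth, max_iter = 30) {
  wall <- if (is.null(truth$structural)) truth$wall_position else
    truth$structural$hard_wall
  grid <- exp(seq(log(wall * 0.6), log(wall * 20), length.out = 4000))
  target <- truth$adhesion_minimum
  base <- .truth_energy_raw(grid, truth)
  ic <- which.min(base)
  alpha <- 0
  width <- 0.25 * grid[ic]
  for (iter in seq_len(max_iter)) {
    center <- grid[ic]
    width <- 0.25 * center
    # the Gaussian equals alpha at its own centre, so this pins W(center)
    alpha <- target - base[ic]
    W <- base + alpha * exp(-((grid - center) / width)^2)
    i <- which.min(W)
    if (abs(W[i] - target) <= 1e-4 * abs(target)) break
    ic <- i
  }
  W <- base + alpha * exp(-((grid - center) / width)^2)
  if (abs(min(W) - target) > 1e-3 * abs(target)) {
    stop("adhesion calibration failed to pin the contact minimum",
         call. = FALSE)
  }
  list(center = center, width = width, alpha = alpha)
}

#' Total ground-truth energy (the simulator's interaction law)
#'
#' @param D separations in m (> 0); vectorized.
#' @param truth a [ground_truth()].
#' @return energy per unit area, J/m^2.
#' @export
truth_energy <- function(D, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  W <- .truth_energy_raw(D, truth)
  ac <- truth$adhesion_correction
  if (!is.null(ac)) {
    W <- W + ac$alpha * exp(-((D - ac$center) / ac$width)^2)
  }
  W
}

#' Spring jump-in distance for a pure van der Waals interaction
#'
#' A spring-mounted surface loses stability where the interaction force
#' gradient exceeds the spring constant. For `F = -A R / (6 D^2)` that gives
#' the closed-form jump-in separation `(A R / (3 k_N))^(1/3)`.
#'
#' @param hamaker J; @param radius m; @param spring_constant N/m.
#' @return separation in m.
#' @export
vdw_jump_in_distance <- function(hamaker, radius = 10e-3,
                                 spring_constant = 150) {
  (hamaker * radius / (3 * spring_constant))^(1 / 3)
}

#' Force curve container
#'
#' Ordered `(D, W)` samples with direction and instrument metadata. Approach
#' curves are ordered by decreasing separation, retraction curves by
#' increasing separation.
#'
#' @param separation separations in m.
#' @param signal interaction free energy per unit area in J/m^2.
#' @param direction `"approach"` or `"retract"`.
#' @param instrument an [instrument_spec()].
#' @param drive optional drive positions in m (same length).
#' @param ground_truth_id optional provenance tag.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(separation, signal,
                        direction = c("approach", "retract"),
                        instrument = instrument_spec(), drive = NULL,
                        ground_truth_id = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(separation) == length(signal))
  ord_ok <- if (direction == "approach") {
    all(diff(separation) <= 0)
  } else {
    all(diff(separation) >= 0)
  }
  if (!ord_ok) {
    stop(sprintf("`separation` must be %s for a %s curve",
                 if (direction == "approach") "non-increasing" else
                   "non-decreasing", direction), call. = FALSE)
  }
  structure(
    list(separation = separation, signal = signal, direction = direction,
         instrument = instrument, drive = drive,
         ground_truth_id = ground_truth_id),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve> %s, %d samples, D in [%.3g, %.3g] nm\n",
    x$direction, length(x$separation),
    min(x$separation) * 1e9, max(x$separation) * 1e9))
  invisible(x)
}

# internal: run code with a temporary RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a quasi-static SFB force curve
#'
#' Quasi-static mechanics of a spring-mounted surface driven toward or away
#' from a fixed surface interacting through the ground-truth energy law
#' `W(D)` (force `F = 2 pi R W`). For each drive position `X` the recorded
#' separation is the mechanically stable equilibrium `k_N (D - X) = F(D)`
#' with `dF/dD < k_N`, followed by continuity in the drive direction; where
#' the current branch loses stability the curve jumps to the next stable
#' branch (inward on approach, outward on retraction). The recorded signal
#' is `W(D)` plus seeded iid Gaussian noise.
#'
#' @param truth a [ground_truth()].
#' @param instrument an [instrument_spec()].
#' @param direction `"approach"` or `"retract"`.
#' @param drive_from,drive_to drive range in m. The drive position is where
#'   the spring-mounted surface would sit with an undeflected spring, so a
#'   strong repulsion makes the recorded separation exceed it and pushing
#'   into contact requires negative drive positions (spring compression).
#'   On approach `drive_to = NULL` (default) keeps driving inward until the
#'   recorded separation reaches the hard wall; on retraction `drive_to` is
#'   required.
#' @param min_separation stop an open-ended approach once the recorded
#'   separation falls below this (default: 1.1x the hard-wall distance).
#' @param seed overrides `instrument$seed` for the noise stream.
#' @param n_grid number of points of the internal log-spaced separation grid
#'   used for the stability scan.
#' @return a [force_curve()].
#' @export
simulate_quasistatic <- function(truth, instrument = instrument_spec(),
                                 direction = c("approach", "retract"),
                                 drive_from = NULL, drive_to = NULL,
                                 min_separation = NULL,
                                 seed = NULL, n_grid = 20000) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(instrument, "instrument_spec"))
  direction <- match.arg(direction)
  kN <- instrument$spring_constant
  R <- instrument$radius
  wall <- if (is.null(truth$structural)) truth$wall_position else
    truth$structural$hard_wall
  step <- instrument$sampling_step

  if (direction == "approach" && is.null(drive_from)) {
    stop("`drive_from` is required for approach", call. = FALSE)
  }
  if (direction == "retract") {
    if (is.null(drive_to)) stop("`drive_to` is required for retraction",
                                call. = FALSE)
    if (is.null(drive_from)) drive_from <- 0
  }
  # the outer-branch equilibrium sits beyond the drive position by the
  # spring extension F/k_N, so the scan grid must cover D = X + F(X)/k_N
  x_max <- max(abs(c(drive_from, drive_to)))
  ext <- max(0, energy_to_force(truth_energy(max(x_max, 2 * wall), truth),
                                R)) / kN
  d_hi <- (x_max + ext) * 1.1 + 20 * wall
  if (R / d_hi < 1e3) {
    stop("Derjaguin validity violated: radius must exceed 1000x the ",
         "largest separation", call. = FALSE)
  }
  grid <- exp(seq(log(wall * 0.55), log(d_hi), length.out = n_grid))
  Fg <- energy_to_force(truth_energy(grid, truth), R)

  open_ended <- FALSE
  if (direction == "approach") {
    if (is.null(drive_to)) {
      open_ended <- TRUE
      # stop a touch above the wall: the post-contact branch climbs the
      # steep wall extremely slowly in drive units and carries no features
      if (is.null(min_separation)) min_separation <- 1.1 * wall
      # drive far enough inward that the spring can compress past the
      # strongest repulsion on the outer branches; the loop breaks as soon
      # as the recorded separation reaches `min_separation`
      drive_to <- -1.05 * max(Fg[grid >= wall]) / kN - 10 * step
    }
    X <- seq(drive_from, drive_to, by = -step)
  } else {
    X <- seq(drive_from, drive_to, by = step)
  }

  tol <- 2 * step
  prev <- NA_real_
  i_prev <- NA_integer_
  ng <- length(grid)
  D_rec <- numeric(length(X))
  n_used <- length(X)
  # stable roots (upward zero crossings of g) within grid index range lo:hi
  scan_roots <- function(Xk, lo, hi) {
    idx <- lo:hi
    g <- kN * (grid[idx] - Xk) - Fg[idx]
    n <- length(g)
    up <- which(g[-n] < 0 & g[-1] >= 0)
    if (!length(up)) return(NULL)
    i <- idx[up]
    list(D = grid[i] - (kN * (grid[i] - Xk) - Fg[i]) *
           (grid[i + 1] - grid[i]) /
           ((kN * (grid[i + 1] - Xk) - Fg[i + 1]) -
              (kN * (grid[i] - Xk) - Fg[i])),
         i = i)
  }
  for (k in seq_along(X)) {
    res <- NULL
    if (!is.na(i_prev)) {
      # the branch moves only slightly per drive step: search a local
      # window first, falling back to a full scan at folds
      res <- scan_roots(X[k], max(1L, i_prev - 300L),
                        min(ng, i_prev + 300L))
      if (!is.null(res)) {
        ok <- if (direction == "approach") res$D <= prev + tol else
          res$D >= prev - tol
        if (!any(ok)) res <- NULL else {
          res$D <- res$D[ok]
          res$i <- res$i[ok]
        }
      }
    }
    if (is.null(res)) res <- scan_roots(X[k], 1L, ng)
    if (is.null(res)) {
      stop(sprintf("no stable branch at drive position %.3g nm", X[k] * 1e9),
           call. = FALSE)
    }
    roots <- res$D
    pick <- if (is.na(prev)) {
      if (direction == "approach") which.max(roots) else which.min(roots)
    } else if (direction == "approach") {
      cand <- which(roots <= prev + tol)
      if (length(cand)) cand[which.max(roots[cand])] else
        which(roots > prev)[which.min(roots[roots > prev])]
    } else {
      cand <- which(roots >= prev - tol)
      if (length(cand)) cand[which.min(roots[cand])] else
        which(roots < prev)[which.max(roots[roots < prev])]
    }
    prev <- roots[pick]
    i_prev <- res$i[pick]
    D_rec[k] <- prev
    if (open_ended && prev <= min_separation) {
      n_used <- k
      break
    }
  }
  X <- X[seq_len(n_used)]
  D_rec <- D_rec[seq_len(n_used)]

  W_rec <- truth_energy(D_rec, truth)
  use_seed <- if (!is.null(seed)) seed else instrument$seed
  if (instrument$noise_sigma > 0) {
    if (is.null(use_seed)) stop("a seed is mandatory for noisy output",
                                call. = FALSE)
    W_rec <- W_rec + .with_seed(use_seed,
      stats::rnorm(length(W_rec), 0, instrument$noise_sigma))
  }
  force_curve(D_rec, W_rec, direction, instrument, drive = X)
}

#' Generate a synthetic force-curve dataset
#'
#' Simulates replicate noisy curves for a set of ground truths and writes
#' them as curve files plus a JSON manifest recording every ground-truth
#' parameter and seed, for later recovery scoring. Deterministic given the
#' seeds: the replicate `j` of truth `i` uses seed `base_seed + (i-1)*1000 +
#' j`.
#'
#' @param truths named list of [ground_truth()] objects.
#' @param instrument an [instrument_spec()] (its `noise_sigma` applies to all
#'   curves).
#' @param drive_from named numeric (per truth) or single drive start in m.
#' @param replicates replicate curves per truth.
#' @param base_seed integer.
#' @param out_dir output directory (created if missing).
#' @param direction `"approach"` or `"retract"`.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
generate_dataset <- function(truths, instrument, drive_from,
                             replicates = 1, base_seed = 1,
                             out_dir, direction = "approach") {
  stopifnot(is.list(truths), length(names(truths)) == length(truths))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(drive_from) == 1) {
    drive_from <- stats::setNames(rep(drive_from, length(truths)),
                                  names(truths))
  }
  entries <- list()
  paths <- character(0)
  for (i in seq_along(truths)) {
    id <- names(truths)[i]
    truth <- truths[[i]]
    for (j in seq_len(replicates)) {
      seed <- base_seed + (i - 1L) * 1000L + j
      fname <- sprintf("%s_%s_rep%02d.csv", id, direction, j)
      path <- file.path(out_dir, fname)
      if (path %in% paths) stop("duplicate output path: ", path,
                                call. = FALSE)
      paths <- c(paths, path)
      curve <- simulate_quasistatic(truth, instrument, direction,
                                    drive_from = drive_from[[id]],
                                    seed = seed)
      curve$ground_truth_id <- id
      write_curve(curve, path)
      entries[[length(entries) + 1]] <- list(
        file = fname, truth_id = id, seed = seed, direction = direction,
        psi_eff_V = truth$dlvo$psi_eff, kappa_per_m = truth$dlvo$kappa,
        p = truth$dlvo$p, hamaker_J = truth$dlvo$hamaker,
        eps_e = truth$eps_e,
        noise_sigma_J_m2 = instrument$noise_sigma,
        layer_thickness_m = if (is.null(truth$structural)) NULL else
          truth$structural$layer_thickness,
        adhesion_minimum_J_m2 = truth$adhesion_minimum
      )
    }
  }
  manifest <- list(base_seed = base_seed, replicates = replicates,
                   instrument = list(
                     radius_m = instrument$radius,
                     spring_constant_N_m = instrument$spring_constant,
                     sampling_step_m = instrument$sampling_step,
                     noise_sigma_J_m2 = instrument$noise_sigma),
                   curves = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
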
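#' Integrator parameters
#'
#' Overdamped (Brownian) Langevin dynamics in reduced units: energies in
#' kBT at the reference temperature (so `temperature = 1` is the
#' physical reference state), lengths in angstrom, friction absorbed
#' into the reduced time unit.
#'
#' @param dt Time step (reduced time). The default keeps
#'   `k_bond * dt / gamma` well inside the stable, low-bias regime of
#'   the Euler-Maruyama update.
#' @param gamma Friction coefficient (reduced).
#' @param temperature Reduced temperature T* (kBT units), >= 0.
#' @param stride Record every `stride`-th step (>= 1).
#' @param seed Integer RNG seed; the per-step Gaussian draws are made in
#'   fixed coordinate order, so equal seeds give bitwise-equal runs.
#' @param blowup_bound Abort if any |coordinate| exceeds this (A).
#' @return List of class `dynamics_params`.
#' @export
dynamics_params <- function(dt = 0.002, gamma = 1, temperature = 1,
                            stride = 10, seed = 1, blowup_bound = 1e4) {
  stopifnot(dt > 0, gamma > 0, temperature >= 0, stride >= 1)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 stride = as.integer(stride), seed = as.integer(seed),
                 blowup_bound = blowup_bound),
            class = "dynamics_params")
}

#' Run overdamped Langevin dynamics under a protocol schedule
#'
#' Position update `r <- r + (dt/gamma) F + sqrt(2 T* dt/gamma) xi` with
#' iid standard-normal `xi` per coordinate. `F` is the CG potential
#' force plus the bias forces of whichever schedule region the current
#' step falls in. Frames (coordinates, region label, bias and potential
#' energy) are recorded every `stride` steps, plus the initial state.
#'
#' @param system A [build_cg_system()] result.
#' @param schedule A [protocol_schedule()]; its total step count defines
#'   the run length.
#' @param params [dynamics_params()].
#' @param init Initial n x 3 coordinates (default: system reference).
#' @return A `cg_trajectory`.
#' @export
integrate_dynamics <- function(system, schedule, params = dynamics_params(),
                               init = system$ref) {
  n <- nrow(system$beads)
  if (!is.matrix(init) || nrow(init) != n || ncol(init) != 3) {
    abort(sprintf("Initial coordinates must be %d x 3", n),
          class = "flycast_shape_error")
  }
  # resolve all restraints against the bead table before step 0
  resolved <- purrr::map(schedule$restraints, function(rs) {
    purrr::map(rs, resolve_restraint, x = system$beads, policy = "all")
  })
  total <- as.integer(max(schedule$end))
  stride <- params$stride
  n_rec <- 1L + total %/% stride
  coords_arr <- array(NA_real_, c(n_rec, n, 3))
  rec_step <- integer(n_rec)
  rec_region <- character(n_rec)
  rec_bias <- numeric(n_rec)
  rec_pot <- numeric(n_rec)

  # seeded, restorable RNG
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)

  xyz <- init
  mob <- params$dt / params$gamma
  noise_scale <- sqrt(2 * params$temperature * mob)

  region_of <- function(step) {
    # step is the 0-based index of the step about to be taken
    i <- which(step >= schedule$start & step < schedule$end)
    i[1]
  }

  eval_forces <- function(xyz, reg_idx) {
    pef <- potential_energy_forces(system, xyz)
    bias_e <- 0
    f <- pef$forces
    for (res in resolved[[reg_idx]]) {
      b <- bias_eval(res, xyz, n)
      bias_e <- bias_e + b$energy
      f <- f + b$forces
    }
    list(pot = pef$energy, bias = bias_e, forces = f)
  }

  rec <- 0L
  record <- function(step, reg_idx, ev) {
    rec <<- rec + 1L
    coords_arr[rec, , ] <<- xyz
    rec_step[rec] <<- step
    rec_region[rec] <<- schedule$label[reg_idx]
    rec_bias[rec] <<- ev$bias
    rec_pot[rec] <<- ev$pot
  }

  for (step in seq_len(total)) {
    reg_idx <- region_of(step - 1L)
    ev <- eval_forces(xyz, reg_idx)
    if ((step - 1L) %% stride == 0L) record(step - 1L, reg_idx, ev)
    xi <- matrix(rnorm(n * 3), n, 3)
    xyz <- xyz + mob * ev$forces + noise_scale * xi
    if (step %% 100L == 0L || step == total) {
      if (!all(is.finite(xyz)) || max(abs(xyz)) > params$blowup_bound) {
        abort(paste0("Integration diverged at step ", step),
              class = "flycast_diverged")
      }
    }
  }
  record(total, region_of(total - 1L), eval_forces(xyz, region_of(total - 1L)))

  frames <- tibble(step = rec_step[seq_len(rec)],
                   region = rec_region[seq_len(rec)],
                   bias_energy = rec_bias[seq_len(rec)],
                   potential_energy = rec_pot[seq_len(rec)])
  new_trajectory(
    topology = system$beads[, c("chain", "resno", "resname", "mass")],
    coords = coords_arr[seq_len(rec), , , drop = FALSE],
    frames = frames, schedule = schedule, params = params,
    provenance = list(seed = params$seed,
                      params_digest = rlang::hash(unclass(params)),
                      schedule_digest = rlang::hash(schedule))
  )
}

#' Protocol configuration for a staged binding run
#'
#' @param anchors Anchor mapping for Region I (see
#'   [pseudo_native_restraints()]).
#' @param native_table Residue-pair table with `d0` targets for Region
#'   III (see [native_complex_restraints()]).
#' @param native_reference Optional reference complex structure from
#'   which `d0` values are measured instead.
#' @param separation Initial COM-COM separation of the two chains (A).
#' @param region_steps Three region lengths in steps.
#' @param wall_d0,wall_k Region-I wall position (A) and stiffness.
#' @param native_k Region-III harmonic stiffness.
#' @param cg [cg_params()].
#' @param dynamics [dynamics_params()].
#' @param disordered `NULL`, or a disordered-segment flag (list with
#'   `chain`, `resno`) passed to [build_cg_system()].
#' @param phospho `NULL`, or the phosphorylation flag passed to
#'   [build_cg_system()].
#' @return List of class `protocol_config`.
#' @export
protocol_config <- function(anchors, native_table = NULL,
                            native_reference = NULL, separation = 60,
                            region_steps = c(I = 10000, II = 90000,
                                             III = 10000),
                            wall_d0 = 5, wall_k = 10, native_k = 10,
                            cg = cg_params(), dynamics = dynamics_params(),
                            disordered = NULL, phospho = NULL) {
  if (is.null(native_table) && is.null(native_reference)) {
    abort("Provide a native distance table or a reference complex",
          class = "flycast_config_error")
  }
  structure(list(anchors = anchors, native_table = native_table,
                 native_reference = native_reference,
                 separation = separation, region_steps = region_steps,
                 wall_d0 = wall_d0, wall_k = wall_k, native_k = native_k,
                 cg = cg, dynamics = dynamics, disordered = disordered,
                 phospho = phospho),
            class = "protocol_config")
}

#' Run the full three-region binding protocol
#'
#' Places the two apo chains with their centres of mass `separation`
#' angstrom apart along x (the ligand in a random orientation drawn
#' from the seeded RNG), then integrates Region I (pseudo-native
#' capture walls), Region II (unrestrained exploration) and Region III
#' (native-complex harmonics).
#'
#' @param apo_a,apo_b The receptor and ligand structures (distinct
#'   chain ids).
#' @param config A [protocol_config()].
#' @return A `cg_trajectory` with region-labelled frames.
#' @export
run_binding_protocol <- function(apo_a, apo_b, config) {
  combined <- combine_structures(apo_a, apo_b)
  system <- build_cg_system(combined, params = config$cg,
                            disordered = config$disordered,
                            phospho = config$phospho)
  beads <- system$beads
  chains_a <- unique(apo_a$chain)
  in_a <- beads$chain %in% chains_a

  region1 <- pseudo_native_restraints(config$anchors, d0 = config$wall_d0,
                                      k = config$wall_k)
  region3 <- native_complex_restraints(
    table = config$native_table %||% native_distance_table_14_3_3(),
    reference = config$native_reference, k = config$native_k)
  schedule <- protocol_schedule(config$region_steps,
                                region1 = region1, region3 = region3)

  # initial placement: receptor COM at origin, ligand COM at
  # (separation, 0, 0), ligand orientation random but seeded
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config$dynamics$seed + 1L)
  rot <- random_rotation()
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  xyz <- system$ref
  ma <- beads$mass[in_a]; mb <- beads$mass[!in_a]
  com_a <- colSums(xyz[in_a, , drop = FALSE] * ma) / sum(ma)
  xyz[in_a, ] <- sweep(xyz[in_a, , drop = FALSE], 2, com_a)
  com_b <- colSums(xyz[!in_a, , drop = FALSE] * mb) / sum(mb)
  bloc <- sweep(xyz[!in_a, , drop = FALSE], 2, com_b) %*% t(rot)
  xyz[!in_a, ] <- sweep(bloc, 2, c(config$separation, 0, 0), "+")

  # fail before step 0 if any restraint group cannot be resolved
  purrr::walk(c(region1, region3), resolve_restraint, x = beads,
              policy = "all")

  integrate_dynamics(system, schedule, params = config$dynamics,
                     init = xyz)
}
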
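# Synthetic fixtures: toy dimers with a known native pose, ideal and
# breathing helices, and jitter trajectories with known statistics.
# Everything is deterministic under a fixed seed.

#' Ideal CA helix
#'
#' @param n Number of residues (>= 2).
#' @param rise Rise per residue (A).
#' @param twist Twist per residue (degrees).
#' @param radius Helix radius (A). The defaults give the canonical
#'   3.8 A CA-CA step.
#' @param chain Chain id.
#' @param resname Residue name for all beads.
#' @param start_resno First residue number.
#' @return A CA-only `flycast_structure`.
#' @export
ideal_ca_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                           chain = "A", resname = "ALA",
                           start_resno = 1L) {
  i <- seq_len(n) - 1
  ang <- i * twist * pi / 180
  as_structure(tibble(
    chain = chain, resno = start_resno + as.integer(i), ins = "",
    resname = resname, atom = "CA", element = "C",
    x = radius * cos(ang), y = radius * sin(ang), z = i * rise,
    mass = residue_mass(resname)
  ))
}

# compact self-avoiding CA walk; pull > 0 biases steps toward the
# running centroid. Rejection with bounded retries, then restart.
compact_walk <- function(n, step = 3.8, min_dist = 3.0, pull = 0.4,
                         max_retry = 300, max_restart = 40) {
  for (attempt in seq_len(max_restart)) {
    pos <- matrix(NA_real_, n, 3)
    pos[1, ] <- 0
    ok <- TRUE
    for (k in 2:n) {
      centroid <- colMeans(pos[seq_len(k - 1), , drop = FALSE])
      placed <- FALSE
      for (r in seq_len(max_retry)) {
        u <- rnorm(3)
        drift <- centroid - pos[k - 1, ]
        dn <- sqrt(sum(drift^2))
        if (dn > 1e-9) u <- u + pull * drift / dn * sqrt(3)
        u <- u / sqrt(sum(u^2))
        cand <- pos[k - 1, ] + step * u
        if (k <= 2) { placed <- TRUE }
        else {
          d2 <- rowSums(sweep(pos[seq_len(k - 2), , drop = FALSE], 2,
                              cand)^2)
          placed <- all(d2 >= min_dist^2)
        }
        if (placed) { pos[k, ] <- cand; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  abort("Self-avoiding walk generation failed (infeasible spec)",
        class = "flycast_generation_error")
}

walk_structure <- function(pos, chain, resname = "ALA",
                           start_resno = 1L, resnames = NULL) {
  n <- nrow(pos)
  rn <- resnames %||% rep(resname, n)
  as_structure(tibble(
    chain = chain, resno = start_resno + seq_len(n) - 1L, ins = "",
    resname = rn, atom = "CA", element = "C",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    mass = ifelse(is.na(residue_mass(rn)), 110, residue_mass(rn))
  ))
}

#' Toy dimer specification
#'
#' @param n_a Receptor chain length (residues).
#' @param n_b Ligand chain length, including the disordered tail.
#' @param tail_length Length of the ligand's disordered N-terminal tail
#'   (no native contacts are formed there, so a phosphorylation flag
#'   visibly changes its excursions).
#' @param phospho_site Ligand residue number of the phospho-site (must
#'   lie in the tail).
#' @param anchor_1,anchor_2 Ligand residue numbers of the two anchors
#'   (in the globular part).
#' @param separation Initial COM separation emitted in the config (A).
#' @param seed Integer seed.
#' @return List of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(n_a = 40, n_b = 30, tail_length = 8,
                           phospho_site = 4, anchor_1 = 15, anchor_2 = 18,
                           separation = 60, seed = 1) {
  if (anchor_1 <= tail_length || anchor_2 <= tail_length ||
      anchor_1 > n_b || anchor_2 > n_b || anchor_1 == anchor_2) {
    abort("Anchors must be distinct residues in the globular part",
          class = "flycast_generation_error")
  }
  if (phospho_site > tail_length) {
    abort("The phospho site must lie in the disordered tail",
          class = "flycast_generation_error")
  }
  structure(list(n_a = n_a, n_b = n_b, tail_length = tail_length,
                 phospho_site = phospho_site, anchor_1 = anchor_1,
                 anchor_2 = anchor_2, separation = separation,
                 seed = seed),
            class = "toy_dimer_spec")
}

#' Generate a toy dimer with a known native pose
#'
#' Builds two compact self-avoiding CA chains (3.8 A steps), docks the
#' ligand against the receptor surface to define a clash-free native
#' complex, and derives the full protocol configuration from that pose:
#' two 5 A wall restraints (ligand anchors against their nearest
#' receptor groups) and a six-pair native distance table measured from
#' the native complex, which therefore satisfies its own table exactly.
#' The ligand's N-terminal tail is built extended and gets no native
#' contacts.
#'
#' @param spec A [toy_dimer_spec()].
#' @return List with `apo_a`, `apo_b`, `native` (structures), `config`
#'   (anchors, native table, separation, phospho flag, seed).
#' @export
make_toy_dimer <- function(spec = toy_dimer_spec()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  pos_a <- compact_walk(spec$n_a)
  pos_a <- sweep(pos_a, 2, colMeans(pos_a))

  # ligand: extended tail then compact globular part
  n_glob <- spec$n_b - spec$tail_length
  glob <- compact_walk(n_glob)
  tail_dir <- glob[1, ] - colMeans(glob)          # away from the core
  tail_dir <- tail_dir / sqrt(sum(tail_dir^2))
  tail <- matrix(NA_real_, spec$tail_length, 3)
  for (t in seq_len(spec$tail_length)) {
    d <- tail_dir + rnorm(3, sd = 0.25)
    d <- d / sqrt(sum(d^2))
    tail[spec$tail_length - t + 1, ] <- glob[1, ] + (t * 3.8) * d
  }
  # enforce consecutive 3.8 A steps along the tail
  for (t in seq(spec$tail_length, 1)) {
    anchor_pos <- if (t == spec$tail_length) glob[1, ] else tail[t + 1, ]
    v <- tail[t, ] - anchor_pos
    tail[t, ] <- anchor_pos + 3.8 * v / sqrt(sum(v^2))
  }
  pos_b <- rbind(tail, glob)

  # dock: put ligand anchor 1 just outside the receptor surface bead
  # most exposed along +x, in a clash-free random orientation
  # anchor groups on the receptor, chosen a priori around the most
  # surface-exposed bead: group 1 = that bead and its 3 nearest
  # neighbours, group 2 = the next 3 nearest beads
  r_from_center <- sqrt(rowSums(pos_a^2))
  b1 <- spec$anchor_1
  b2 <- spec$anchor_2
  resnames_b <- rep("ALA", spec$n_b)
  resnames_b[spec$phospho_site] <- "THR"
  apo_a <- walk_structure(pos_a, "A")

  sites <- order(r_from_center, decreasing = TRUE)[1:6]
  placed <- NULL
  for (site in sites) {
    u <- pos_a[site, ] / r_from_center[site]
    d_site <- sqrt(rowSums(sweep(pos_a, 2, pos_a[site, ])^2))
    g1 <- order(d_site)[1:4] # includes the site itself
    g2 <- setdiff(order(d_site), g1)[1:3]
    anchors <- list(
      list(a = atom_selection("A", sort(apo_a$resno[g1])),
           b = atom_selection("B", b1)),
      list(a = atom_selection("A", sort(apo_a$resno[g2])),
           b = atom_selection("B", b2))
    )
    # dock by restrained descent: start the ligand outside the capture
    # site and relax under the two wall restraints; excluded volume
    # keeps the pose clash-free
    rot <- random_rotation()
    start_b <- sweep(sweep(pos_b, 2, colMeans(pos_b)) %*% t(rot), 2,
                     pos_a[site, ] + 18 * u, "+")
    init_b <- walk_structure(start_b, "B", resnames = resnames_b)
    combined <- combine_structures(apo_a, init_b)
    disordered <- list(chain = "B", resno = seq_len(spec$tail_length))
    sys <- build_cg_system(combined, disordered = disordered)
    walls <- pseudo_native_restraints(anchors, d0 = 5, k = 10)
    sched <- make_schedule("dock", 2500, list(walls))
    traj <- integrate_dynamics(
      sys, sched,
      params = dynamics_params(dt = 0.002, gamma = 1, temperature = 0.05,
                               stride = 2500,
                               seed = (spec$seed * 13L + site) %% .max_seed),
      init = sys$ref)
    final <- frame_coords(traj, n_frames(traj))
    cand <- final[sys$beads$chain == "B", , drop = FALSE]
    recep <- final[sys$beads$chain == "A", , drop = FALSE]
    w1 <- sqrt(sum((cand[b1, ] - colMeans(recep[g1, , drop = FALSE]))^2))
    w2 <- sqrt(sum((cand[b2, ] - colMeans(recep[g2, , drop = FALSE]))^2))
    if (w1 <= 5.5 && w2 <= 5.5) {
      placed <- cand
      pos_a_final <- recep
      break
    }
  }
  if (is.null(placed)) {
    abort("Could not dock the ligand (anchors colliding / infeasible spec)",
          class = "flycast_generation_error")
  }
  # the receptor relaxes slightly during docking; keep its final
  # coordinates so the native pose is self-consistent
  pos_a <- pos_a_final
  apo_a <- walk_structure(pos_a, "A")
  native_b <- walk_structure(placed, "B", resnames = resnames_b)
  native <- combine_structures(apo_a, native_b, title = "toy dimer native")

  # native table: six interface ligand residues (globular part), each
  # paired with its nearest distinct receptor residue
  glob_idx <- (spec$tail_length + 1):spec$n_b
  cross <- as.matrix(stats::dist(rbind(placed, pos_a)))
  cross <- cross[seq_len(spec$n_b), spec$n_b + seq_len(spec$n_a)]
  near <- apply(cross[glob_idx, ], 1, min)
  cand_b <- glob_idx[order(near)]
  chosen_b <- integer(0)
  chosen_a <- integer(0)
  for (bb in cand_b) {
    aa <- order(cross[bb, ])
    aa <- aa[!aa %in% chosen_a][1]
    if (length(chosen_b) < 6 && !is.na(aa)) {
      chosen_b <- c(chosen_b, bb)
      chosen_a <- c(chosen_a, aa)
    }
  }
  if (length(chosen_b) < 6) {
    abort("Could not find six interface residue pairs",
          class = "flycast_generation_error")
  }
  table <- tibble(chain_a = "A", res_a = as.integer(chosen_a),
                  chain_b = "B", res_b = as.integer(chosen_b))
  table$d0 <- vapply(seq_len(6), function(i) {
    com_distance(native, atom_selection("A", table$res_a[i]),
                 atom_selection("B", table$res_b[i]), policy = "all")
  }, numeric(1))

  apo_b <- walk_structure(sweep(placed, 2, colMeans(placed)), "B",
                          resnames = resnames_b)

  list(
    apo_a = apo_a, apo_b = apo_b, native = native,
    config = list(anchors = anchors, native_table = table,
                  separation = spec$separation, wall_d0 = 5,
                  disordered = list(chain = "B",
                                    resno = seq_len(spec$tail_length)),
                  # phosphorylation targets the receptor pocket formed
                  # by anchor group 1 (the capture site)
                  phospho = list(chain = "B", resno = spec$phospho_site,
                                 window = 2,
                                 pocket = data.frame(
                                   chain = "A",
                                   resno = sort(apo_a$resno[g1])),
                                 pocket_d0 = 5),
                  seed = spec$seed, spec = spec)
  )
}

#' Jitter trajectory with known fluctuation statistics
#'
#' Frames are the base coordinates plus iid Gaussian noise of standard
#' deviation `sigma` per coordinate, so the expected RMSF of every bead
#' is `sigma * sqrt(3)` (without superposition).
#'
#' @param base A CA-level structure providing the topology.
#' @param sigma Noise standard deviation (A), >= 0.
#' @param frames Number of frames.
#' @param seed Integer seed.
#' @return A `cg_trajectory`.
#' @export
make_jitter_trajectory <- function(base, sigma, frames, seed = 1) {
  stopifnot(sigma >= 0, frames >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  xyz <- coords(base)
  n <- nrow(xyz)
  arr <- array(NA_real_, c(frames, n, 3))
  for (f in seq_len(frames)) {
    arr[f, , ] <- xyz + matrix(rnorm(n * 3, sd = sigma), n, 3)
  }
  new_trajectory(
    topology = as_tibble(base)[, c("chain", "resno", "resname", "mass")],
    coords = arr,
    frames = tibble(step = seq_len(frames) - 1L, region = NA_character_,
                    bias_energy = NA_real_, potential_energy = NA_real_),
    provenance = list(seed = seed, generator = "jitter", sigma = sigma)
  )
}

#' Breathing helix with a prescribed capture-radius oscillation
#'
#' An ideal CA helix whose coordinates are scaled uniformly about the
#' centroid so that the radius of gyration oscillates sinusoidally:
#' `Rg(t) = Rg0 + amplitude * sin(2 pi t / period)`. The max-minus-min
#' excursion of the capture radius is exactly `2 * amplitude`.
#'
#' @param residues Number of residues (>= 4); 29 matches a long
#'   regulatory helix such as helix 9 of 14-3-3.
#' @param amplitude Oscillation amplitude of the radius of gyration (A).
#' @param period Oscillation period (frames).
#' @param frames Number of frames (default: two periods).
#' @param seed Kept for generator-interface symmetry; this generator is
#'   deterministic.
#' @return A `cg_trajectory`.
#' @export
make_breathing_helix <- function(residues = 29, amplitude = 1,
                                 period = 100, frames = 2 * period,
                                 seed = 1) {
  stopifnot(residues >= 4, amplitude >= 0, period >= 2)
  base <- ideal_ca_helix(residues)
  xyz <- coords(base)
  mass <- base$mass
  cm <- mass_center(xyz, mass)
  centered <- sweep(xyz, 2, cm)
  rg0 <- gyration_radius(xyz, mass)
  if (amplitude >= rg0) abort("amplitude must be below the base radius")
  n <- nrow(xyz)
  arr <- array(NA_real_, c(frames, n, 3))
  t_idx <- seq_len(frames) - 1L
  for (f in seq_len(frames)) {
    s <- 1 + amplitude * sin(2 * pi * t_idx[f] / period) / rg0
    arr[f, , ] <- sweep(centered * s, 2, cm, "+")
  }
  new_trajectory(
    topology = as_tibble(base)[, c("chain", "resno", "resname", "mass")],
    coords = arr,
    frames = tibble(step = t_idx, region = NA_character_,
                    bias_energy = NA_real_, potential_energy = NA_real_),
    provenance = list(seed = seed, generator = "breathing_helix",
                      amplitude = amplitude, period = period)
  )
}
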
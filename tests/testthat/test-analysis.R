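# --- RMSD / RMSF -----------------------------------------------------

static_trajectory <- function(base, frames = 5) {
  make_jitter_trajectory(base, sigma = 0, frames = frames, seed = 1)
}

test_that("RMSD to the reference is zero for copies and rigid motions", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 2))
  ref <- d$native
  traj <- static_trajectory(ref, frames = 4)
  fit <- atom_selection("A", atoms = "calpha")
  expect_true(all(rmsd_series(traj, ref, fit)$value < 1e-9))
  # rigidly move every frame: superposition removes the motion
  rot <- flycast:::random_rotation()
  moved <- traj
  for (f in seq_len(n_frames(moved))) {
    moved$coords[f, , ] <- sweep(frame_coords(traj, f) %*% t(rot), 2,
                                 c(8, -4, 2), "+")
  }
  expect_true(all(rmsd_series(moved, ref, fit)$value < 1e-8))
})

test_that("per-frame RMSD matches a brute-force Kabsch oracle", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 3))
  ref <- d$native
  traj <- make_jitter_trajectory(ref, sigma = 0.7, frames = 10, seed = 9)
  fit <- atom_selection("B", atoms = "calpha")
  got <- rmsd_series(traj, ref, fit)$value
  ridx <- resolve_selection(ref, fit)
  for (f in seq_len(10)) {
    kf <- kabsch_superpose(frame_coords(traj, f)[ridx, ],
                           coords(ref)[ridx, ])
    expect_equal(got[f], kf$rmsd, tolerance = 1e-9)
  }
})

test_that("segment RMSDs recompose into the whole-selection RMSD", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 4))
  ref <- d$native
  traj <- make_jitter_trajectory(ref, sigma = 0.5, frames = 6, seed = 2)
  fit <- atom_selection("A", atoms = "calpha")
  segs <- list(s1 = atom_selection("A", 1:10),
               s2 = atom_selection("A", 11:25),
               s3 = atom_selection("A", 26:40))
  by_seg <- rmsd_by_segments(traj, ref, fit, segs)
  whole <- rmsd_series(traj, ref, fit, measure = atom_selection("A"))
  recomposed <- by_seg |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(value = sqrt(sum(.data$n_atoms * .data$value^2) /
                                    sum(.data$n_atoms)))
  expect_equal(recomposed$value, whole$value, tolerance = 1e-9)
})

test_that("segments must not overlap and map onto author numbering", {
  chain <- ideal_ca_helix(200)
  traj <- static_trajectory(chain)
  segs <- list(nterm = atom_selection("A", 1:25),
               motif = atom_selection("A", 30:57),
               cterm = atom_selection("A", 141:198))
  out <- rmsd_by_segments(traj, chain, atom_selection("A"), segs)
  expect_setequal(unique(out$segment), c("nterm", "motif", "cterm"))
  expect_true(all(out$value < 1e-9))
  bad <- list(a = atom_selection("A", 1:25), b = atom_selection("A", 20:30))
  expect_error(rmsd_by_segments(traj, chain, atom_selection("A"), bad),
               "overlap")
})

test_that("RMSF is zero for static frames and sigma*sqrt(3) for jitter", {
  base <- ideal_ca_helix(20)
  expect_true(all(rmsf(static_trajectory(base))$value < 1e-12))
  sigma <- 0.5
  traj <- make_jitter_trajectory(base, sigma = sigma, frames = 10000,
                                 seed = 4)
  vals <- rmsf(traj)$value # no superposition
  expect_true(all(abs(vals - sigma * sqrt(3)) / (sigma * sqrt(3)) < 0.05))
  # frame order invariance
  perm <- sample(n_frames(traj))
  shuffled <- traj
  shuffled$coords <- traj$coords[perm, , , drop = FALSE]
  expect_equal(rmsf(shuffled)$value, vals, tolerance = 1e-12)
})

# --- SASA ------------------------------------------------------------

single_atom <- function(element = "C") {
  as_structure(tibble::tibble(chain = "A", resno = 1L, ins = "",
                              resname = "ALA", atom = element,
                              element = element, x = 0, y = 0, z = 0))
}

test_that("SASA of an isolated sphere is the analytic area", {
  s <- sasa(single_atom("C"))
  expect_equal(sasa_total(s), 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("SASA is additive for non-overlapping atoms", {
  st <- as_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L), ins = "", resname = "ALA",
    atom = "C", element = "C", x = c(0, 100), y = 0, z = 0))
  expect_equal(sasa_total(sasa(st)), 2 * 4 * pi * 3.1^2,
               tolerance = 1e-9)
})

test_that("overlapping spheres match a Monte-Carlo surface integral", {
  st <- as_structure(tibble::tibble(
    chain = "A", resno = c(1L, 2L), ins = "", resname = "ALA",
    atom = "C", element = "C", x = c(0, 2), y = 0, z = 0))
  got <- sasa_total(sasa(st))
  # Monte-Carlo oracle: 1e6 uniform surface points per sphere
  set.seed(14)
  n_mc <- 1e6
  centers <- rbind(c(0, 0, 0), c(2, 0, 0))
  re <- 3.1
  mc_total <- 0
  for (i in 1:2) {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * re, 2, centers[i, ], "+")
    other <- centers[3 - i, ]
    outside <- rowSums(sweep(pts, 2, other)^2) > re^2
    mc_total <- mc_total + mean(outside) * 4 * pi * re^2
  }
  expect_rel_equal(got, mc_total, 0.01)
})

test_that("total SASA is invariant under rigid motion to < 0.1%", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 5))
  st <- d$native
  base <- sasa_total(sasa(st, radii = rep(3, nrow(st))))
  set.seed(15)
  for (rep in 1:3) {
    rot <- flycast:::random_rotation()
    moved <- set_coords(st, sweep(coords(st) %*% t(rot), 2,
                                  rnorm(3, sd = 10), "+"))
    got <- sasa_total(sasa(moved, radii = rep(3, nrow(moved))))
    expect_rel_equal(got, base, 0.001)
  }
})

test_that("normalised complex SASA is 100% for separated chains,
           bounded by 100, and symmetric in the partition", {
  a <- ideal_ca_helix(8, chain = "A")
  b <- ideal_ca_helix(8, chain = "B")
  far <- combine_structures(a, set_coords(b, sweep(coords(b), 2,
                                                   c(100, 0, 0), "+")))
  r <- rep(3, nrow(far))
  expect_equal(normalized_complex_sasa(far, chains_a = "A",
                                       chains_b = "B", radii = r), 100,
               tolerance = 1e-9)
  d <- make_toy_dimer(toy_dimer_spec(seed = 6))
  rr <- rep(3, nrow(d$native))
  v1 <- normalized_complex_sasa(d$native, chains_a = "A", chains_b = "B",
                                radii = rr)
  v2 <- normalized_complex_sasa(d$native, chains_a = "B", chains_b = "A",
                                radii = rr)
  expect_lt(v1, 100)
  expect_equal(v1, v2, tolerance = 1e-12)
  # partitions must cover exactly
  expect_error(normalized_complex_sasa(d$native,
                                       sel_a = atom_selection("A"),
                                       sel_b = atom_selection("B", 1:5)),
               class = "flycast_partition_error")
})

# --- contacts and capture radius ------------------------------------

test_that("polar contact counting honours cutoff, patterns and levels", {
  st <- as_structure(tibble::tibble(
    chain = c("A", "A", "B", "B"), resno = c(1L, 2L, 1L, 2L), ins = "",
    resname = "GLY",
    atom = c("N", "CA", "O", "CA"),
    element = c("N", "C", "O", "C"),
    x = c(0, 5, 3, 20), y = 0, z = 0))
  sa <- atom_selection("A")
  sb <- atom_selection("B")
  expect_equal(contact_count(st, sa, sb, cutoff = 3.5), 1) # N...O at 3.0
  expect_equal(contact_count(st, sa, sb, cutoff = 2.5), 0)
  expect_equal(contact_count(st, sb, sa, cutoff = 3.5),
               contact_count(st, sa, sb, cutoff = 3.5)) # symmetric
  expect_equal(contact_count(st, sa, sb, cutoff = 3.5,
                             level = "residues"), 1)
  # empty selection counts zero
  expect_equal(contact_count(st, atom_selection("A", 99), sb), 0)
  expect_error(contact_count(st, sa, atom_selection("A")),
               class = "flycast_partition_error")
})

test_that("capture radius tracks rigid, scaled and breathing selections", {
  base <- ideal_ca_helix(29)
  static <- static_trajectory(base, frames = 5)
  sel <- atom_selection("A")
  cr <- capture_radius_series(static, sel)
  expect_equal(stats::sd(cr$value), 0)
  # uniform doubling doubles the radius
  doubled <- static
  cm <- colMeans(frame_coords(static, 1))
  for (f in seq_len(n_frames(doubled))) {
    doubled$coords[f, , ] <- sweep(
      sweep(frame_coords(static, f), 2, cm) * 2, 2, cm, "+")
  }
  expect_equal(capture_radius_series(doubled, sel)$value,
               2 * cr$value, tolerance = 1e-9)
  # breathing helix: excursion equals twice the amplitude, and doubling
  # the amplitude doubles the excursion
  for (amp in c(0.5, 1)) {
    traj <- make_breathing_helix(residues = 29, amplitude = amp,
                                 period = 40, frames = 80)
    vals <- capture_radius_series(traj, sel)$value
    expect_equal(max(vals) - min(vals), 2 * amp, tolerance = 0.01 * amp)
  }
  # amplitude zero: constant
  flat <- make_breathing_helix(residues = 29, amplitude = 0, period = 40,
                               frames = 40)
  expect_equal(stats::sd(capture_radius_series(flat, sel)$value), 0)
  # single-bead selections are degenerate
  expect_error(capture_radius_series(static, atom_selection("A", 1)),
               class = "flycast_degenerate_selection")
})
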
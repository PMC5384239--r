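test_that("a helix maps to beads with 3.8 A backbone bonds", {
  sys <- build_cg_system(ideal_ca_helix(10))
  expect_equal(nrow(sys$beads), 10)
  expect_equal(nrow(sys$bonds), 9)
  expect_equal(sys$bonds$r0, rep(sys$bonds$r0[1], 9), tolerance = 1e-9)
  expect_equal(sys$bonds$r0[1], 3.8, tolerance = 0.05)
  expect_equal(sys$beads$mass, rep(71.08, 10))
})

test_that("distant chains get no inter-chain contacts unless flagged", {
  a <- ideal_ca_helix(8, chain = "A")
  b <- ideal_ca_helix(8, chain = "B")
  b <- set_coords(b, sweep(coords(b), 2, c(60, 0, 0), "+"))
  sys <- build_cg_system(combine_structures(a, b))
  cross <- sys$beads$chain[sys$contacts$i] != sys$beads$chain[sys$contacts$j]
  expect_equal(sum(cross), 0)
  # complex reference at close range does produce inter-chain contacts
  b2 <- set_coords(b, sweep(coords(b), 2, c(-54, 0, 0), "+"))
  sys2 <- build_cg_system(combine_structures(a, b2),
                          complex_reference = TRUE)
  cross2 <- sys2$beads$chain[sys2$contacts$i] !=
    sys2$beads$chain[sys2$contacts$j]
  expect_gt(sum(cross2), 0)
})

test_that("the contact list matches a brute-force distance scan", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 2))
  st <- d$apo_a
  sys <- build_cg_system(st)
  xyz <- coords(st)
  n <- nrow(xyz)
  brute <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(st$resno[j] - st$resno[i]) >= 3 &&
        sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 8) {
      brute[[length(brute) + 1]] <- c(i, j)
    }
  }
  got <- sort(paste(sys$contacts$i, sys$contacts$j))
  want <- sort(vapply(brute, function(p) paste(p[1], p[2]), ""))
  expect_identical(got, want)
})

test_that("forces vanish at the reference minimum and beyond the cutoff", {
  sys <- build_cg_system(ideal_ca_helix(12))
  pef <- potential_energy_forces(sys)
  expect_lt(max(abs(pef$forces)), 1e-9)
  expect_equal(pef$energy, -nrow(sys$contacts)) # each well at -eps
  # two isolated beads beyond sigma: zero pair energy
  sys2 <- two_bead_system(separation = 10)
  expect_equal(potential_energy_forces(sys2)$energy, 0)
})

test_that("forces are the exact negative energy gradient", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 3))
  sys <- build_cg_system(d$native, phospho = list(chain = "B", resno = 4))
  set.seed(21)
  xyz <- sys$ref + matrix(rnorm(nrow(sys$ref) * 3, sd = 0.4), ncol = 3)
  pef <- potential_energy_forces(sys, xyz)
  eps <- 1e-6
  idx <- sample(nrow(xyz), 8)
  for (i in idx) for (c in 1:3) {
    xp <- xyz; xp[i, c] <- xp[i, c] + eps
    xm <- xyz; xm[i, c] <- xm[i, c] - eps
    num <- -(potential_energy_forces(sys, xp)$energy -
               potential_energy_forces(sys, xm)$energy) / (2 * eps)
    expect_equal(pef$forces[i, c], num,
                 tolerance = 1e-5 * max(1, abs(num)))
  }
})

test_that("total force and torque vanish; energy is rigid-invariant", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 4))
  sys <- build_cg_system(d$native)
  set.seed(22)
  xyz <- sys$ref + matrix(rnorm(nrow(sys$ref) * 3, sd = 0.3), ncol = 3)
  pef <- potential_energy_forces(sys, xyz)
  expect_lt(max(abs(colSums(pef$forces))), 1e-8)
  com <- colMeans(xyz)
  rel <- sweep(xyz, 2, com)
  torque <- colSums(cbind(
    rel[, 2] * pef$forces[, 3] - rel[, 3] * pef$forces[, 2],
    rel[, 3] * pef$forces[, 1] - rel[, 1] * pef$forces[, 3],
    rel[, 1] * pef$forces[, 2] - rel[, 2] * pef$forces[, 1]))
  expect_lt(max(abs(torque)), 1e-8)
  rot <- flycast:::random_rotation()
  moved <- sweep(xyz %*% t(rot), 2, c(5, -3, 11), "+")
  expect_equal(potential_energy_forces(sys, moved)$energy, pef$energy,
               tolerance = 1e-9)
})

test_that("coordinate/bead mismatch is a shape error", {
  sys <- build_cg_system(ideal_ca_helix(5))
  expect_error(potential_energy_forces(sys, matrix(0, 4, 3)),
               class = "flycast_shape_error")
})

test_that("a missing CA atom fails the build with the residue named", {
  st <- as_structure(tibble::tibble(
    chain = "A", resno = 1:2, ins = "", resname = "GLY",
    atom = c("CA", "CB"), element = "C",
    x = c(0, 3.8), y = 0, z = 0))
  expect_error(build_cg_system(st), class = "flycast_build_error",
               regexp = "A:2")
})

test_that("the phosphorylation flag releases local contacts and can
           target a pocket", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 5))
  site <- d$config$phospho$resno
  plain <- build_cg_system(d$native)
  ph <- build_cg_system(d$native,
                        phospho = list(chain = "B", resno = site,
                                       window = 2))
  zone <- which(ph$beads$chain == "B" &
                  abs(ph$beads$resno - site) <= 2)
  in_zone <- function(sys) sum((sys$contacts$i %in% zone |
                                  sys$contacts$j %in% zone) &
    sys$beads$chain[sys$contacts$i] == sys$beads$chain[sys$contacts$j])
  expect_equal(in_zone(ph), 0)
  pocket <- data.frame(chain = "A", resno = c(5, 6))
  ph2 <- build_cg_system(d$native,
                         phospho = list(chain = "B", resno = site,
                                        pocket = pocket, pocket_d0 = 5))
  expect_equal(nrow(ph2$contacts), nrow(ph$contacts) + 2)
})

test_that("the disordered segment forms no native contacts", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 6))
  sys <- build_cg_system(d$native, disordered = d$config$disordered)
  tail_beads <- which(sys$beads$chain == "B" &
                        sys$beads$resno %in% d$config$disordered$resno)
  expect_equal(sum(sys$contacts$i %in% tail_beads |
                     sys$contacts$j %in% tail_beads), 0)
})

test_that("topology files round-trip through the plain-text format", {
  d <- make_toy_dimer(toy_dimer_spec(seed = 2))
  sys <- build_cg_system(d$native)
  path <- withr::local_tempfile(fileext = ".top")
  write_cg_topology(sys, path)
  back <- read_cg_topology(path)
  expect_equal(back$beads$chain, sys$beads$chain)
  expect_equal(back$beads$mass, sys$beads$mass, tolerance = 1e-6)
  expect_equal(back$bonds$r0, sys$bonds$r0, tolerance = 1e-5)
  expect_equal(nrow(back$contacts), nrow(sys$contacts))
  expect_equal(nrow(back$rep_pairs), nrow(sys$rep_pairs))
  # energies agree at matched coordinates
  e1 <- potential_energy_forces(sys, sys$ref)$energy
  e2 <- potential_energy_forces(back, back$ref)$energy
  expect_equal(e1, e2, tolerance = 1e-6)
})
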
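test_that("centre of mass matches a direct summation oracle", {
  expect_equal(center_of_mass(matrix(c(1, 2, 3), 1), mass = 2), c(1, 2, 3))
  expect_equal(center_of_mass(matrix(c(0, 0, 0, 2, 0, 0), 2,
                                     byrow = TRUE), mass = c(1, 1)),
               c(1, 0, 0))
  set.seed(5)
  xyz <- matrix(rnorm(150), 50, 3)
  m <- runif(50, 0.5, 200)
  oracle <- c(0, 0, 0)
  for (i in 1:50) oracle <- oracle + m[i] * xyz[i, ]
  oracle <- oracle / sum(m)
  expect_equal(center_of_mass(xyz, mass = m), oracle, tolerance = 1e-9)
})

test_that("centre of mass is equivariant under rigid transforms", {
  set.seed(6)
  xyz <- matrix(rnorm(60), 20, 3)
  m <- runif(20, 1, 10)
  rot <- flycast:::random_rotation()
  tr <- c(3, -2, 7)
  moved <- sweep(xyz %*% t(rot), 2, tr, "+")
  expect_equal(center_of_mass(moved, mass = m),
               as.numeric(rot %*% center_of_mass(xyz, mass = m)) + tr,
               tolerance = 1e-9)
})

test_that("COM distance is symmetric, zero on itself, exact on points", {
  st <- two_chain_structure()
  sa <- atom_selection("A", 1:4)
  sb <- atom_selection("B", 1:4)
  expect_equal(com_distance(st, sa, sa), 0)
  expect_equal(com_distance(st, sa, sb), com_distance(st, sb, sa))
  two <- as_structure(tibble::tibble(
    chain = c("A", "B"), resno = 1L, ins = "", resname = "GLY",
    atom = "CA", element = "C", x = c(0, 5), y = 0, z = 0))
  expect_equal(com_distance(two, atom_selection("A"), atom_selection("B")),
               5)
  expect_error(com_distance(st, atom_selection("A", 999), sb),
               class = "flycast_empty_selection")
})

test_that("radius of gyration has its analytic values", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1), mass = 3), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE)
  expect_equal(radius_of_gyration(two, mass = c(1, 1)), 1)
  square <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), 4, 3,
                   byrow = TRUE)
  expect_equal(radius_of_gyration(square, mass = rep(1, 4)), sqrt(2) / 2)
})

test_that("Rg and COM distance are invariant under rigid transforms", {
  set.seed(7)
  st <- two_chain_structure()
  sa <- atom_selection("A")
  sb <- atom_selection("B")
  for (rep in 1:5) {
    rot <- flycast:::random_rotation()
    tr <- rnorm(3, sd = 20)
    moved <- set_coords(st, sweep(coords(st) %*% t(rot), 2, tr, "+"))
    expect_rel_equal(radius_of_gyration(moved),
                     radius_of_gyration(st), 1e-9)
    expect_rel_equal(com_distance(moved, sa, sb),
                     com_distance(st, sa, sb), 1e-9)
  }
})

test_that("Kabsch recovers rigid motions exactly", {
  set.seed(8)
  p <- matrix(rnorm(24), 8, 3)
  self <- kabsch_superpose(p, p)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(p %*% t(rot90z), 2, c(10, 0, 0), "+")
  fit <- kabsch_superpose(moved, p)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD never beats nor trails a 2-degree rotation grid", {
  # independent brute-force oracle: rmsd minimised over a ZYZ Euler
  # grid via the trace identity ssd = c - 2 tr(Rz(c) K)
  grid_min_rmsd <- function(p, q, step_deg = 2) {
    pc <- sweep(p, 2, colMeans(p))
    qc <- sweep(q, 2, colMeans(q))
    m <- crossprod(pc, qc) # M = sum p_i q_i^T, ssd = cc - 2 tr(R M)
    cc <- sum(pc^2) + sum(qc^2)
    n <- nrow(p)
    ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
    bet <- seq(0, 180, by = step_deg) * pi / 180
    rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    ry <- function(b) matrix(c(cos(b), 0, sin(b), 0, 1, 0,
                               -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    best <- -Inf
    cg <- cos(ang); sg <- sin(ang)
    for (a in ang) {
      za <- rz(a)
      for (b in bet) {
        k <- m %*% za %*% ry(b)   # tr(Rz(g) k')
        tr_g <- cg * (k[1, 1] + k[2, 2]) + sg * (k[2, 1] - k[1, 2]) +
          k[3, 3]
        best <- max(best, max(tr_g))
      }
    }
    sqrt(max(cc - 2 * best, 0) / n)
  }
  set.seed(9)
  for (rep in 1:20) {
    p <- matrix(rnorm(24), 8, 3)
    q <- matrix(rnorm(24), 8, 3)
    k_rmsd <- kabsch_superpose(p, q)$rmsd
    g_rmsd <- grid_min_rmsd(p, q)
    expect_lte(k_rmsd, g_rmsd + 1e-9)
    expect_lt(g_rmsd - k_rmsd, 0.05) # grid resolution tolerance
  }
})

test_that("Kabsch RMSD never exceeds the unfitted RMSD", {
  set.seed(10)
  for (rep in 1:10) {
    p <- matrix(rnorm(30), 10, 3)
    q <- p + matrix(rnorm(30, sd = 0.8), 10, 3)
    expect_lte(kabsch_superpose(p, q)$rmsd, rmsd_raw(p, q) + 1e-12)
  }
})

test_that("Kabsch agrees with an independent reference implementation", {
  set.seed(12)
  p <- matrix(rnorm(45), 15, 3)
  q <- matrix(rnorm(45), 15, 3)
  ours <- kabsch_superpose(p, q)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(q)), as.numeric(t(p)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3) # bio3d rounds to 3 dp
})

test_that("degenerate superpositions are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + 0.0, line),
               class = "flycast_degenerate_fit")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               class = "flycast_degenerate_fit")
})
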
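#' Mass-weighted centre of mass
#'
#' @param x A `flycast_structure`, CG bead table, or an n x 3 matrix.
#' @param selection Optional [atom_selection()] (table input only).
#' @param mass Masses, required when `x` is a bare matrix.
#' @param policy Atom policy for structures: `"heavy"` (default, drops
#'   hydrogens), `"all"`, or `"calpha"`.
#' @return Length-3 numeric vector (angstrom).
#' @export
center_of_mass <- function(x, selection = NULL, mass = NULL,
                           policy = "heavy") {
  if (is.matrix(x)) {
    if (is.null(mass)) mass <- rep(1, nrow(x))
    return(mass_center(x, mass))
  }
  idx <- if (is.null(selection)) seq_len(nrow(x)) else
    resolve_atoms(x, selection, policy)
  if (length(idx) == 0) abort("Selection resolves to zero atoms",
                              class = "flycast_empty_selection")
  mass_center(coords(x, idx), x$mass[idx])
}

mass_center <- function(xyz, mass) {
  stopifnot(nrow(xyz) >= 1, all(mass > 0), length(mass) == nrow(xyz))
  as.numeric(colSums(xyz * mass) / sum(mass))
}

#' Distance between the centres of mass of two selections
#'
#' Symmetric in its two selections. By default the COM of each group is
#' taken over all heavy atoms of the selected residues, mass-weighted.
#'
#' @param x A structure or bead table.
#' @param sel_a,sel_b [atom_selection()]s; each must resolve non-empty.
#' @param policy `"heavy"`, `"all"`, or `"calpha"`.
#' @return Scalar distance in angstrom.
#' @export
com_distance <- function(x, sel_a, sel_b, policy = "heavy") {
  ia <- resolve_atoms(x, sel_a, policy)
  ib <- resolve_atoms(x, sel_b, policy)
  if (length(ia) == 0) abort(paste0("Empty selection: ", format(sel_a)),
                             class = "flycast_empty_selection")
  if (length(ib) == 0) abort(paste0("Empty selection: ", format(sel_b)),
                             class = "flycast_empty_selection")
  mass <- if ("mass" %in% names(x)) x$mass else rep(1, nrow(x))
  ca <- mass_center(coords_any(x, ia), mass[ia])
  cb <- mass_center(coords_any(x, ib), mass[ib])
  sqrt(sum((ca - cb)^2))
}

# coordinate rows from either a structure tibble or a bead table
coords_any <- function(x, idx) {
  as.matrix(x[idx, c("x", "y", "z"), drop = FALSE]) |> unname()
}

#' Mass-weighted radius of gyration
#'
#' `sqrt( sum m_i |r_i - r_COM|^2 / sum m_i )`; invariant under rigid
#' transforms. This is the capture-radius kernel.
#'
#' @inheritParams center_of_mass
#' @return Scalar radius in angstrom.
#' @export
radius_of_gyration <- function(x, selection = NULL, mass = NULL,
                               policy = "heavy") {
  if (is.matrix(x)) {
    if (is.null(mass)) mass <- rep(1, nrow(x))
    return(gyration_radius(x, mass))
  }
  idx <- if (is.null(selection)) seq_len(nrow(x)) else
    resolve_atoms(x, selection, policy)
  if (length(idx) == 0) abort("Selection resolves to zero atoms",
                              class = "flycast_empty_selection")
  gyration_radius(coords(x, idx), x$mass[idx])
}

gyration_radius <- function(xyz, mass) {
  cm <- mass_center(xyz, mass)
  d2 <- rowSums(sweep(xyz, 2, cm)^2)
  sqrt(sum(mass * d2) / sum(mass))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1, reflections excluded) and
#' translation minimising the unweighted least-squares deviation of
#' `mobile` onto `reference` over the fitted points, via SVD of the
#' 3 x 3 covariance with sign correction of the smallest singular
#' vector.
#'
#' @param mobile,reference n x 3 coordinate matrices (or structures),
#'   row i of `mobile` corresponding to row i of `reference`.
#' @param fit Optional integer indices of the rows used for the fit
#'   (default: all rows). At least 3 non-collinear points.
#' @return A list of class `kabsch_fit` with elements `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (post-fit RMSD over the fitted
#'   points, angstrom). Apply with [apply_fit()].
#' @export
kabsch_superpose <- function(mobile, reference, fit = NULL) {
  pm <- if (is.matrix(mobile)) mobile else coords(mobile)
  pr <- if (is.matrix(reference)) reference else coords(reference)
  if (nrow(pm) != nrow(pr)) {
    abort("mobile and reference must have the same number of points")
  }
  if (is.null(fit)) fit <- seq_len(nrow(pm))
  m <- pm[fit, , drop = FALSE]
  r <- pr[fit, , drop = FALSE]
  if (nrow(m) < 3) abort("Need at least 3 points to superpose",
                         class = "flycast_degenerate_fit")
  cm <- colMeans(m)
  cr <- colMeans(r)
  mc <- sweep(m, 2, cm)
  rc <- sweep(r, 2, cr)
  sv_ref <- svd(rc)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1e-300)) {
    abort("Fit points are collinear: superposition is degenerate",
          class = "flycast_degenerate_fit")
  }
  h <- crossprod(mc, rc)            # 3x3 covariance  t(mc) %*% rc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # maps mobile -> reference
  trans <- as.numeric(cr - rot %*% cm)
  fitted <- sweep(mc %*% t(rot), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "kabsch_fit")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param fit A `kabsch_fit` (or any list with `rotation`,
#'   `translation`).
#' @return Transformed n x 3 matrix.
#' @export
apply_fit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch fit> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Root-mean-square deviation between paired coordinates
#'
#' @param a,b n x 3 matrices.
#' @return Scalar RMSD (angstrom), with no superposition applied.
#' @export
rmsd_raw <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# rotation taking unit(a) onto unit(b) about their common normal
rotation_align <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) { # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# rotation by angle theta about unit axis
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * vx + (1 - cos(theta)) * vx %*% vx
}

# uniform random rotation matrix (uses the current RNG stream)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
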
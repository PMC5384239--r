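#' Count polar contacts between two selections
#'
#' Hydrogen bonds are approximated by a heavy-atom donor/acceptor
#' distance criterion: N/O (by default) atoms of one selection within
#' `cutoff` of N/O atoms of the other. No angle term is applied, so the
#' criterion works on crystal structures without hydrogens. Counting is
#' either per atom pair (symmetric in the two selections) or per
#' distinct residue of `sel_b` with at least one contact.
#'
#' @param x A structure (or one trajectory frame via
#'   [frame_structure()]... any atom table with `element` works).
#' @param sel_a,sel_b Disjoint [atom_selection()]s.
#' @param cutoff Distance cutoff (A); default 3.5 (0.35 nm).
#' @param level `"pairs"` (atom-pair count) or `"residues"` (distinct
#'   `sel_b` residues contacted).
#' @param elements Elements eligible on both sides (default N and O).
#' @param elements_a,elements_b Side-specific element patterns
#'   overriding `elements` (e.g. phosphate oxygens on one side against
#'   basic nitrogens on the other).
#' @return Integer count.
#' @export
contact_count <- function(x, sel_a, sel_b, cutoff = 3.5,
                          level = c("pairs", "residues"),
                          elements = c("N", "O"),
                          elements_a = elements, elements_b = elements) {
  level <- match.arg(level)
  if (cutoff <= 0) abort("cutoff must be > 0")
  ia <- resolve_selection(x, sel_a)
  ib <- resolve_selection(x, sel_b)
  if (length(intersect(ia, ib)) > 0) {
    abort("Selections must be disjoint", class = "flycast_partition_error")
  }
  ia <- ia[x$element[ia] %in% elements_a]
  ib <- ib[x$element[ib] %in% elements_b]
  if (length(ia) == 0 || length(ib) == 0) return(0L)
  pa <- coords_any(x, ia)
  pb <- coords_any(x, ib)
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  hits <- d2 < cutoff^2
  if (level == "pairs") {
    sum(hits)
  } else {
    touched <- ib[colSums(hits) > 0]
    nrow(unique(tibble(chain = x$chain[touched], resno = x$resno[touched])))
  }
}

#' Per-frame contact count along a trajectory
#'
#' On CG trajectories every bead counts as a polar centre (element
#' filtering is skipped) - a stand-in convention for bead models.
#'
#' @param traj A `cg_trajectory`.
#' @param sel_a,sel_b Disjoint selections.
#' @param cutoff Distance cutoff (A).
#' @param level `"pairs"` or `"residues"`.
#' @return A `metric_series` (count).
#' @export
contact_count_series <- function(traj, sel_a, sel_b, cutoff = 3.5,
                                 level = "pairs") {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    st <- frame_structure(traj, f)
    as.numeric(contact_count(st, sel_a, sel_b, cutoff = cutoff,
                             level = level, elements = "C"))
  }, numeric(1))
  metric_series(traj$frames$step, vals, metric = "contact_count",
                units = "count", region = traj$frames$region,
                selection = paste(format(sel_a), format(sel_b)))
}

#' Capture radius along a trajectory
#'
#' The capture radius of a residue selection is its mass-weighted
#' radius of gyration, evaluated per frame; it measures the
#' conformational reach of a segment (the fly-casting observable). A
#' single-bead selection is rejected - its radius of gyration is
#' identically zero - with advice to widen the window (e.g. the
#' phospho-site residue plus/minus two neighbours).
#'
#' @param traj A `cg_trajectory`.
#' @param selection [atom_selection()] resolving to >= 2 beads.
#' @return A `metric_series` (angstrom).
#' @export
capture_radius_series <- function(traj, selection) {
  idx <- resolve_selection(traj$topology, strip_atoms(selection))
  if (length(idx) < 2) {
    abort(paste0(
      "Capture radius needs >= 2 beads (selection gives ", length(idx),
      "); for a single residue use a window, e.g. resno +/- 2"),
      class = "flycast_degenerate_selection")
  }
  mass <- traj$topology$mass[idx]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    gyration_radius(frame_coords(traj, f)[idx, , drop = FALSE], mass)
  }, numeric(1))
  metric_series(traj$frames$step, vals, metric = "capture_radius",
                units = "angstrom", region = traj$frames$region,
                selection = format(selection))
}
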
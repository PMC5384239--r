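# Superposition-based trajectory metrics: RMSD to a reference,
# per-segment RMSD after a common global fit, and per-residue RMSF.

# map trajectory beads onto reference CA atoms by (chain, resno);
# returns list(traj_idx, ref_xyz) for the residues in `sel`
map_beads_to_reference <- function(traj, reference, sel) {
  bidx <- resolve_selection(traj$topology, strip_atoms(sel))
  if (length(bidx) == 0) abort(paste0("Selection empty on trajectory: ",
                                      format(sel)),
                               class = "flycast_empty_selection")
  ca_sel <- atom_selection(sel$chain, sel$resno, "calpha")
  ridx <- resolve_selection(reference, ca_sel)
  key_t <- paste(traj$topology$chain[bidx], traj$topology$resno[bidx])
  key_r <- paste(reference$chain[ridx], reference$resno[ridx])
  common <- intersect(key_t, key_r)
  if (length(common) != length(key_t) || length(common) != length(key_r)) {
    abort(paste0("Selection resolves differently in trajectory (",
                 length(key_t), ") and reference (", length(key_r), ")"),
          class = "flycast_selection_mismatch")
  }
  list(traj_idx = bidx[match(common, key_t)],
       ref_xyz = coords(reference, ridx[match(common, key_r)]))
}

strip_atoms <- function(sel) atom_selection(sel$chain, sel$resno, "all")

#' Per-frame RMSD to a reference after least-squares superposition
#'
#' Each frame is superposed onto the reference over the fit selection
#' (CA atoms) with [kabsch_superpose()], then the RMSD is measured over
#' the measure selection.
#'
#' @param traj A `cg_trajectory`.
#' @param reference Reference structure (e.g. the native complex).
#' @param fit [atom_selection()] used for the superposition.
#' @param measure Selection the RMSD is reported over (default: `fit`).
#' @return A `metric_series` (angstrom).
#' @export
rmsd_series <- function(traj, reference, fit, measure = fit) {
  mf <- map_beads_to_reference(traj, reference, fit)
  mm <- map_beads_to_reference(traj, reference, measure)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    kf <- kabsch_superpose(xyz[mf$traj_idx, , drop = FALSE], mf$ref_xyz)
    moved <- apply_fit(xyz[mm$traj_idx, , drop = FALSE], kf)
    rmsd_raw(moved, mm$ref_xyz)
  }, numeric(1))
  metric_series(traj$frames$step, vals, metric = "rmsd",
                units = "angstrom", region = traj$frames$region,
                selection = format(measure))
}

#' Per-segment RMSD after one common global fit
#'
#' All segments are measured after the same per-frame superposition on
#' the fit selection, so segment values decompose the global RMSD:
#' the atom-count-weighted mean of squared segment RMSDs over a
#' partition equals the squared whole-selection RMSD.
#'
#' @param traj A `cg_trajectory`.
#' @param reference Reference structure.
#' @param fit Fit selection.
#' @param segments Named list of [atom_selection()]s (non-overlapping).
#' @return A `metric_series` in long form with a `segment` column.
#' @export
rmsd_by_segments <- function(traj, reference, fit, segments) {
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    names(segments) <- paste0("segment", seq_along(segments))
  }
  keys <- lapply(segments, function(s) {
    m <- map_beads_to_reference(traj, reference, s)
    if (length(m$traj_idx) == 0) abort("Empty segment")
    m
  })
  all_idx <- unlist(lapply(keys, `[[`, "traj_idx"))
  if (anyDuplicated(all_idx)) abort("Segments overlap")
  mf <- map_beads_to_reference(traj, reference, fit)
  out <- purrr::imap(keys, function(m, nm) {
    vals <- vapply(seq_len(n_frames(traj)), function(f) {
      xyz <- frame_coords(traj, f)
      kf <- kabsch_superpose(xyz[mf$traj_idx, , drop = FALSE], mf$ref_xyz)
      moved <- apply_fit(xyz[m$traj_idx, , drop = FALSE], kf)
      rmsd_raw(moved, m$ref_xyz)
    }, numeric(1))
    tibble(step = traj$frames$step, region = traj$frames$region,
           segment = nm, value = vals, n_atoms = length(m$traj_idx))
  })
  tb <- bind_rows(out)
  structure(tb, class = c("metric_series", class(tb)),
            metric = "rmsd_segments", units = "angstrom",
            selection = paste(names(segments), collapse = "+"))
}

#' Per-residue root-mean-square fluctuation
#'
#' After superposing every frame in the window onto a common reference
#' frame over the fit selection, the RMSF of each bead is the square
#' root of the time-mean squared deviation from its time-mean position.
#'
#' @param traj A `cg_trajectory`.
#' @param measure Selection of beads reported (default: all beads).
#' @param fit Fit selection, or `NULL` for no superposition (identity).
#' @param window `c(start_step, end_step)` limiting the frames used
#'   (inclusive; default: all frames).
#' @return A `metric_series` indexed by residue (columns `chain`,
#'   `resno`, `value`).
#' @export
rmsf <- function(traj, measure = NULL, fit = NULL, window = NULL) {
  frames_in <- seq_len(n_frames(traj))
  if (!is.null(window)) {
    frames_in <- which(traj$frames$step >= window[1] &
                         traj$frames$step <= window[2])
    if (length(frames_in) == 0) abort("Empty frame window")
  }
  top <- traj$topology
  midx <- if (is.null(measure)) seq_len(nrow(top)) else
    resolve_selection(top, strip_atoms(measure))
  if (length(midx) == 0) abort("Empty measure selection",
                               class = "flycast_empty_selection")
  fidx <- if (is.null(fit)) NULL else
    resolve_selection(top, strip_atoms(fit))
  ref_xyz <- frame_coords(traj, frames_in[1])
  aligned <- array(NA_real_, c(length(frames_in), length(midx), 3))
  for (k in seq_along(frames_in)) {
    xyz <- frame_coords(traj, frames_in[k])
    if (!is.null(fidx)) {
      kf <- kabsch_superpose(xyz[fidx, , drop = FALSE],
                             ref_xyz[fidx, , drop = FALSE])
      xyz <- apply_fit(xyz, kf)
    }
    aligned[k, , ] <- xyz[midx, , drop = FALSE]
  }
  mean_pos <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), mean_pos)^2
  vals <- sqrt(apply(dev2, 2, mean) * 3) # mean over frames & coords -> *3
  tb <- tibble(chain = top$chain[midx], resno = top$resno[midx],
               value = vals)
  structure(tb, class = c("metric_series", class(tb)),
            metric = "rmsf", units = "angstrom",
            selection = if (is.null(measure)) "all" else format(measure))
}
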
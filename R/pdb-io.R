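#' Read a PDB file into an atom table
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations
#' (highest occupancy wins; ties broken by altloc letter), drops waters
#' and heteroatoms not on the passlist, and assigns element masses.
#' Phosphothreonine (`TPO`) is retained as a polymer residue by default
#' so phospho-site selections work on crystal structures.
#'
#' @param path Path to a PDB file.
#' @param het_passlist HETATM residue names retained as polymer residues.
#' @param model Model number to read from a multi-model file (default 1).
#' @return A [as_structure()] tibble.
#' @export
read_pdb <- function(path, het_passlist = c("TPO"), model = 1) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "flycast_io_error")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("Cannot parse PDB '", path, "': ",
                                     conditionMessage(e)),
                              class = "flycast_format_error")
  )
  at <- as_tibble(pdb$atom)
  at <- pdb_atoms_to_structure(at, het_passlist = het_passlist, path = path)
  at$orig <- NULL
  as_structure(at, title = basename(path))
}

# shared post-processing of a bio3d atom table; keeps the original row
# index in column `orig` so multi-model coordinate columns can follow
pdb_atoms_to_structure <- function(at, het_passlist, path = "") {
  at$orig <- seq_len(nrow(at))
  water <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "DOD")
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & toupper(at$resid) %in% toupper(het_passlist))
  at <- at[keep & !(toupper(at$resid) %in% water), , drop = FALSE]
  if (nrow(at) == 0) {
    abort(paste0("No polymer atoms after filtering: ", path),
          class = "flycast_empty_structure")
  }
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  # altloc policy: keep the highest-occupancy variant, ties -> letter 'A'
  at <- at |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  if (any(blank)) {
    element[blank] <- vapply(at$elety[blank], function(e) {
      tryCatch(bio3d::atom2ele(e), error = function(err) NA_character_)
    }, character(1))
  }
  if (anyNA(element)) {
    abort(paste0("Cannot determine element for atom(s): ",
                 paste(unique(at$elety[is.na(element)]), collapse = ", ")),
          class = "flycast_unknown_element")
  }
  out <- tibble(
    chain = trimws(at$chain), resno = as.integer(at$resno),
    ins = trimws(at$insert), resname = trimws(at$resid),
    atom = trimws(at$elety), element = toupper(trimws(element)),
    x = at$x, y = at$y, z = at$z,
    mass = element_mass(toupper(trimws(element))),
    orig = at$orig
  )
  # sort as as_structure() will, so `orig` tracks the final atom order
  out[order(out$chain, out$resno, out$ins), , drop = FALSE]
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-width ATOM records with 3-decimal coordinates.
#'
#' @param x A `flycast_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  validate_structure(x)
  xyz <- coords(x)
  if (any(abs(xyz) >= 10000)) {
    abort("Coordinates exceed the fixed-width PDB field (|x| >= 10000 A)",
          class = "flycast_overflow_error")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    resno = x$resno, resid = x$resname, chain = x$chain,
    insert = ifelse(nzchar(x$ins), x$ins, ""),
    elety = x$atom, elesy = x$element,
    o = rep(1, nrow(x)), b = rep(0, nrow(x))
  )
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; beads are written as pseudo-atoms
#' named `CA`.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb_trajectory <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nf, 3 * nrow(top))
  for (f in seq_len(nf)) xyz[f, ] <- as.numeric(t(frame_coords(traj, f)))
  if (any(abs(xyz) >= 10000)) {
    abort("Coordinates exceed the fixed-width PDB field",
          class = "flycast_overflow_error")
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = top$resno, resid = top$resname, chain = top$chain,
    elety = rep("CA", nrow(top)), elesy = rep("C", nrow(top)),
    o = rep(1, nrow(top)), b = rep(0, nrow(top))
  )
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path Path to a multi-model PDB file.
#' @param het_passlist Passed on to the atom filter (see [read_pdb()]).
#' @return A `cg_trajectory` whose topology is the first model.
#' @export
read_pdb_trajectory <- function(path, het_passlist = c("TPO")) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("Cannot parse PDB '", path, "': ",
                                     conditionMessage(e)),
                              class = "flycast_format_error")
  )
  at <- pdb_atoms_to_structure(as_tibble(pdb$atom),
                               het_passlist = het_passlist, path = path)
  orig <- at$orig
  at$orig <- NULL
  nf <- nrow(pdb$xyz)
  arr <- array(NA_real_, c(nf, nrow(at), 3))
  for (f in seq_len(nf)) {
    m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    arr[f, , ] <- m[orig, , drop = FALSE]
  }
  # bead-per-residue files (CA pseudo-atoms only) carry residue masses
  if (all(at$atom == "CA")) {
    rm <- residue_mass(at$resname)
    at$mass <- ifelse(is.na(rm), at$mass, rm)
  }
  new_trajectory(
    topology = at[, c("chain", "resno", "resname", "mass")],
    coords = arr,
    frames = tibble(step = seq_len(nf) - 1L, region = NA_character_,
                    bias_energy = NA_real_, potential_energy = NA_real_),
    provenance = list(source = path)
  )
}
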
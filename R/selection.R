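#' Atom selections
#'
#' A selection names a chain, an optional set of residue numbers, and an
#' atom filter: `"all"`, `"calpha"`, `"sidechain"`, or an explicit
#' character vector of atom names. Selections are resolved against a
#' structure with [resolve_selection()], which never silently broadens:
#' an unknown chain is an error and an empty result is returned as a
#' zero-length index vector.
#'
#' @param chain Chain identifier (single string).
#' @param resno Integer vector of residue numbers, or `NULL` for the
#'   whole chain. Author numbering from the PDB file is used throughout.
#' @param atoms `"all"`, `"calpha"`, `"sidechain"`, or atom names.
#' @return An object of class `atom_selection`.
#' @export
#' @examples
#' helix9 <- atom_selection("A", 200:228, atoms = "calpha")
atom_selection <- function(chain, resno = NULL, atoms = "all") {
  stopifnot(is.character(chain), length(chain) == 1)
  if (!is.null(resno)) resno <- as.integer(resno)
  stopifnot(is.character(atoms), length(atoms) >= 1)
  structure(list(chain = chain, resno = resno, atoms = atoms),
            class = "atom_selection")
}

#' @export
format.atom_selection <- function(x, ...) {
  res <- if (is.null(x$resno)) "all residues" else
    paste0(length(x$resno), " residue(s)")
  paste0("<selection chain ", x$chain, ", ", res, ", atoms: ",
         paste(x$atoms, collapse = ","), ">")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN")

#' Resolve a selection to atom indices
#'
#' @param x A `flycast_structure` (or a CG bead table).
#' @param selection An [atom_selection()].
#' @return Integer vector of row indices into `x`, in storage order.
#'   Zero-length if the selection matches no atoms; unknown chains are
#'   an error.
#' @export
resolve_selection <- function(x, selection) {
  stopifnot(inherits(selection, "atom_selection"))
  if (!selection$chain %in% unique(x$chain)) {
    abort(paste0("Chain '", selection$chain, "' not present (has: ",
                 paste(unique(x$chain), collapse = ","), ")"),
          class = "flycast_unknown_chain")
  }
  idx <- which(x$chain == selection$chain)
  if (!is.null(selection$resno)) {
    idx <- idx[x$resno[idx] %in% selection$resno]
  }
  has_atom_col <- "atom" %in% names(x)
  a <- selection$atoms
  if (has_atom_col && !(length(a) == 1 && a == "all")) {
    nm <- x$atom[idx]
    keep <- if (length(a) == 1 && a == "calpha") {
      nm == "CA"
    } else if (length(a) == 1 && a == "sidechain") {
      !nm %in% .backbone_atoms
    } else {
      nm %in% a
    }
    idx <- idx[keep]
  }
  as.integer(idx)
}

# resolve, dropping hydrogens when policy = "heavy"
resolve_atoms <- function(x, selection, policy = c("heavy", "all", "calpha")) {
  policy <- match.arg(policy)
  if (policy == "calpha") {
    selection <- atom_selection(selection$chain, selection$resno, "calpha")
  }
  idx <- resolve_selection(x, selection)
  if (policy == "heavy" && "element" %in% names(x)) {
    idx <- idx[x$element[idx] != "H"]
  }
  idx
}
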
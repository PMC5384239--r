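#' Atom-table structures
#'
#' A structure is a tibble of atom records with one row per atom and the
#' columns `chain`, `resno`, `ins`, `resname`, `atom`, `element`, `x`,
#' `y`, `z`, `mass`. Coordinates are in angstrom, masses in dalton. All
#' geometry in the package operates on this table.
#'
#' @param atoms A data frame with the columns listed above (`ins` and
#'   `mass` may be omitted; insertion codes default to `""` and masses
#'   are assigned from the element table).
#' @param title Optional title string carried as an attribute.
#' @return A tibble of class `flycast_structure`.
#' @export
as_structure <- function(atoms, title = "") {
  atoms <- as_tibble(atoms)
  req <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing structure columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- element_mass(atoms$element)
  }
  atoms <- atoms[, c("chain", "resno", "ins", "resname", "atom",
                     "element", "x", "y", "z", "mass")]
  atoms$resno <- as.integer(atoms$resno)
  validate_structure(atoms)
  # stable sort: residues non-decreasing within a chain, atom order kept
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$ins), , drop = FALSE]
  structure(atoms,
            class = c("flycast_structure", class(as_tibble(atoms))),
            title = title)
}

validate_structure <- function(atoms) {
  if (nrow(atoms) == 0) {
    abort("Structure has zero atoms", class = "flycast_empty_structure")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("Non-finite coordinates in structure")
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("All atoms must have positive mass")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate atom record(s): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  invisible(atoms)
}

#' Extract the coordinate matrix of a structure
#'
#' @param x A `flycast_structure`.
#' @param indices Optional integer atom indices.
#' @return An n x 3 numeric matrix (angstrom).
#' @export
coords <- function(x, indices = NULL) {
  m <- as.matrix(x[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (!is.null(indices)) m <- m[indices, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#'
#' @param x A `flycast_structure`.
#' @param xyz An n x 3 matrix matching the atom count.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == nrow(x), ncol(xyz) == 3)
  x$x <- xyz[, 1]
  x$y <- xyz[, 2]
  x$z <- xyz[, 3]
  x
}

#' @export
print.flycast_structure <- function(x, ...) {
  title <- attr(x, "title")
  chains <- unique(x$chain)
  nres <- nrow(unique(x[, c("chain", "resno", "ins")]))
  cat(sprintf("<structure> %d atoms, %d residues, chain(s) %s%s\n",
              nrow(x), nres, paste(chains, collapse = ","),
              if (nzchar(title)) paste0(" - ", title) else ""))
  NextMethod()
}

# combine structures (e.g. two chains into a complex); chains must not clash
combine_structures <- function(a, b, title = "") {
  if (length(intersect(unique(a$chain), unique(b$chain))) > 0) {
    abort("Cannot combine structures sharing chain ids")
  }
  as_structure(bind_rows(as_tibble(a), as_tibble(b)), title = title)
}
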
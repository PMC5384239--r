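.max_seed <- 2147483647 # largest 32-bit R integer seed

# Element masses (Da) and van der Waals radii (angstrom).
# Radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80; H 1.10 (Bondi-style set).

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  "NA" = 22.990, K = 39.098, CL = 35.45, F = 18.998, BR = 79.904,
  I = 126.904
)

.vdw_radii <- c(
  H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

# Average amino-acid residue masses (Da), used as bead masses in the
# one-bead-per-residue model. TPO = phosphothreonine (Thr + HPO3).
.residue_masses <- c(
  ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY = 57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13,
  TPO = 181.08
)

element_mass <- function(element, context = NULL) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    abort(paste0(
      "Unknown element(s): ", paste(bad, collapse = ", "),
      if (!is.null(context)) paste0(" (", context, ")")
    ), class = "flycast_unknown_element")
  }
  unname(m)
}

element_vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    abort(paste0("No van der Waals radius for element(s): ",
                 paste(bad, collapse = ", ")),
          class = "flycast_unknown_element")
  }
  unname(r)
}

residue_mass <- function(resname) {
  m <- .residue_masses[toupper(resname)]
  unname(m) # NA for unknown residues; callers decide the fallback
}
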
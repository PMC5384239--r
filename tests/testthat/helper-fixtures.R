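# Shared fixture builders. Everything is generated in code; no data
# files are read from disk except those a test writes itself.

# write PDB text lines to a temp file, return the path
write_pdb_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, record = "ATOM", altloc = " ",
                          occ = 1.0) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, x, y, z, occ, 0, element)
}

# a small two-chain CA structure with deterministic coordinates
two_chain_structure <- function(n_a = 12, n_b = 8) {
  a <- ideal_ca_helix(n_a, chain = "A")
  b <- ideal_ca_helix(n_b, chain = "B")
  xyz <- coords(b)
  xyz[, 1] <- xyz[, 1] + 30
  combine_structures(a, set_coords(b, xyz))
}

# minimal CG system: two free single-bead chains at a given separation
# (no bonds, no contacts; the one repulsive pair is inactive beyond
# sigma) - used for restraint statistics
two_bead_system <- function(separation = 10) {
  st <- as_structure(tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 1L), ins = "",
    resname = "GLY", atom = "CA", element = "C",
    x = c(0, separation), y = 0, z = 0, mass = 57.05
  ))
  build_cg_system(st)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol)
}
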
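#' Deterministic checks against a 14-3-3/AANAT complex crystal structure
#'
#' Given a crystallographic complex of 14-3-3 (receptor) and a
#' phospho-Thr31 AANAT chain (ligand), recomputes three printed
#' reference quantities: the six residue-pair COM distances used as
#' native-complex restraint targets, the residue-level count of
#' phosphate contacts from pThr31 to the conserved basic triad (Lys49,
#' Arg56, Arg127), and the normalised complex SASA under the
#' monomer-sum convention. Supply the structure yourself (e.g. PDB
#' accession 1IB1, one 14-3-3 monomer plus one AANAT chain); the
#' package ships no crystallographic data.
#'
#' @param x A complex structure from [read_pdb()] (TPO retained), or a
#'   path to one.
#' @param receptor_chain,ligand_chain Chain ids of 14-3-3 and AANAT in
#'   the file.
#' @return A list with `com_distances` (tibble: the six pairs, measured
#'   distance and target), `phospho_contact_count`, `normalized_sasa`.
#' @export
crystal_complex_checks <- function(x, receptor_chain = "A",
                                   ligand_chain = "B") {
  if (is.character(x)) x <- read_pdb(x)
  tab <- native_distance_table_14_3_3(receptor_chain, ligand_chain)
  tab$measured <- vapply(seq_len(nrow(tab)), function(i) {
    com_distance(x, atom_selection(tab$chain_a[i], tab$res_a[i]),
                 atom_selection(tab$chain_b[i], tab$res_b[i]),
                 policy = "heavy")
  }, numeric(1))

  phospho_o <- atom_selection(ligand_chain, 31,
                              atoms = c("O1P", "O2P", "O3P", "OG1"))
  triad <- atom_selection(receptor_chain, c(49, 56, 127),
                          atoms = "sidechain")
  n_contacts <- contact_count(x, phospho_o, triad, cutoff = 3.5,
                              level = "residues",
                              elements_a = "O", elements_b = "N")

  nsasa <- normalized_complex_sasa(x, chains_a = receptor_chain,
                                   chains_b = ligand_chain)
  list(com_distances = tab, phospho_contact_count = n_contacts,
       normalized_sasa = nsasa)
}
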
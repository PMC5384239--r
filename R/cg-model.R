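#' Coarse-grained model parameters
#'
#' Reduced energy units with `k_B T = 1` at the reference temperature.
#' Defaults are conventional Go-model scales: stiff backbone bonds,
#' unit-depth native contact wells, and a soft excluded-volume radius
#' comparable to a residue diameter.
#'
#' @param k_bond Bond stiffness (energy / A^2).
#' @param eps_contact Native-contact well depth (energy).
#' @param eps_rep Excluded-volume strength (energy).
#' @param sigma Excluded-volume radius (A).
#' @param cutoff Native-contact cutoff on CA-CA distances (A).
#' @return A list of class `cg_params`.
#' @export
cg_params <- function(k_bond = 100, eps_contact = 1, eps_rep = 1,
                      sigma = 4.0, cutoff = 8.0) {
  p <- list(k_bond = k_bond, eps_contact = eps_contact,
            eps_rep = eps_rep, sigma = sigma, cutoff = cutoff)
  if (any(unlist(p) <= 0)) abort("All cg_params must be strictly positive")
  structure(p, class = "cg_params")
}

#' Build a one-bead-per-residue system from a structure
#'
#' Each residue becomes one bead at its CA position carrying the full
#' residue mass. Consecutive residues within a chain are bonded at their
#' observed CA-CA distance; residue pairs at sequence separation >= 3
#' whose CA distance is below `contact_cutoff` become Go-type native
#' contacts. Inter-chain contacts are included only when the source
#' structure is flagged as a complex reference.
#'
#' @param x A `flycast_structure` with a CA atom in every residue.
#' @param params [cg_params()].
#' @param contact_cutoff Native-contact cutoff (A).
#' @param complex_reference If `TRUE`, also build inter-chain contacts.
#' @param disordered Optional list with `chain` and `resno` naming
#'   residues of an intrinsically disordered segment; these beads get
#'   no native contacts (they stay bonded and repulsive only).
#' @param phospho Optional phosphorylation flag: a list with elements
#'   `chain`, `resno`, and optionally `window` (default 2), `pocket`
#'   (a data frame of chain/resno rows naming partner beads to attract),
#'   `pocket_d0` (A, default 5) and `pocket_eps` (default
#'   `params$eps_contact`). Removes the site's intra-chain native
#'   contacts within `resno +/- window` (local disorder release) and
#'   optionally adds attractive inter-chain contacts to the pocket.
#' @return A list of class `cg_system`: `beads` tibble, `bonds`,
#'   `contacts`, `rep_pairs`, `params`, `ref` coordinate matrix.
#' @export
build_cg_system <- function(x, params = cg_params(),
                            contact_cutoff = params$cutoff,
                            complex_reference = FALSE,
                            disordered = NULL, phospho = NULL) {
  res <- unique(as_tibble(x)[, c("chain", "resno", "ins", "resname")])
  ca_idx <- integer(nrow(res))
  for (i in seq_len(nrow(res))) {
    j <- which(x$chain == res$chain[i] & x$resno == res$resno[i] &
                 x$ins == res$ins[i] & x$atom == "CA")
    if (length(j) == 0) {
      abort(paste0("Residue ", res$chain[i], ":", res$resno[i],
                   res$ins[i], " (", res$resname[i], ") has no CA atom"),
            class = "flycast_build_error")
    }
    ca_idx[i] <- j[1]
  }
  if (nrow(res) < 2) abort("Need at least 2 residues to build a CG system",
                           class = "flycast_build_error")
  mass <- residue_mass(res$resname)
  # unknown residue names fall back to the summed atom masses
  for (i in which(is.na(mass))) {
    mass[i] <- sum(x$mass[x$chain == res$chain[i] & x$resno == res$resno[i]])
  }
  ref <- coords(x, ca_idx)
  beads <- tibble(chain = res$chain, resno = res$resno,
                  resname = res$resname, mass = mass,
                  x = ref[, 1], y = ref[, 2], z = ref[, 3])
  n <- nrow(beads)

  # bonds: consecutive residue numbers within a chain
  bi <- integer(0); bj <- integer(0)
  for (i in seq_len(n - 1)) {
    if (beads$chain[i + 1] == beads$chain[i] &&
        beads$resno[i + 1] == beads$resno[i] + 1L) {
      bi <- c(bi, i); bj <- c(bj, i + 1L)
    }
  }
  r0b <- sqrt(rowSums((ref[bi, , drop = FALSE] - ref[bj, , drop = FALSE])^2))
  if (any(r0b < 2.5 | r0b > 4.5)) {
    abort(paste0("Bond rest length outside [2.5, 4.5] A at bead(s) ",
                 paste(bi[r0b < 2.5 | r0b > 4.5], collapse = ",")),
          class = "flycast_build_error")
  }
  bonds <- tibble(i = bi, j = bj, r0 = r0b)

  # native contacts: |seq sep| >= 3 within a chain, CA distance < cutoff
  dm <- as.matrix(stats::dist(ref))
  same_chain <- outer(beads$chain, beads$chain, "==")
  seqsep <- abs(outer(beads$resno, beads$resno, "-"))
  upper <- upper.tri(dm)
  intra <- upper & same_chain & seqsep >= 3 & dm < contact_cutoff
  inter <- upper & !same_chain & dm < contact_cutoff & complex_reference
  sel <- which(intra | inter, arr.ind = TRUE)
  contacts <- tibble(i = as.integer(sel[, 1]), j = as.integer(sel[, 2]),
                     r0 = dm[sel], eps = params$eps_contact)

  if (!is.null(disordered)) {
    dz <- which(beads$chain == disordered$chain &
                  beads$resno %in% disordered$resno)
    contacts <- contacts[!(contacts$i %in% dz | contacts$j %in% dz), ,
                         drop = FALSE]
  }

  if (!is.null(phospho)) {
    contacts <- apply_phospho(contacts, beads, phospho, params)
  }

  # repulsion pair list: every i<j pair that is neither bonded nor a contact
  all_pairs <- which(upper, arr.ind = TRUE)
  tag <- function(i, j) i * (n + 1) + j
  excluded <- c(tag(bonds$i, bonds$j), tag(contacts$i, contacts$j))
  keep <- !tag(all_pairs[, 1], all_pairs[, 2]) %in% excluded
  rep_pairs <- cbind(i = as.integer(all_pairs[keep, 1]),
                     j = as.integer(all_pairs[keep, 2]))

  structure(list(beads = beads, bonds = bonds, contacts = contacts,
                 rep_pairs = rep_pairs, params = params, ref = ref,
                 phospho = phospho),
            class = "cg_system")
}

apply_phospho <- function(contacts, beads, phospho, params) {
  window <- phospho$window %||% 2L
  site <- which(beads$chain == phospho$chain & beads$resno == phospho$resno)
  if (length(site) != 1) {
    abort(paste0("Phospho site ", phospho$chain, ":", phospho$resno,
                 " not found among beads"), class = "flycast_build_error")
  }
  zone <- which(beads$chain == phospho$chain &
                  abs(beads$resno - phospho$resno) <= window)
  drop <- (contacts$i %in% zone | contacts$j %in% zone) &
    beads$chain[contacts$i] == beads$chain[contacts$j]
  contacts <- contacts[!drop, , drop = FALSE]
  if (!is.null(phospho$pocket)) {
    pk <- as_tibble(phospho$pocket)
    pidx <- vapply(seq_len(nrow(pk)), function(r) {
      w <- which(beads$chain == pk$chain[r] & beads$resno == pk$resno[r])
      if (length(w) != 1) abort(paste0("Pocket bead ", pk$chain[r], ":",
                                       pk$resno[r], " not found"),
                                class = "flycast_build_error")
      w
    }, integer(1))
    extra <- tibble(i = pmin(site, pidx), j = pmax(site, pidx),
                    r0 = phospho$pocket_d0 %||% 5,
                    eps = phospho$pocket_eps %||% params$eps_contact)
    contacts <- bind_rows(contacts, extra)
  }
  contacts
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf(
    "<cg_system> %d beads (%s), %d bonds, %d contacts, %d repulsive pairs\n",
    nrow(x$beads), paste(unique(x$beads$chain), collapse = ","),
    nrow(x$bonds), nrow(x$contacts), nrow(x$rep_pairs)))
  invisible(x)
}

#' Potential energy and forces of a CG configuration
#'
#' Energy terms: harmonic bonds `1/2 k (r - r0)^2`; native contacts as
#' 12-10 wells `eps (5 (r0/r)^12 - 6 (r0/r)^10)` with minimum `-eps` at
#' `r0`; and pairwise repulsion `eps_rep ((sigma/r)^12 - 1)` truncated
#' (and continuous) at `sigma` for all other pairs. Forces are the exact
#' negative gradient.
#'
#' @param system A `cg_system`.
#' @param xyz n x 3 coordinate matrix (defaults to the reference).
#' @return List with `energy` (scalar) and `forces` (n x 3 matrix).
#' @export
potential_energy_forces <- function(system, xyz = system$ref) {
  n <- nrow(system$beads)
  if (!is.matrix(xyz) || nrow(xyz) != n || ncol(xyz) != 3) {
    abort(sprintf("Coordinates must be a %d x 3 matrix", n),
          class = "flycast_shape_error")
  }
  energy <- 0
  forces <- matrix(0, n, 3)

  acc <- function(i, j, fvec) {
    # fvec is the force on i; -fvec acts on j
    s <- rowsum(rbind(fvec, -fvec), group = c(i, j))
    rows <- as.integer(rownames(s))
    forces[rows, ] <<- forces[rows, , drop = FALSE] + s
  }

  b <- system$bonds
  if (nrow(b) > 0) {
    dv <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    k <- system$params$k_bond
    energy <- energy + sum(0.5 * k * (r - b$r0)^2)
    dEdr <- k * (r - b$r0)
    acc(b$i, b$j, dv * (-dEdr / r))
  }

  ct <- system$contacts
  if (nrow(ct) > 0) {
    dv <- xyz[ct$i, , drop = FALSE] - xyz[ct$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    q <- ct$r0 / r
    energy <- energy + sum(ct$eps * (5 * q^12 - 6 * q^10))
    dEdr <- (60 * ct$eps / r) * (q^10 - q^12)
    acc(ct$i, ct$j, dv * (-dEdr / r))
  }

  rp <- system$rep_pairs
  if (nrow(rp) > 0) {
    dv <- xyz[rp[, 1], , drop = FALSE] - xyz[rp[, 2], , drop = FALSE]
    r2 <- rowSums(dv^2)
    sig <- system$params$sigma
    close <- which(r2 < sig^2)
    if (length(close) > 0) {
      r <- sqrt(r2[close])
      er <- system$params$eps_rep
      q12 <- (sig / r)^12
      energy <- energy + sum(er * (q12 - 1))
      dEdr <- -12 * er * q12 / r
      acc(rp[close, 1], rp[close, 2], dv[close, , drop = FALSE] * (-dEdr / r))
    }
  }

  list(energy = energy, forces = forces)
}

#' @exportS3Method generics::glance
glance.cg_system <- function(x, ...) {
  tibble(n_beads = nrow(x$beads), n_chains = length(unique(x$beads$chain)),
         n_bonds = nrow(x$bonds), n_contacts = nrow(x$contacts),
         sigma = x$params$sigma, k_bond = x$params$k_bond,
         phosphorylated = !is.null(x$phospho))
}

#' @exportS3Method generics::tidy
tidy.cg_system <- function(x, ...) x$beads

#' Write / read a plain-text CG topology
#'
#' Sections `[beads]`, `[bonds]`, `[contacts]`, `[params]`,
#' tab-separated. Reference coordinates travel in the bead table.
#'
#' @param system A `cg_system`.
#' @param path File path.
#' @return `write_cg_topology` returns `path` invisibly;
#'   `read_cg_topology` returns a `cg_system`.
#' @export
write_cg_topology <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines("# flycast cg topology v1", con)
  writeLines("[params]", con)
  for (nm in names(system$params)) w(nm, format(system$params[[nm]]))
  writeLines("[beads]", con)
  b <- system$beads
  for (i in seq_len(nrow(b))) {
    w(b$chain[i], b$resno[i], b$resname[i], format(b$mass[i]),
      sprintf("%.6f", b$x[i]), sprintf("%.6f", b$y[i]),
      sprintf("%.6f", b$z[i]))
  }
  writeLines("[bonds]", con)
  for (i in seq_len(nrow(system$bonds))) {
    w(system$bonds$i[i], system$bonds$j[i],
      sprintf("%.6f", system$bonds$r0[i]))
  }
  writeLines("[contacts]", con)
  for (i in seq_len(nrow(system$contacts))) {
    w(system$contacts$i[i], system$contacts$j[i],
      sprintf("%.6f", system$contacts$r0[i]),
      format(system$contacts$eps[i]))
  }
  invisible(path)
}

#' @rdname write_cg_topology
#' @export
read_cg_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  sec <- cumsum(grepl("^\\[", lines))
  names_sec <- gsub("\\[|\\]", "", lines[grepl("^\\[", lines)])
  blocks <- split(lines[!grepl("^\\[", lines)],
                  factor(names_sec[sec[!grepl("^\\[", lines)]],
                         levels = names_sec))
  parse_tsv <- function(v) if (length(v) == 0) character(0) else
    do.call(rbind, strsplit(v, "\t", fixed = TRUE))
  pm <- parse_tsv(blocks$params)
  params <- do.call(cg_params, as.list(setNames(as.numeric(pm[, 2]),
                                                pm[, 1])))
  bm <- parse_tsv(blocks$beads)
  beads <- tibble(chain = bm[, 1], resno = as.integer(bm[, 2]),
                  resname = bm[, 3], mass = as.numeric(bm[, 4]),
                  x = as.numeric(bm[, 5]), y = as.numeric(bm[, 6]),
                  z = as.numeric(bm[, 7]))
  ref <- as.matrix(beads[, c("x", "y", "z")]) |> unname()
  bo <- parse_tsv(blocks$bonds)
  bonds <- if (length(bo) == 0) tibble(i = integer(), j = integer(),
                                       r0 = numeric()) else
    tibble(i = as.integer(bo[, 1]), j = as.integer(bo[, 2]),
           r0 = as.numeric(bo[, 3]))
  co <- parse_tsv(blocks$contacts)
  contacts <- if (length(co) == 0)
    tibble(i = integer(), j = integer(), r0 = numeric(), eps = numeric())
  else tibble(i = as.integer(co[, 1]), j = as.integer(co[, 2]),
              r0 = as.numeric(co[, 3]), eps = as.numeric(co[, 4]))
  n <- nrow(beads)
  upper <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tagf <- function(i, j) i * (n + 1) + j
  excluded <- c(tagf(bonds$i, bonds$j), tagf(contacts$i, contacts$j))
  keep <- !tagf(upper[, 1], upper[, 2]) %in% excluded
  structure(list(beads = beads, bonds = bonds, contacts = contacts,
                 rep_pairs = cbind(i = as.integer(upper[keep, 1]),
                                   j = as.integer(upper[keep, 2])),
                 params = params, ref = ref, phospho = NULL),
            class = "cg_system")
}
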
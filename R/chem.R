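# Low-level chemistry backend.
#
# All SMILES parsing, canonicalization, descriptor, SMARTS and fingerprint
# calculations are delegated to Open Babel via ChemmineOB. Molecular graphs
# are handled in-package as plain atom/bond tables serialized to V2000
# molfiles, which is the exchange format used to talk to Open Babel for
# fragment cutting and core/substituent reassembly.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES. Invalid strings yield
#' `NA` instead of an error, so callers can report parse failures per record.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\tx\n")),
      error = function(e) ""
    )
    if (!nzchar(out)) return(NA_character_)
    sub("[\t\n].*$", "", out)
  }, character(1), USE.NAMES = FALSE)
}

#' Test SMILES validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector; `TRUE` where the string parses to a molecule.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# Apply an Open Babel per-molecule function over a vector of valid SMILES.
# All inputs must parse; validate with is_valid_smiles() first.
ob_apply <- function(smiles, f) {
  stopifnot(length(smiles) >= 1L)
  input <- paste0(smiles, "\tm", seq_along(smiles), collapse = "\n")
  ChemmineOB::forEachMol("SMILES", input, f)
}

# Count unique SMARTS matches per molecule.
smarts_count <- function(smiles, smarts) {
  if (length(smiles) == 0L) return(integer(0))
  mols <- ob_apply(smiles, identity)
  if (!is.list(mols)) mols <- list(mols)
  res <- ChemmineOB::smartsSearch_OB(mols, smarts, uniqueMatches = TRUE)
  as.integer(unlist(res, use.names = FALSE))
}

# Physicochemical property table from Open Babel (MW, logP, TPSA, HBD, HBA1...).
ob_properties <- function(smiles) {
  if (length(smiles) == 0L) return(data.frame())
  res <- ob_apply(smiles, function(m) ChemmineOB::prop_OB(m))
  do.call(rbind, res)
}

## ---- molfile-backed molecular graphs ----------------------------------

# A `molgraph` is a list with:
#   elements: character vector of atomic symbols ("*" marks attachment points)
#   charges:  integer vector of formal charges
#   bonds:    integer matrix with columns a, b, order (1-based atom indices)

molgraph <- function(elements, charges, bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "order")))
  structure(list(elements = elements, charges = as.integer(charges),
                 bonds = bonds), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", length(x$elements), " atoms, ", nrow(x$bonds),
      " bonds\n", sep = "")
  invisible(x)
}

n_heavy_atoms <- function(mol) sum(mol$elements != "*" & mol$elements != "H")

parse_molfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- integer(n_atoms)
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- cbind(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- matrix(integer(0), ncol = 3)
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fields <- scan(text = sub("^M  CHG", "", ln), quiet = TRUE)
    n <- fields[1]
    for (i in seq_len(n)) charges[fields[2 * i]] <- fields[2 * i + 1]
  }
  molgraph(elements, charges, bonds)
}

write_molfile <- function(mol, title = "mol") {
  n_atoms <- length(mol$elements)
  n_bonds <- nrow(mol$bonds)
  header <- c(title, "  comodiag", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n_atoms, n_bonds))
  atoms <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    mol$elements)
  bonds <- if (n_bonds > 0) {
    sprintf("%3d%3d%3d  0  0  0  0",
            mol$bonds[, "a"], mol$bonds[, "b"], mol$bonds[, "order"])
  } else character(0)
  chg <- which(mol$charges != 0L)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, mol$charges[chg]), collapse = ""))
  } else character(0)
  paste0(paste(c(header, atoms, bonds, chg_lines, "M  END", "$$$$"),
               collapse = "\n"), "\n")
}

#' Parse a SMILES string into an editable molecular graph
#'
#' @param smiles A single valid SMILES string (may contain `*` attachment
#'   points).
#' @return A `molgraph` object (atom/bond tables).
#' @export
mol_from_smiles <- function(smiles) {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tx\n"))
  if (!nzchar(sdf)) stop("invalid SMILES: ", smiles)
  parse_molfile(sdf)
}

#' Write a molecular graph back to (canonical) SMILES
#'
#' @param mol A `molgraph`.
#' @param canonical Emit canonical SMILES (default) or input-order SMILES.
#' @return A SMILES string, `NA` if Open Babel rejects the graph.
#' @export
mol_to_smiles <- function(mol, canonical = TRUE) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", if (canonical) "CAN" else "SMI",
                              write_molfile(mol)),
    error = function(e) ""
  )
  if (!nzchar(out)) return(NA_character_)
  sub("[\t\n].*$", "", out)
}

mol_igraph <- function(mol) {
  igraph::graph_from_edgelist(mol$bonds[, c("a", "b"), drop = FALSE],
                              directed = FALSE)
}

# Indices of bonds not contained in any ring (graph bridges).
acyclic_bond_indices <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(integer(0))
  g <- mol_igraph(mol)
  if (igraph::vcount(g) < length(mol$elements)) {
    g <- igraph::add_vertices(g, length(mol$elements) - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  sort(as.integer(br))
}

# Logical vector: atom participates in at least one ring bond.
ring_atoms <- function(mol) {
  inring <- rep(FALSE, length(mol$elements))
  if (nrow(mol$bonds) == 0L) return(inring)
  cyclic <- setdiff(seq_len(nrow(mol$bonds)), acyclic_bond_indices(mol))
  inring[as.vector(mol$bonds[cyclic, c("a", "b")])] <- TRUE
  inring
}

# Connected component id per atom.
atom_components <- function(mol) {
  n <- length(mol$elements)
  if (nrow(mol$bonds) == 0L) return(seq_len(n))
  g <- mol_igraph(mol)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$membership
}

# Extract the sub-molecule on `atoms`, adding one "*" attachment atom bonded
# to each entry of `attach_to` (indices into the original molecule).
mol_subgraph <- function(mol, atoms, attach_to = integer(0)) {
  atoms <- sort(atoms)
  remap <- match(seq_along(mol$elements), atoms)
  keep <- mol$bonds[, "a"] %in% atoms & mol$bonds[, "b"] %in% atoms
  bonds <- mol$bonds[keep, , drop = FALSE]
  bonds[, "a"] <- remap[bonds[, "a"]]
  bonds[, "b"] <- remap[bonds[, "b"]]
  elements <- mol$elements[atoms]
  charges <- mol$charges[atoms]
  dummy_idx <- integer(length(attach_to))
  for (i in seq_along(attach_to)) {
    elements <- c(elements, "*")
    charges <- c(charges, 0L)
    dummy_idx[i] <- length(elements)
    bonds <- rbind(bonds, c(remap[attach_to[i]], length(elements), 1L))
  }
  out <- molgraph(elements, charges, bonds)
  attr(out, "dummy_atoms") <- dummy_idx
  out
}

# Cut a set of acyclic bonds. A valid decomposition is star-shaped: one
# component (the core) touches every cut and each remaining component
# (a substituent) touches exactly one. Several components may qualify as
# the core (always two for a single cut); one decomposition is returned
# per valid core choice. Returns a (possibly empty) list.
cut_to_core <- function(mol, bond_idx) {
  cuts <- mol$bonds[bond_idx, , drop = FALSE]
  rest <- molgraph(mol$elements, mol$charges,
                   mol$bonds[-bond_idx, , drop = FALSE])
  comp <- atom_components(rest)
  ends <- rbind(cuts[, "a"], cuts[, "b"])
  # component x cut incidence
  touched <- lapply(seq_len(max(comp)), function(k) {
    which(apply(ends, 2, function(e) any(comp[e] == k)))
  })
  n_touch <- lengths(touched)
  candidates <- which(n_touch == length(bond_idx))
  out <- list()
  for (core_comp in candidates) {
    sub_comps <- setdiff(which(n_touch > 0L), core_comp)
    if (any(n_touch[sub_comps] != 1L)) next
    if (length(sub_comps) != length(bond_idx)) next
    core_attach <- integer(length(bond_idx))
    sub_mols <- vector("list", length(bond_idx))
    ok <- TRUE
    for (i in seq_len(length(bond_idx))) {
      e <- ends[, i]
      core_end <- e[comp[e] == core_comp]
      if (length(core_end) != 1L) { ok <- FALSE; break }
      sub_end <- setdiff(e, core_end)
      core_attach[i] <- core_end
      sub_atoms <- which(comp == comp[sub_end])
      sub_mols[[i]] <- mol_subgraph(mol, sub_atoms, attach_to = sub_end)
    }
    if (!ok) next
    core <- mol_subgraph(mol, which(comp == core_comp),
                         attach_to = core_attach)
    out[[length(out) + 1L]] <- list(core = core, substituents = sub_mols)
  }
  out
}

# Canonical signature of one attachment site: the core SMILES with that
# site marked by a xenon probe atom (an element never used in fragments).
site_signature <- function(core_mol, dummy_atom) {
  m <- core_mol
  m$elements[dummy_atom] <- "Xe"
  mol_to_smiles(m)
}

# Merge substituent fragments onto a core. `core` is a molgraph whose "*"
# atoms (in `site_dummies` order) are replaced by the fragments; a fragment
# of "H" deletes the attachment point (implicit hydrogen).
assemble_molgraph <- function(core, site_dummies, fragment_mols) {
  stopifnot(length(site_dummies) == length(fragment_mols))
  elements <- core$elements
  charges <- core$charges
  bonds <- core$bonds
  drop_atoms <- integer(0)
  for (i in seq_along(site_dummies)) {
    d <- site_dummies[i]
    frag <- fragment_mols[[i]]
    if (is.character(frag) && identical(frag, "H")) {
      drop_atoms <- c(drop_atoms, d)
      next
    }
    fd <- which(frag$elements == "*")
    if (length(fd) != 1L)
      stop("substituent fragment must have exactly one attachment point")
    frag_attach <- unique(c(
      frag$bonds[frag$bonds[, "a"] == fd, "b"],
      frag$bonds[frag$bonds[, "b"] == fd, "a"]))
    offset <- length(elements)
    elements <- c(elements, frag$elements)
    charges <- c(charges, frag$charges)
    fb <- frag$bonds
    fb[, c("a", "b")] <- fb[, c("a", "b")] + offset
    core_attach <- unique(c(
      bonds[bonds[, "a"] == d, "b"], bonds[bonds[, "b"] == d, "a"]))
    bonds <- rbind(bonds, fb,
                   c(core_attach, frag_attach + offset, 1L))
    drop_atoms <- c(drop_atoms, d, fd + offset)
  }
  keep <- setdiff(seq_along(elements), drop_atoms)
  remap <- match(seq_along(elements), keep)
  keep_bond <- !(bonds[, "a"] %in% drop_atoms | bonds[, "b"] %in% drop_atoms)
  bonds <- bonds[keep_bond, , drop = FALSE]
  bonds[, "a"] <- remap[bonds[, "a"]]
  bonds[, "b"] <- remap[bonds[, "b"]]
  molgraph(elements[keep], charges[keep], bonds)
}
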
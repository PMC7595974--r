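# Analog series: core scaffolds, retrosynthetic fragmentation, series
# extraction and substituent pools.
#
# A series is a set of compounds sharing one core scaffold with labeled
# attachment sites; each analog is the core plus one substituent (or H)
# per site. Fragmentation cuts acyclic single bonds matching a
# configurable rule set of common retrosynthetic disconnections.

## ---- fragmentation rule set -------------------------------------------

# Bond-environment helpers used by rules. `adj` is the neighbor list with
# bond orders; all predicates receive the two bond endpoints a, b.
atom_has_double <- function(mol, adj, atom, neighbor_element) {
  nb <- adj[[atom]]
  any(mol$elements[nb$atom] == neighbor_element & nb$order == 2)
}

adjacency <- function(mol) {
  adj <- rep(list(list(atom = integer(0), order = integer(0))),
             length(mol$elements))
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds[i, "a"]; b <- mol$bonds[i, "b"]
    o <- mol$bonds[i, "order"]
    adj[[a]]$atom <- c(adj[[a]]$atom, b); adj[[a]]$order <- c(adj[[a]]$order, o)
    adj[[b]]$atom <- c(adj[[b]]$atom, a); adj[[b]]$order <- c(adj[[b]]$order, o)
  }
  adj
}

#' Default retrosynthetic disconnection rules
#'
#' A configurable list of named bond-environment patterns. Each rule is a
#' predicate over an acyclic single bond (endpoints a, b) of a molecular
#' graph. The shipped default covers the common disconnections: amide,
#' ester, sulfonamide, amine, ether, and ring-to-chain (aryl/alkyl) bonds.
#'
#' @return Named list of rule functions `f(mol, adj, ring, a, b)`.
#' @export
default_rule_set <- function() {
  list(
    amide = function(mol, adj, ring, a, b) {
      (mol$elements[a] == "C" && mol$elements[b] == "N" &&
         atom_has_double(mol, adj, a, "O")) ||
        (mol$elements[b] == "C" && mol$elements[a] == "N" &&
           atom_has_double(mol, adj, b, "O"))
    },
    ester = function(mol, adj, ring, a, b) {
      (mol$elements[a] == "C" && mol$elements[b] == "O" &&
         atom_has_double(mol, adj, a, "O")) ||
        (mol$elements[b] == "C" && mol$elements[a] == "O" &&
           atom_has_double(mol, adj, b, "O"))
    },
    sulfonamide = function(mol, adj, ring, a, b) {
      (mol$elements[a] == "S" && mol$elements[b] == "N" &&
         atom_has_double(mol, adj, a, "O")) ||
        (mol$elements[b] == "S" && mol$elements[a] == "N" &&
           atom_has_double(mol, adj, b, "O"))
    },
    amine = function(mol, adj, ring, a, b) {
      els <- mol$elements[c(a, b)]
      "C" %in% els && "N" %in% els &&
        !atom_has_double(mol, adj, a, "O") &&
        !atom_has_double(mol, adj, b, "O")
    },
    ether = function(mol, adj, ring, a, b) {
      els <- mol$elements[c(a, b)]
      "C" %in% els && "O" %in% els &&
        !atom_has_double(mol, adj, a, "O") &&
        !atom_has_double(mol, adj, b, "O")
    },
    ring_chain = function(mol, adj, ring, a, b) {
      xor(ring[a], ring[b])
    }
  )
}

# Indices of acyclic single bonds matched by at least one rule.
matched_bonds <- function(mol, rule_set = default_rule_set()) {
  acyc <- acyclic_bond_indices(mol)
  acyc <- acyc[mol$bonds[acyc, "order"] == 1L]
  if (length(acyc) == 0L) return(integer(0))
  adj <- adjacency(mol)
  ring <- ring_atoms(mol)
  hits <- vapply(acyc, function(i) {
    a <- mol$bonds[i, "a"]; b <- mol$bonds[i, "b"]
    if (mol$elements[a] == "*" || mol$elements[b] == "*") return(FALSE)
    any(vapply(rule_set, function(rule) isTRUE(rule(mol, adj, ring, a, b)),
               logical(1)))
  }, logical(1))
  acyc[hits]
}

# Memoized fragment graph parsing (assembly hot path).
.fragment_cache <- new.env(parent = emptyenv())
fragment_mol <- function(smiles) {
  if (identical(smiles, "H")) return("H")
  key <- smiles
  if (!exists(key, envir = .fragment_cache)) {
    assign(key, mol_from_smiles(smiles), envir = .fragment_cache)
  }
  get(key, envir = .fragment_cache)
}

## ---- fragmentation ----------------------------------------------------

#' Fragment a compound into core + substituent candidates
#'
#' Enumerates decompositions obtained by cutting 1..`max_sites` acyclic
#' single bonds matching the rule set, such that one fragment (the core)
#' touches every cut and each remaining fragment (a substituent) touches
#' exactly one. Reassembling any decomposition regenerates the input
#' molecule (canonical-SMILES equality). A molecule with no rule-matching
#' bonds yields the single trivial decomposition (itself as core).
#'
#' @param smiles A valid SMILES string.
#' @param rule_set Rules from [default_rule_set()] or compatible.
#' @param max_sites Maximum number of cuts (attachment sites).
#' @param max_substituent_atoms Heavy-atom cap per substituent fragment.
#' @return List of decompositions, each with `core_smiles` (canonical,
#'   `*` marking sites), ordered `site_signatures`, `substituents`
#'   (canonical fragment SMILES aligned with sites) and `core_heavy`.
#'   The core is the dominant fragment: decompositions whose core has
#'   fewer heavy atoms than one of its substituents are discarded.
#' @export
fragment_compound <- function(smiles, rule_set = default_rule_set(),
                              max_sites = 4L, max_substituent_atoms = 13L) {
  mol <- mol_from_smiles(smiles)
  cuttable <- matched_bonds(mol, rule_set)
  decomps <- list()
  if (length(cuttable)) {
    for (k in seq_len(min(max_sites, length(cuttable)))) {
      for (subset in utils::combn(length(cuttable), k, simplify = FALSE)) {
        for (dec in cut_to_core(mol, cuttable[subset])) {
          heavy <- vapply(dec$substituents, n_heavy_atoms, numeric(1))
          if (any(heavy > max_substituent_atoms)) next
          if (n_heavy_atoms(dec$core) < max(heavy)) next
          dummies <- which(dec$core$elements == "*")
          sigs <- vapply(dummies, function(d) site_signature(dec$core, d),
                         character(1))
          subs <- vapply(dec$substituents, mol_to_smiles, character(1))
          ord <- order(sigs, subs, method = "radix")
          decomps[[length(decomps) + 1L]] <- list(
            core_smiles = mol_to_smiles(dec$core),
            site_signatures = sigs[ord],
            substituents = canonical_smiles(subs[ord]),
            core_heavy = n_heavy_atoms(dec$core))
        }
      }
    }
  }
  if (length(decomps) == 0L) {
    decomps <- list(list(core_smiles = canonical_smiles(smiles),
                         site_signatures = character(0),
                         substituents = character(0),
                         core_heavy = n_heavy_atoms(mol)))
  }
  # one decomposition per distinct core
  keep <- !duplicated(vapply(decomps, `[[`, character(1), "core_smiles"))
  decomps[keep]
}

## ---- core scaffolds and series ----------------------------------------

#' Define a core scaffold with labeled substitution sites
#'
#' @param core_smiles SMILES with `*` atoms marking attachment points.
#' @return A `core_scaffold`: parsed graph, site atom indices and
#'   canonical per-site signatures (sites ordered by signature).
#' @export
core_scaffold <- function(core_smiles) {
  can <- canonical_smiles(core_smiles)
  if (is.na(can)) stop("core SMILES does not parse: ", core_smiles)
  mol <- mol_from_smiles(can)
  dummies <- which(mol$elements == "*")
  if (length(dummies) == 0L)
    stop("core has no attachment points (no '*' atoms)")
  sigs <- vapply(dummies, function(d) site_signature(mol, d), character(1))
  ord <- order(sigs, dummies, method = "radix")
  structure(list(smiles = can, mol = mol,
                 site_dummies = dummies[ord],
                 site_signatures = sigs[ord],
                 n_sites = length(dummies)),
            class = "core_scaffold")
}

#' @export
print.core_scaffold <- function(x, ...) {
  cat("<core_scaffold> ", x$smiles, " (", x$n_sites, " sites)\n", sep = "")
  invisible(x)
}

#' Assemble an analog from a core and per-site substituents
#'
#' @param core A `core_scaffold` (or `analog_series`).
#' @param substituents Character vector of fragment SMILES (single `*`
#'   attachment point each) or `"H"`, one per site, in site order.
#' @return Canonical SMILES of the assembled molecule.
#' @export
assemble_analog <- function(core, substituents) {
  if (inherits(core, "analog_series")) core <- core$core
  stopifnot(inherits(core, "core_scaffold"),
            length(substituents) == core$n_sites)
  frags <- lapply(substituents, fragment_mol)
  mol <- assemble_molgraph(core$mol, core$site_dummies, frags)
  mol_to_smiles(mol)
}

#' Construct an analog series
#'
#' @param core A `core_scaffold` or core SMILES.
#' @param analogs data.frame with columns `id`, `potency` and per-site
#'   substituent columns `sub_1..sub_k` (fragment SMILES or `"H"`).
#'   A `smiles` column, if present, is checked against reassembly.
#' @param target_name Optional biological target label.
#' @return An `analog_series`.
#' @export
analog_series <- function(core, analogs, target_name = "") {
  if (!inherits(core, "core_scaffold")) core <- core_scaffold(core)
  sub_cols <- paste0("sub_", seq_len(core$n_sites))
  stopifnot(all(c("id", sub_cols) %in% names(analogs)))
  if (!"potency" %in% names(analogs)) analogs$potency <- NA_real_
  asm <- vapply(seq_len(nrow(analogs)), function(i) {
    assemble_analog(core, unlist(analogs[i, sub_cols], use.names = FALSE))
  }, character(1))
  if ("smiles" %in% names(analogs)) {
    bad <- which(canonical_smiles(analogs$smiles) != asm)
    if (length(bad))
      stop("analog(s) do not reassemble from core + substituents: ",
           paste(analogs$id[bad], collapse = ", "))
  }
  analogs$smiles <- asm
  if (anyDuplicated(analogs$id))
    stop("duplicate analog identifiers")
  structure(list(core = core,
                 analogs = analogs[, c("id", "smiles", "potency", sub_cols)],
                 target_name = target_name),
            class = "analog_series")
}

#' @export
print.analog_series <- function(x, ...) {
  cat("<analog_series> ", nrow(x$analogs), " analogs on core ",
      x$core$smiles, " (", x$core$n_sites, " sites)",
      if (nzchar(x$target_name)) paste0(" [", x$target_name, "]") else "",
      "\n", sep = "")
  invisible(x)
}

# Match one compound onto a given core: find per-site substituents (H at
# unused sites) whose assembly reproduces the compound. Returns a named
# character vector of length n_sites, or NULL.
match_to_core <- function(core, smiles, rule_set = default_rule_set()) {
  can <- canonical_smiles(smiles)
  decomps <- fragment_compound(can, rule_set, max_sites = core$n_sites)
  # include the fully-H case: compound equals the bare core
  decomps <- c(decomps, list(list(core_smiles = can,
                                  substituents = character(0))))
  for (dec in decomps) {
    subs <- dec$substituents
    j <- length(subs)
    if (j > core$n_sites) next
    site_sets <- utils::combn(core$n_sites, max(j, 1), simplify = FALSE)
    if (j == 0L) site_sets <- list(integer(0))
    perms <- permutations(j)
    for (sites in site_sets) {
      for (p in perms) {
        assign_vec <- rep("H", core$n_sites)
        if (j > 0) assign_vec[sites] <- subs[p]
        if (identical(assemble_analog(core, assign_vec), can))
          return(assign_vec)
      }
    }
  }
  NULL
}

permutations <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

#' Build a series from an explicit core and a compound table
#'
#' Each compound is fragmented and matched onto the core; compounds that
#' cannot be expressed as core + per-site substituents are excluded with
#' a warning.
#'
#' @param core A `core_scaffold` or core SMILES with `*` sites.
#' @param compounds Compound table (id, smiles, potency).
#' @param rule_set Fragmentation rules.
#' @param target_name Optional target label.
#' @return An `analog_series`.
#' @export
series_from_core <- function(core, compounds,
                             rule_set = default_rule_set(),
                             target_name = "") {
  if (!inherits(core, "core_scaffold")) core <- core_scaffold(core)
  rows <- list()
  unmatched <- character(0)
  for (i in seq_len(nrow(compounds))) {
    subs <- match_to_core(core, compounds$smiles[i], rule_set)
    if (is.null(subs)) {
      unmatched <- c(unmatched, compounds$id[i])
      next
    }
    row <- data.frame(id = compounds$id[i],
                      potency = compounds$potency[i],
                      stringsAsFactors = FALSE)
    for (s in seq_along(subs)) row[[paste0("sub_", s)]] <- subs[s]
    rows[[length(rows) + 1L]] <- row
  }
  if (length(unmatched))
    warning("compound(s) not matching the core, excluded: ",
            paste(unmatched, collapse = ", "))
  if (length(rows) == 0L) stop("no compounds match the core")
  analog_series(core, do.call(rbind, rows), target_name)
}

#' Extract analog series from a compound set
#'
#' Groups compounds sharing an identical canonical core (same attachment
#' topology). Each compound is assigned to at most one series: the core
#' matched by the most compounds wins, ties broken by larger core
#' heavy-atom count, then lexicographic canonical SMILES. After grouping,
#' remaining compounds are absorbed into a series when they match its
#' core with H at unused sites.
#'
#' @param compounds Compound table with potencies.
#' @param rule_set Fragmentation rules.
#' @param min_size Minimum series size (smaller groups are discarded).
#' @param max_sites Maximum substitution sites considered.
#' @return List of `analog_series`, largest first.
#' @export
extract_series <- function(compounds, rule_set = default_rule_set(),
                           min_size = 3L, max_sites = 4L) {
  n <- nrow(compounds)
  decomp_by_cpd <- lapply(seq_len(n), function(i) {
    decs <- fragment_compound(compounds$smiles[i], rule_set, max_sites)
    # non-trivial cores only: a series core needs at least one site
    decs[vapply(decs, function(d) length(d$substituents) > 0, logical(1))]
  })
  core_tab <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (d in decomp_by_cpd[[i]]) {
      key <- d$core_smiles
      cur <- if (exists(key, envir = core_tab)) get(key, envir = core_tab)
             else list(count = 0L, heavy = d$core_heavy)
      cur$count <- cur$count + 1L
      assign(key, cur, envir = core_tab)
    }
  }
  pick_core <- function(decs) {
    if (length(decs) == 0L) return(NULL)
    stats <- t(vapply(decs, function(d) {
      info <- get(d$core_smiles, envir = core_tab)
      c(count = info$count, heavy = d$core_heavy)
    }, numeric(2)))
    keys <- vapply(decs, `[[`, character(1), "core_smiles")
    ord <- order(-stats[, "count"], -stats[, "heavy"], keys)
    decs[[ord[1]]]
  }
  chosen <- lapply(decomp_by_cpd, pick_core)
  core_of <- vapply(chosen, function(d) {
    if (is.null(d)) NA_character_ else d$core_smiles
  }, character(1))

  groups <- split(seq_len(n), core_of)
  groups <- groups[order(-lengths(groups))]
  series_list <- list()
  assigned <- rep(FALSE, n)
  for (core_smi in names(groups)) {
    idx <- groups[[core_smi]][!assigned[groups[[core_smi]]]]
    # size filter comes after absorption of H-substituted analogs; a core
    # still needs >= 2 identical-core compounds to seed a series
    if (length(idx) < 2L) next
    core <- core_scaffold(core_smi)
    rows <- lapply(idx, function(i) {
      d <- chosen[[i]]
      row <- data.frame(id = compounds$id[i],
                        potency = compounds$potency[i],
                        stringsAsFactors = FALSE)
      for (s in seq_len(core$n_sites)) row[[paste0("sub_", s)]] <-
          d$substituents[match(core$site_signatures[s], d$site_signatures)]
      row
    })
    ser <- analog_series(core, do.call(rbind, rows))
    assigned[idx] <- TRUE
    # absorb compounds expressible on this core with H at some sites
    rest <- which(!assigned)
    for (i in rest) {
      subs <- match_to_core(core, compounds$smiles[i], rule_set)
      if (!is.null(subs)) {
        row <- ser$analogs[0, ]
        new_row <- data.frame(id = compounds$id[i],
                              smiles = canonical_smiles(compounds$smiles[i]),
                              potency = compounds$potency[i],
                              stringsAsFactors = FALSE)
        for (s in seq_along(subs)) new_row[[paste0("sub_", s)]] <- subs[s]
        ser$analogs <- rbind(ser$analogs, new_row[, names(ser$analogs)])
        assigned[i] <- TRUE
      }
    }
    series_list[[length(series_list) + 1L]] <- ser
  }
  keep <- vapply(series_list, function(s) nrow(s$analogs) >= min_size,
                 logical(1))
  series_list <- series_list[keep]
  ord <- order(-vapply(series_list, function(s) nrow(s$analogs), numeric(1)))
  series_list[ord]
}

## ---- substituent pools -------------------------------------------------

#' Build a substituent pool
#'
#' @param source An `analog_series` (pool of its own substituents,
#'   provenance `"series"`) or a character vector of fragment SMILES with
#'   one `*` attachment point each (provenance `"external"`).
#' @param max_heavy_atoms Heavy-atom cap per fragment (default 13).
#' @return A `substituent_pool`: deduplicated canonical fragments.
#' @export
build_pool <- function(source, max_heavy_atoms = 13L) {
  if (inherits(source, "analog_series")) {
    sub_cols <- paste0("sub_", seq_len(source$core$n_sites))
    frags <- unlist(source$analogs[, sub_cols], use.names = FALSE)
    frags <- setdiff(frags, "H")
    provenance <- "series"
  } else {
    frags <- as.character(source)
    provenance <- "external"
  }
  can <- canonical_smiles(frags)
  if (anyNA(can)) stop("invalid fragment SMILES: ",
                       paste(frags[is.na(can)], collapse = ", "))
  n_attach <- vapply(can, function(s) {
    sum(fragment_mol(s)$elements == "*")
  }, numeric(1))
  if (any(n_attach != 1L))
    stop("fragment(s) without exactly one attachment point: ",
         paste(can[n_attach != 1L], collapse = ", "))
  can <- unique(can)
  heavy <- vapply(can, function(s) n_heavy_atoms(fragment_mol(s)), numeric(1))
  can <- can[heavy <= max_heavy_atoms]
  if (length(can) == 0L) stop("empty pool after size filtering")
  structure(list(fragments = unname(can),
                 max_heavy_atoms = max_heavy_atoms,
                 provenance = provenance),
            class = "substituent_pool")
}

#' @export
print.substituent_pool <- function(x, ...) {
  cat("<substituent_pool> ", length(x$fragments), " fragments (",
      x$provenance, "), <= ", x$max_heavy_atoms, " heavy atoms\n", sep = "")
  invisible(x)
}
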
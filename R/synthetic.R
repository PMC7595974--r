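# Synthetic analog series with known ground truth.
#
# Series are assembled from a shipped library of chemically valid cores
# and substituent fragments, so that descriptor, fingerprint and SMILES
# code paths are exercised end to end. Potency follows an additive
# per-substituent model with optional pairwise (non-additive) interaction
# terms and Gaussian measurement noise; all components are stored
# alongside the series for oracle tests. Substituent alphabets are drawn
# so that every attachment is cleavable by the default retrosynthetic
# rule set, making fragmentation/extraction recovery exact.

# Cores by number of substitution sites. Sites attach through
# ring-to-chain, amide/amine (N) or ether (O) bonds.
synthetic_cores <- function() {
  list(`2` = "*c1ccc(C(=O)N*)cc1",
       `3` = "*Oc1cc(*)ccc1C(=O)N*",
       `4` = "*Oc1cc(*)ccc1C(=O)N(*)Cc1ccc(*)cc1")
}

# Substituent fragment library. Attachment atom is carbon throughout
# (halogens are separate); `cyclic` marks fragments attaching through a
# ring atom (aryl or cycloalkyl). Those form ring-ring bonds at ring
# sites, which no default rule cleaves, so they are only compatible with
# heteroatom (N/O) sites.
synthetic_fragments <- function() {
  data.frame(
    smiles = c("*C", "*CC", "*CCC", "*C(C)C", "*CCCC", "*C(C)(C)C",
               "*CO", "*CCO", "*COC", "*CCOC",
               "*C(F)(F)F", "*CC(F)(F)F", "*CN(C)C", "*C#N", "*C(C)=O",
               "*Cc1ccccc1", "*CCc1ccccc1", "*Cc1ccncc1",
               "*C1CC1", "*C1CCCC1",
               "*c1ccccc1", "*c1ccc(C)cc1", "*c1ccc(F)cc1", "*c1ccncc1",
               "*c1cccs1", "*c1ccco1", "*c1ccc(OC)cc1"),
    cyclic = c(rep(FALSE, 18), rep(TRUE, 9)),
    stringsAsFactors = FALSE)
}

synthetic_halogens <- function() c("*F", "*Cl", "*Br")

# Site kind: "ring" when the attachment neighbor is a ring carbon,
# otherwise "hetero" (N or O attachment).
site_kinds <- function(core) {
  ring <- ring_atoms(core$mol)
  vapply(core$site_dummies, function(d) {
    nb <- unique(c(core$mol$bonds[core$mol$bonds[, "a"] == d, "b"],
                   core$mol$bonds[core$mol$bonds[, "b"] == d, "a"]))
    if (core$mol$elements[nb] == "C" && ring[nb]) "ring" else "hetero"
  }, character(1))
}

# Fragments compatible with a site kind (recovery-safe under the default
# rule set): ring sites take acyclic-attached fragments and halogens,
# heteroatom sites take carbon-attached fragments including cyclic ones.
compatible_fragments <- function(kind) {
  lib <- synthetic_fragments()
  if (kind == "ring") c(lib$smiles[!lib$cyclic], synthetic_halogens())
  else lib$smiles
}

#' Specification for a synthetic analog series
#'
#' @param n_sites Number of substitution sites (2-4).
#' @param substituents_per_site Alphabet size per site.
#' @param n_eas Number of existing analogs to draw (distinct substituent
#'   combinations; must not exceed the combinatorial space).
#' @param base_potency Baseline pIC50 of the unsubstituted-reference
#'   combination.
#' @param effect_sd SD of per-(site, substituent) additive contributions.
#' @param interaction_sd SD of pairwise (site, substituent) x (site,
#'   substituent) non-additive terms; 0 gives a strictly additive SAR.
#' @param noise_sd SD of Gaussian measurement noise on recorded potency.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `series_generator_spec`.
#' @export
series_generator_spec <- function(n_sites = 2L, substituents_per_site = 6L,
                                  n_eas = 20L, base_potency = 6,
                                  effect_sd = 0.5, interaction_sd = 0,
                                  noise_sd = 0.1, seed = 1L) {
  stopifnot(n_sites %in% 2:4, substituents_per_site >= 2L,
            effect_sd >= 0, interaction_sd >= 0, noise_sd >= 0)
  space <- substituents_per_site^n_sites
  if (n_eas > space)
    stop("n_eas (", n_eas, ") exceeds the combinatorial space (", space, ")")
  structure(list(n_sites = as.integer(n_sites),
                 substituents_per_site = as.integer(substituents_per_site),
                 n_eas = as.integer(n_eas), base_potency = base_potency,
                 effect_sd = effect_sd, interaction_sd = interaction_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "series_generator_spec")
}

#' Generate a synthetic analog series with ground truth
#'
#' Recorded potency is
#' `base + sum(site effects) + sum(pairwise interactions) + noise`.
#' The ground-truth decomposition (alphabets, effect tables, interaction
#' arrays, noiseless potencies) is stored in `$ground_truth`.
#'
#' @param spec A [series_generator_spec()].
#' @return An `analog_series` with a `ground_truth` element.
#' @export
generate_series <- function(spec = series_generator_spec()) {
  stopifnot(inherits(spec, "series_generator_spec"))
  set.seed(spec$seed)
  core <- core_scaffold(synthetic_cores()[[as.character(spec$n_sites)]])
  kinds <- site_kinds(core)
  alphabets <- lapply(kinds, function(k) {
    sample(compatible_fragments(k), spec$substituents_per_site)
  })
  effects <- lapply(alphabets, function(a) {
    stats::setNames(stats::rnorm(length(a), 0, spec$effect_sd), a)
  })
  interactions <- list()
  for (i in seq_len(spec$n_sites - 1)) {
    for (j in (i + 1):spec$n_sites) {
      m <- matrix(stats::rnorm(length(alphabets[[i]]) * length(alphabets[[j]]),
                               0, spec$interaction_sd),
                  nrow = length(alphabets[[i]]),
                  dimnames = list(alphabets[[i]], alphabets[[j]]))
      interactions[[paste(i, j)]] <- m
    }
  }
  space <- prod(lengths(alphabets))
  combo_idx <- sample.int(space, spec$n_eas)
  combos <- t(vapply(combo_idx - 1L, function(x) {
    out <- integer(spec$n_sites)
    for (s in seq_len(spec$n_sites)) {
      out[s] <- x %% lengths(alphabets)[s] + 1L
      x <- x %/% lengths(alphabets)[s]
    }
    out
  }, integer(spec$n_sites)))

  truth <- list(core = core$smiles, alphabets = alphabets, effects = effects,
                interactions = interactions, base_potency = spec$base_potency,
                spec = spec)
  sub_tab <- vapply(seq_len(spec$n_sites), function(s) {
    alphabets[[s]][combos[, s]]
  }, character(spec$n_eas))
  sub_tab <- matrix(sub_tab, nrow = spec$n_eas)
  pot_true <- apply(sub_tab, 1, function(subs) true_potency(truth, subs))
  noise <- stats::rnorm(spec$n_eas, 0, spec$noise_sd)

  analogs <- data.frame(id = sprintf("ea_%03d", seq_len(spec$n_eas)),
                        potency = pot_true + noise,
                        stringsAsFactors = FALSE)
  for (s in seq_len(spec$n_sites)) analogs[[paste0("sub_", s)]] <- sub_tab[, s]
  series <- analog_series(core, analogs, target_name = "synthetic")
  truth$potency_true <- stats::setNames(pot_true, analogs$id)
  series$ground_truth <- truth
  series
}

#' Noiseless model potency of a substituent combination
#'
#' @param truth The `ground_truth` element of a generated series (or a
#'   generated series itself).
#' @param substituents Character vector of fragment SMILES, one per site.
#' @return The additive + interaction model value (no noise).
#' @export
true_potency <- function(truth, substituents) {
  if (inherits(truth, "analog_series")) truth <- truth$ground_truth
  stopifnot(!is.null(truth$effects))
  p <- truth$base_potency
  n_sites <- length(truth$effects)
  stopifnot(length(substituents) == n_sites)
  for (s in seq_len(n_sites)) {
    e <- truth$effects[[s]][substituents[s]]
    if (is.na(e)) stop("substituent not in site ", s, " alphabet: ",
                       substituents[s])
    p <- p + e
  }
  for (key in names(truth$interactions)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    p <- p + truth$interactions[[key]][substituents[ij[1]],
                                       substituents[ij[2]]]
  }
  unname(p)
}

#' Generate a virtual-analog pool for a synthetic series
#'
#' @param series An `analog_series`.
#' @param n Pool size (unique VAs).
#' @param strategy `"close_in"` (series substituents only) or
#'   `"diverse"` (full fragment library).
#' @param seed Integer seed.
#' @param ... Passed to [enumeration_spec()].
#' @return Compound table of VAs.
#' @export
generate_va_pool <- function(series, n = 1000L,
                             strategy = c("close_in", "diverse"),
                             seed = 1L, ...) {
  strategy <- match.arg(strategy)
  pool <- if (strategy == "close_in") {
    build_pool(series)
  } else {
    build_pool(synthetic_fragments()$smiles)
  }
  enumerate_vas(enumeration_spec(series, pool, n_target = n, seed = seed,
                                 ...))
}

# Scaffolds used for background corpora; disjoint from the series cores
# so that a fresh generative model samples no series-core-containing
# molecules.
corpus_cores <- function() {
  c("*c1ccccc1", "*c1ccncc1", "*C1CCCCC1", "*c1cccs1", "*c1ccco1",
    "*CC(=O)OC", "*NC(=O)C1CCCC1", "*NS(=O)(=O)C", "*OCC", "*N(C)C",
    "*c1ccc(*)cc1", "*Cc1ccc(*)cc1", "*c1ccnc(*)c1", "*CC(*)C",
    "*OCC(=O)N(C)*")
}

#' Generate a background SMILES corpus for generative pretraining
#'
#' Small drug-like molecules assembled from one-site scaffolds and the
#' fragment library: all strings are valid, canonical, unique and bounded
#' in length. None contains the synthetic series cores.
#'
#' @param n Number of unique SMILES.
#' @param seed Integer seed.
#' @param max_length Maximum string length (characters).
#' @return Character vector of `n` canonical SMILES.
#' @export
generate_corpus <- function(n = 500L, seed = 1L, max_length = 80L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  cores <- corpus_cores()
  frags <- c(synthetic_fragments()$smiles, synthetic_halogens(), "H")
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 200L * n) {
    guard <- guard + 1L
    core <- core_scaffold(cores[sample.int(length(cores), 1L)])
    subs <- sample(frags, core$n_sites, replace = TRUE)
    smi <- assemble_analog(core, subs)
    if (is.na(smi) || nchar(smi) > max_length) next
    out <- unique(c(out, smi))
  }
  if (length(out) < n)
    stop("could not generate ", n, " unique corpus molecules")
  out[seq_len(n)]
}
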
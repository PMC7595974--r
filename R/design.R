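# Scaffold-based enumeration of virtual analogs.
#
# Diverse and close-in VAs are generated the same way and differ only in
# the substituent pool: close-in VAs recombine substituents observed in
# the series itself, diverse VAs draw from an external fragment pool.

#' Enumeration settings for virtual analog design
#'
#' @param series An `analog_series`.
#' @param pool A `substituent_pool` ([build_pool()]).
#' @param n_target Number of unique VAs requested.
#' @param size_range Heavy-atom (min, max) for accepted VAs; defaults to
#'   the range spanned by the series' existing analogs.
#' @param h_probabilities Per-site probability of placing H instead of a
#'   pool fragment; defaults to the fraction of existing analogs carrying
#'   H at each site (the series' own substitution statistics).
#' @param seed Integer seed.
#' @param max_draw_factor Rejection sampling is bounded at
#'   `max_draw_factor * n_target` draws.
#' @return An `enumeration_spec`.
#' @export
enumeration_spec <- function(series, pool, n_target = 1000L,
                             size_range = NULL, h_probabilities = NULL,
                             seed = 1L, max_draw_factor = 100L) {
  stopifnot(inherits(series, "analog_series"),
            inherits(pool, "substituent_pool"), n_target >= 1L)
  n_sites <- series$core$n_sites
  sub_cols <- paste0("sub_", seq_len(n_sites))
  if (is.null(h_probabilities)) {
    h_probabilities <- vapply(sub_cols, function(s) {
      mean(series$analogs[[s]] == "H")
    }, numeric(1))
  }
  stopifnot(length(h_probabilities) == n_sites,
            all(h_probabilities >= 0), all(h_probabilities <= 1))
  if (is.null(size_range)) {
    heavy <- vapply(series$analogs$smiles, function(s) {
      n_heavy_atoms(fragment_mol(s))
    }, numeric(1))
    size_range <- range(heavy)
  }
  structure(list(series = series, pool = pool,
                 n_target = as.integer(n_target),
                 size_range = size_range,
                 h_probabilities = unname(h_probabilities),
                 seed = as.integer(seed),
                 max_draw_factor = as.integer(max_draw_factor)),
            class = "enumeration_spec")
}

#' Enumerate diverse or close-in virtual analogs
#'
#' Every VA is the series core with each site independently set to H
#' (with its site probability) or a uniformly drawn pool fragment.
#' Candidates outside the heavy-atom size range are rejected and redrawn;
#' the output is deduplicated by canonical SMILES and excludes existing
#' analogs. Deterministic given the seed.
#'
#' @param spec An [enumeration_spec()].
#' @return Compound table of VAs, origin `close_in_VA` when the pool
#'   provenance is `"series"`, else `diverse_VA`. If the bounded draw
#'   budget cannot reach `n_target` unique VAs, a shortfall warning is
#'   emitted and the partial result returned.
#' @export
enumerate_vas <- function(spec) {
  stopifnot(inherits(spec, "enumeration_spec"))
  core <- spec$series$core
  n_sites <- core$n_sites
  frags <- spec$pool$fragments
  frag_heavy <- vapply(frags, function(s) n_heavy_atoms(fragment_mol(s)),
                       numeric(1))
  core_heavy <- n_heavy_atoms(core$mol)
  ea_smiles <- spec$series$analogs$smiles
  origin <- if (spec$pool$provenance == "series") "close_in_VA"
            else "diverse_VA"

  set.seed(spec$seed)
  found <- character(0)
  seen_tuples <- new.env(parent = emptyenv())
  draws <- 0L
  max_draws <- spec$max_draw_factor * spec$n_target
  while (length(found) < spec$n_target && draws < max_draws) {
    draws <- draws + 1L
    use_h <- stats::runif(n_sites) < spec$h_probabilities
    pick <- sample.int(length(frags), n_sites, replace = TRUE)
    subs <- ifelse(use_h, "H", frags[pick])
    heavy <- core_heavy + sum(frag_heavy[pick[!use_h]])
    if (heavy < spec$size_range[1] || heavy > spec$size_range[2]) next
    key <- paste(subs, collapse = "|")
    if (exists(key, envir = seen_tuples)) next
    assign(key, TRUE, envir = seen_tuples)
    smi <- assemble_analog(core, subs)
    if (is.na(smi) || smi %in% ea_smiles || smi %in% found) next
    found <- c(found, smi)
  }
  if (length(found) < spec$n_target)
    warning("enumeration shortfall: ", length(found), " of ",
            spec$n_target, " unique VAs after ", draws, " draws")
  compound_records(found, id = paste0(substr(origin, 1, 1), "va_",
                                      seq_along(found)),
                   origin = origin)
}

#' Pairwise overlap between compound populations
#'
#' Counts canonical-SMILES intersections for every pair of populations
#' (populations are deduplicated first); the diagonal holds unique sizes.
#'
#' @param populations Named list of compound tables or SMILES vectors.
#' @return Symmetric integer matrix of intersection counts.
#' @export
population_overlap <- function(populations) {
  stopifnot(is.list(populations), length(populations) >= 2L,
            !is.null(names(populations)))
  sets <- lapply(populations, function(p) {
    smi <- if (is.data.frame(p)) p$smiles else as.character(p)
    unique(canonical_smiles(smi))
  })
  k <- length(sets)
  out <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      out[i, j] <- out[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  out
}
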
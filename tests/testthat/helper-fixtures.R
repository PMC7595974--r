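# Shared fixtures. Everything is generated in code; heavyweight objects
# (the pretrained prior, reference synthetic series) are memoized in the
# global environment so multiple test files can share one computation.

TEST_CORE <- "*c1ccc(C(=O)N*)cc1"

# Build a small two-site series directly from substituent tuples.
mk_series <- function(subs1, subs2, potency, core = TEST_CORE,
                      ids = NULL) {
  n <- length(subs1)
  if (is.null(ids)) ids <- paste0("c", seq_len(n))
  analog_series(core, data.frame(id = ids, sub_1 = subs1, sub_2 = subs2,
                                 potency = potency,
                                 stringsAsFactors = FALSE))
}

test_cache <- function() {
  if (!exists(".comodiag_test_cache", envir = globalenv())) {
    assign(".comodiag_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".comodiag_test_cache", envir = globalenv())
}

cache_get <- function(key, build) {
  cache <- test_cache()
  if (!exists(key, envir = cache)) assign(key, build(), envir = cache)
  get(key, envir = cache)
}

# Desk-scale pretrained prior shared by the generative and acceptance
# tests (500-molecule corpus, 55 epochs).
get_test_prior <- function() {
  cache_get("prior", function() {
    corpus <- generate_corpus(500, seed = 4, max_length = 50)
    pretrain(corpus, generative_config(epochs = 55, seed = 1))
  })
}

# One fine-tuning run on a synthetic series, shared likewise.
get_test_tl <- function() {
  cache_get("tl", function() {
    prior <- get_test_prior()
    series <- get_tl_series()
    transfer_learn(prior, series)
  })
}

get_tl_series <- function() {
  cache_get("tl_series", function() {
    generate_series(series_generator_spec(n_sites = 2,
                                          substituents_per_site = 6,
                                          n_eas = 25, seed = 7))
  })
}

# Reference synthetic series reused by several oracle tests.
get_ref_series <- function() {
  cache_get("ref_series", function() {
    generate_series(series_generator_spec(n_sites = 3,
                                          substituents_per_site = 5,
                                          n_eas = 30, noise_sd = 0,
                                          seed = 101))
  })
}

# Brute-force quartet oracle: tests all analog triples x ordered site
# pairs for the double-exchange pattern, independent of the network
# implementation. Returns a canonical set of quartet signatures.
oracle_quartets <- function(series) {
  sub_cols <- paste0("sub_", seq_len(series$core$n_sites))
  m <- as.matrix(series$analogs[, sub_cols, drop = FALSE])
  rownames(m) <- series$analogs$id
  n <- nrow(m); k <- ncol(m)
  keys <- apply(m, 1, paste, collapse = "|")
  sigs <- character(0)
  for (ref in seq_len(n)) for (x in seq_len(n)) for (y in seq_len(n)) {
    if (ref == x || ref == y || x == y) next
    dx <- which(m[ref, ] != m[x, ])
    dy <- which(m[ref, ] != m[y, ])
    if (length(dx) != 1L || length(dy) != 1L || dx == dy) next
    target <- m[ref, ]
    target[dx] <- m[x, dx]
    target[dy] <- m[y, dy]
    tkey <- paste(target, collapse = "|")
    s1 <- min(dx, dy); s2 <- max(dx, dy)
    # unordered (x, y) roles: normalize by site order
    xs <- if (dx == s1) rownames(m)[x] else rownames(m)[y]
    ys <- if (dx == s1) rownames(m)[y] else rownames(m)[x]
    sigs <- c(sigs, paste(s1, s2, rownames(m)[ref], xs, ys, tkey,
                          tkey %in% keys, sep = "::"))
  }
  sort(unique(sigs))
}

quartet_signatures <- function(quartets) {
  if (nrow(quartets) == 0L) return(character(0))
  sort(unique(paste(quartets$s1, quartets$s2, quartets$ea_ref,
                    quartets$ea_x, quartets$ea_y, quartets$target_key,
                    quartets$target_status == "FW_EA", sep = "::")))
}
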
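# SMILES tokenization and vocabulary.
#
# Multi-character atom symbols (two-letter elements, bracket atoms) and
# two-digit ring closures are single tokens, so that detokenization is
# the identity on every valid SMILES.

SMILES_TOKEN_REGEX <- "\\[[^]]*\\]|Br|Cl|%[0-9]{2}|."

#' Tokenize a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return Character vector of structural tokens;
#'   `paste(tokens, collapse = "")` reproduces the input exactly.
#' @export
tokenize_smiles <- function(smiles) {
  regmatches(smiles, gregexpr(SMILES_TOKEN_REGEX, smiles))[[1]]
}

#' Build a vocabulary from a SMILES corpus
#'
#' Invalid SMILES are rejected with a diagnostic. The vocabulary holds
#' the sorted structural tokens plus `<pad>`, `<start>` and `<end>`
#' markers.
#'
#' @param corpus Character vector of SMILES.
#' @return A `smiles_vocabulary`.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) >= 1L)
  ok <- is_valid_smiles(corpus)
  if (any(!ok)) {
    warning(sum(!ok), " invalid SMILES rejected from corpus: ",
            paste(utils::head(corpus[!ok], 5), collapse = ", "),
            if (sum(!ok) > 5) ", ..." else "")
    corpus <- corpus[ok]
  }
  if (length(corpus) == 0L) stop("no valid SMILES in corpus")
  toks <- unique(unlist(lapply(corpus, tokenize_smiles)))
  toks <- sort(toks, method = "radix")
  tokens <- c("<pad>", "<start>", "<end>", toks)
  structure(list(tokens = tokens, size = length(tokens),
                 index = stats::setNames(seq_along(tokens), tokens),
                 pad = 1L, start = 2L, end = 3L),
            class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("<smiles_vocabulary> ", x$size, " tokens: ",
      paste(utils::head(x$tokens, 15), collapse = " "),
      if (x$size > 15) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Encode SMILES as token-id sequences
#'
#' @param smiles Character vector of SMILES.
#' @param vocab A `smiles_vocabulary`.
#' @return List of integer vectors `<start> tokens <end>`. Unknown
#'   tokens raise an error naming the token.
#' @export
encode_smiles <- function(smiles, vocab) {
  lapply(smiles, function(s) {
    toks <- tokenize_smiles(s)
    ids <- vocab$index[toks]
    if (anyNA(ids))
      stop("out-of-vocabulary token '", toks[which(is.na(ids))[1]],
           "' in: ", s)
    c(vocab$start, unname(ids), vocab$end)
  })
}

#' Syntactic SMILES well-formedness check
#'
#' Verifies branch parentheses balance (no empty branches), ring-bond
#' closure matching, and that the string neither starts nor ends with a
#' bond or branch symbol. This complements the parser, which repairs
#' some malformed strings instead of rejecting them.
#'
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
smiles_grammar_ok <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    toks <- tokenize_smiles(s)
    depth <- 0L
    open_rings <- character(0)
    prev <- ""
    for (tk in toks) {
      if (tk == "(") {
        if (prev %in% c("", "(", "-", "=", "#", "/", "\\")) return(FALSE)
        depth <- depth + 1L
      } else if (tk == ")") {
        if (depth == 0L || prev %in% c("(", "-", "=", "#", "/", "\\"))
          return(FALSE)
        depth <- depth - 1L
      } else if (grepl("^[0-9]$|^%[0-9]{2}$", tk)) {
        if (prev %in% c("", "(", ")")) return(FALSE)
        if (tk %in% open_rings) open_rings <- setdiff(open_rings, tk)
        else open_rings <- c(open_rings, tk)
      }
      prev <- tk
    }
    depth == 0L && length(open_rings) == 0L &&
      !(prev %in% c("-", "=", "#", "/", "\\", "("))
  }, logical(1), USE.NAMES = FALSE)
}

# Validity filter for model-sampled strings: well-formed grammar, parses
# in the backend, and the canonical form stays within the vocabulary's
# token universe (a canonical form with new bracket atoms means the
# parser "repaired" a chemically broken string, e.g. into radicals).
valid_sampled_smiles <- function(smiles, vocab) {
  ok <- smiles_grammar_ok(smiles)
  can <- rep(NA_character_, length(smiles))
  can[ok] <- canonical_smiles(smiles[ok])
  ok <- ok & !is.na(can)
  known <- vocab$tokens
  ok[ok] <- vapply(can[ok], function(s) {
    all(tokenize_smiles(s) %in% known)
  }, logical(1), USE.NAMES = FALSE)
  list(valid = ok, canonical = can)
}

#' Decode token ids back to a SMILES string
#'
#' @param ids Integer vector of token ids.
#' @param vocab A `smiles_vocabulary`.
#' @return SMILES string (special markers stripped).
#' @export
decode_smiles <- function(ids, vocab) {
  ids <- ids[ids > 3L]
  paste(vocab$tokens[ids], collapse = "")
}
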
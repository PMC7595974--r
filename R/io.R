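# Compound and report I/O.
#
# Compound tables are plain data.frames with columns `id`, `smiles`,
# `potency` (pIC50, may be NA) and `origin`. Canonical SMILES is the
# identity key everywhere: records are canonicalized on ingestion and all
# uniqueness/overlap logic compares canonical strings.

VALID_ORIGINS <- c("EA", "diverse_VA", "close_in_VA", "FW_VA", "sampled_VA")

#' Build a validated compound table
#'
#' Canonicalizes SMILES, checks identifier uniqueness and potency
#' finiteness. Records whose SMILES fail to parse are removed from the
#' returned table but reported via a warning and the `"rejected"`
#' attribute — they are never silently dropped.
#'
#' @param smiles Character vector of SMILES.
#' @param id Identifiers (unique); defaults to `cpd_1..n`.
#' @param potency Optional numeric pIC50 values (log10 units).
#' @param origin Compound origin tag, one of `r toString(VALID_ORIGINS)`.
#' @return A data.frame with columns id, smiles (canonical), potency,
#'   origin; rejected rows in `attr(x, "rejected")`.
#' @export
compound_records <- function(smiles, id = NULL, potency = NULL,
                             origin = "EA") {
  n <- length(smiles)
  if (is.null(id)) id <- paste0("cpd_", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate identifier(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (is.null(potency)) potency <- rep(NA_real_, n)
  if (any(!is.na(potency) & !is.finite(potency)))
    stop("non-finite potency values present")
  origin <- match.arg(origin, VALID_ORIGINS)
  can <- canonical_smiles(smiles)
  ok <- !is.na(can)
  if (!any(ok)) {
    warning(sum(!ok), " record(s) rejected (unparseable SMILES): ",
            paste(id[!ok], collapse = ", "))
    stop("no valid molecules in input")
  }
  out <- data.frame(id = id[ok], smiles = can[ok],
                    potency = as.numeric(potency)[ok],
                    origin = origin, stringsAsFactors = FALSE)
  if (any(!ok)) {
    rejected <- data.frame(id = id[!ok], smiles = smiles[!ok],
                           reason = "SMILES failed to parse",
                           stringsAsFactors = FALSE)
    warning(sum(!ok), " record(s) rejected (unparseable SMILES): ",
            paste(rejected$id, collapse = ", "))
    attr(out, "rejected") <- rejected
  }
  if (nrow(out) == 0L) stop("no valid molecules in input")
  out
}

#' Read compounds from SMILES, CSV or SD files
#'
#' CSV files use columns `smiles`, `id` and optionally `pIC50`
#' (or `potency`); extra columns are preserved as opaque metadata in
#' `attr(x, "metadata")`. `.smi` files are `SMILES<tab>id` lines. SDF
#' potencies are read from a named property field.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"smi"`, `"sdf"`; guessed from the file
#'   extension when omitted.
#' @param potency_field SDF property holding the potency (default
#'   `"pIC50"`).
#' @param origin Origin tag assigned to all records.
#' @return A compound table (see [compound_records()]).
#' @export
read_compounds <- function(path, format = c("csv", "smi", "sdf"),
                           potency_field = "pIC50", origin = "EA") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "smi", "sdf")) ext else "csv"
  }
  format <- match.arg(format)
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(tab)[names(tab) == "potency"] <- "pIC50"
    if (!all(c("smiles", "id") %in% names(tab)))
      stop("CSV must contain 'smiles' and 'id' columns")
    pot <- if ("pIC50" %in% names(tab)) tab$pIC50 else NULL
    out <- compound_records(tab$smiles, tab$id, pot, origin = origin)
    extra <- setdiff(names(tab), c("smiles", "id", "pIC50"))
    if (length(extra))
      attr(out, "metadata") <- tab[tab$id %in% out$id, extra, drop = FALSE]
    out
  } else if (format == "smi") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1))
    if (anyNA(ids)) ids <- ifelse(is.na(ids), paste0("cpd_", seq_along(smi)), ids)
    compound_records(smi, ids, origin = origin)
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdfset)
    sdfset <- sdfset[valid]
    smi <- as.character(ChemmineR::sdf2smiles(sdfset))
    ids <- ChemmineR::sdfid(sdfset)
    blocks <- ChemmineR::datablock(sdfset)
    pot <- vapply(blocks, function(b) {
      if (potency_field %in% names(b)) as.numeric(b[[potency_field]])
      else NA_real_
    }, numeric(1))
    compound_records(smi, ids, pot, origin = origin)
  }
}

#' Write a compound table to CSV
#'
#' @param compounds A compound table.
#' @param path Output path.
#' @export
write_compounds <- function(compounds, path) {
  utils::write.csv(compounds, path, row.names = FALSE)
  invisible(path)
}

#' Write a diagnostic score report
#'
#' Serializes a [score_report] (C, D, S, P means and standard deviations,
#' NBH radius, sample sizes, seed, descriptor set) as machine-readable
#' JSON that round-trips through [read_score_report()].
#'
#' @param report A `score_report` object.
#' @param path Output path.
#' @export
write_score_report <- function(report, path) {
  stopifnot(inherits(report, "score_report"))
  if (is.null(report$n_eas) || report$n_eas == 0L)
    stop("refusing to write a report for an empty series")
  payload <- unclass(report)
  payload$per_resample <- as.data.frame(report$per_resample)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a diagnostic score report written by [write_score_report()]
#'
#' @param path Path to the JSON report.
#' @return A `score_report` object.
#' @export
read_score_report <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$per_resample <- as.matrix(payload$per_resample)
  structure(payload, class = "score_report")
}
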
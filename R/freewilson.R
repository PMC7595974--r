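# Free-Wilson analysis on analog series.
#
# Matched molecular pairs (MMPs) are computed positionally from the
# series' per-site decomposition: two analogs form an MMP when they
# differ at exactly one site. Closed double-exchange cycles of four
# compounds (quartets) are the unit of local additivity: with three
# corners measured, the fourth corner's potency is predicted as
# pot(x) + pot(y) - pot(ref).

sub_matrix <- function(series) {
  sub_cols <- paste0("sub_", seq_len(series$core$n_sites))
  m <- as.matrix(series$analogs[, sub_cols, drop = FALSE])
  rownames(m) <- series$analogs$id
  m
}

#' Matched molecular pairs within a series
#'
#' All and only the unordered analog pairs differing at exactly one
#' substitution site.
#'
#' @param series An `analog_series`.
#' @return data.frame with columns `analog_a`, `analog_b`, `site`,
#'   `substituent_a`, `substituent_b`.
#' @export
compute_mmps <- function(series) {
  m <- sub_matrix(series)
  n <- nrow(m)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        diff <- which(m[i, ] != m[j, ])
        if (length(diff) == 1L) {
          out[[length(out) + 1L]] <- data.frame(
            analog_a = rownames(m)[i], analog_b = rownames(m)[j],
            site = diff, substituent_a = m[i, diff],
            substituent_b = m[j, diff], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(analog_a = character(0), analog_b = character(0),
                      site = integer(0), substituent_a = character(0),
                      substituent_b = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' MMP network of a series
#'
#' Undirected graph with analogs as nodes and MMPs as edges.
#'
#' @param series An `analog_series`.
#' @return An `igraph` graph; edges carry `site`, `substituent_a`,
#'   `substituent_b` attributes.
#' @export
mmp_network <- function(series) {
  mmps <- compute_mmps(series)
  g <- igraph::graph_from_data_frame(
    mmps[, c("analog_a", "analog_b", "site",
             "substituent_a", "substituent_b")],
    directed = FALSE,
    vertices = data.frame(name = series$analogs$id))
  g
}

#' Enumerate Free-Wilson quartets
#'
#' A quartet is a closed double substituent-exchange cycle on two sites
#' s1 != s2 with a fixed substituent context at all other sites: corners
#' (a1,b1), (a2,b1), (a1,b2), (a2,b2). Every rectangle is enumerated once
#' per unordered (site pair, exchange) combination; each corner whose
#' three partners exist among the analogs yields one quartet with that
#' corner as target. The target is an FW EA if it exists in the series,
#' otherwise an FW VA.
#'
#' @param series An `analog_series` (needs >= 2 substitution sites).
#' @return data.frame of quartets: sites `s1`, `s2`, ids `ea_ref`,
#'   `ea_x` (differs from ref at s1), `ea_y` (differs at s2),
#'   `target_id` (NA for FW VAs), `target_key` (per-site substituent
#'   tuple, `|`-separated), `target_status` (`"FW_EA"`/`"FW_VA"`).
#' @export
find_quartets <- function(series) {
  m <- sub_matrix(series)
  n_sites <- ncol(m)
  empty <- data.frame(s1 = integer(0), s2 = integer(0),
                      ea_ref = character(0), ea_x = character(0),
                      ea_y = character(0), target_id = character(0),
                      target_key = character(0), target_status = character(0))
  if (n_sites < 2L || nrow(m) < 3L) return(empty)
  key_of <- function(subs) paste(subs, collapse = "|")
  all_keys <- apply(m, 1, key_of)
  id_by_key <- stats::setNames(rownames(m), all_keys)
  out <- list()
  for (s1 in seq_len(n_sites - 1)) {
    for (s2 in (s1 + 1):n_sites) {
      others <- setdiff(seq_len(n_sites), c(s1, s2))
      ctx <- if (length(others)) apply(m[, others, drop = FALSE], 1,
                                       key_of) else rep("", nrow(m))
      for (grp in split(seq_len(nrow(m)), ctx)) {
        A <- sort(unique(m[grp, s1]))
        B <- sort(unique(m[grp, s2]))
        if (length(A) < 2L || length(B) < 2L) next
        present <- matrix(FALSE, length(A), length(B),
                          dimnames = list(A, B))
        present[cbind(m[grp, s1], m[grp, s2])] <- TRUE
        for (ai in seq_len(length(A) - 1)) for (aj in (ai + 1):length(A)) {
          for (bi in seq_len(length(B) - 1)) for (bj in (bi + 1):length(B)) {
            corners <- rbind(c(ai, bi), c(aj, bi), c(ai, bj), c(aj, bj))
            have <- present[corners]
            if (sum(have) < 3L) next
            for (t in seq_len(4)) {
              if (sum(have[-t]) != 3L) next
              # corner t is the target; ref is its diagonal opposite
              opp <- c(4L, 3L, 2L, 1L)[t]
              xc <- setdiff(seq_len(4), c(t, opp))
              # ea_x differs from ref at s1 (same column as ref)
              ref <- corners[opp, ]
              x_corner <- corners[xc[which(corners[xc, 2] == ref[2])], ]
              y_corner <- corners[xc[which(corners[xc, 1] == ref[1])], ]
              make_key <- function(corner) {
                subs <- m[grp[1], ]
                subs[s1] <- A[corner[1]]; subs[s2] <- B[corner[2]]
                key_of(subs)
              }
              tk <- make_key(corners[t, ])
              exists_t <- have[t]
              out[[length(out) + 1L]] <- data.frame(
                s1 = s1, s2 = s2,
                ea_ref = unname(id_by_key[make_key(ref)]),
                ea_x = unname(id_by_key[make_key(x_corner)]),
                ea_y = unname(id_by_key[make_key(y_corner)]),
                target_id = if (exists_t) unname(id_by_key[tk])
                            else NA_character_,
                target_key = tk,
                target_status = if (exists_t) "FW_EA" else "FW_VA",
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate Free-Wilson virtual analogs
#'
#' Assembles the unique FW VA quartet targets (substituent combinations
#' closing a double-exchange cycle that do not yet exist in the series).
#'
#' @param series An `analog_series`.
#' @param quartets Optional precomputed [find_quartets()] result.
#' @return Compound table of FW VAs (origin `FW_VA`) with the
#'   `target_key` preserved in `attr(x, "target_key")`.
#' @export
generate_fw_vas <- function(series, quartets = find_quartets(series)) {
  va_keys <- unique(quartets$target_key[quartets$target_status == "FW_VA"])
  if (length(va_keys) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      potency = numeric(0), origin = character(0)))
  smi <- vapply(va_keys, function(k) {
    assemble_analog(series$core, strsplit(k, "|", fixed = TRUE)[[1]])
  }, character(1), USE.NAMES = FALSE)
  keep <- !smi %in% series$analogs$smiles & !duplicated(smi)
  out <- compound_records(smi[keep], id = paste0("fwva_", seq_len(sum(keep))),
                          origin = "FW_VA")
  attr(out, "target_key") <- va_keys[keep]
  out
}

#' Free-Wilson potency prediction for one quartet
#'
#' Additivity: pot(target) = pot(x) + pot(y) - pot(ref).
#'
#' @param quartet One row of [find_quartets()] output.
#' @param potencies Named numeric vector of EA potencies.
#' @return Predicted pIC50.
#' @export
fw_predict <- function(quartet, potencies) {
  ids <- c(quartet$ea_ref, quartet$ea_x, quartet$ea_y)
  missing <- ids[!(ids %in% names(potencies)) | !is.finite(potencies[ids])]
  if (length(missing))
    stop("missing potency for EA(s): ", paste(missing, collapse = ", "))
  unname(potencies[quartet$ea_x] + potencies[quartet$ea_y] -
           potencies[quartet$ea_ref])
}

#' Aggregate Free-Wilson predictions per target
#'
#' Multiple quartets can share one target; predictions are combined as an
#' unweighted mean with the sample standard deviation.
#'
#' @param series An `analog_series` with potencies.
#' @param quartets Optional precomputed quartets.
#' @param status Restrict to `"FW_VA"` targets (default), `"FW_EA"`, or
#'   both.
#' @return data.frame: `target_key`, `target_id`, `target_status`,
#'   `smiles`, `n_quartets`, `mean_pred`, `sd_pred`.
#' @export
fw_predict_aggregate <- function(series, quartets = find_quartets(series),
                                 status = "FW_VA") {
  stopifnot(all(status %in% c("FW_VA", "FW_EA")))
  q <- quartets[quartets$target_status %in% status, , drop = FALSE]
  if (nrow(q) == 0L)
    return(data.frame(target_key = character(0), target_id = character(0),
                      target_status = character(0), smiles = character(0),
                      n_quartets = integer(0), mean_pred = numeric(0),
                      sd_pred = numeric(0)))
  potencies <- stats::setNames(series$analogs$potency, series$analogs$id)
  preds <- vapply(seq_len(nrow(q)), function(i) fw_predict(q[i, ], potencies),
                  numeric(1))
  agg <- lapply(split(seq_len(nrow(q)), q$target_key), function(idx) {
    data.frame(target_key = q$target_key[idx[1]],
               target_id = q$target_id[idx[1]],
               target_status = q$target_status[idx[1]],
               n_quartets = length(idx),
               mean_pred = mean(preds[idx]),
               sd_pred = if (length(idx) > 1) stats::sd(preds[idx]) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res$smiles <- vapply(res$target_key, function(k) {
    assemble_analog(series$core, strsplit(k, "|", fixed = TRUE)[[1]])
  }, character(1), USE.NAMES = FALSE)
  rownames(res) <- NULL
  res[, c("target_key", "target_id", "target_status", "smiles",
          "n_quartets", "mean_pred", "sd_pred")]
}

#' Free-Wilson participation fraction from counts
#'
#' @param count EAs appearing in at least one quartet.
#' @param n_eas Series size.
#' @return `count / n_eas`.
#' @export
fw_ea_fraction_from_counts <- function(count, n_eas) {
  stopifnot(n_eas > 0, count >= 0, count <= n_eas)
  count / n_eas
}

#' Fraction of existing analogs participating in Free-Wilson neighborhoods
#'
#' An EA belongs to a Free-Wilson neighborhood when it appears in at
#' least one quartet in any role (reference, single-exchange partner, or
#' existing target).
#'
#' @param series An `analog_series`.
#' @param quartets Optional precomputed quartets.
#' @return List with `count`, `n_eas` and `fraction`.
#' @export
fw_ea_fraction <- function(series, quartets = find_quartets(series)) {
  ids <- unique(c(quartets$ea_ref, quartets$ea_x, quartets$ea_y,
                  quartets$target_id[quartets$target_status == "FW_EA"]))
  ids <- ids[!is.na(ids)]
  n <- nrow(series$analogs)
  list(count = length(ids), n_eas = n,
       fraction = if (n > 0) length(ids) / n else 0)
}
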
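# Neighborhood-based diagnostic scoring.
#
# Each existing analog (EA) owns a chemical neighborhood (NBH): the closed
# ball of a fixed radius around its descriptor vector in standardized
# space. Virtual analogs (VAs) falling into these balls drive four scores:
#
#   C (coverage):    fraction of VAs inside at least one NBH.
#   D (density):     1 - 1/d_mean, where d_mean is the mean NBH-membership
#                    multiplicity over covered VAs.
#   S (saturation):  harmonic mean of C and D.
#   P (progression): weighted mean pairwise potency range among EAs whose
#                    NBHs jointly contain a VA (weights 1/m per VA with
#                    multiplicity m > 1).

#' Assign virtual analogs to existing-analog neighborhoods
#'
#' Membership uses the closed ball: VA v belongs to NBH(e) iff the
#' standardized Euclidean distance d(v, e) <= radius.
#'
#' @param ea_vectors Descriptor matrix of EAs (rows named by EA id).
#' @param va_vectors Descriptor matrix of VAs (rows named by VA id).
#' @param radius Nonnegative NBH radius in standardized-descriptor units.
#' @param space A `chem_space` standardizer.
#' @return An `nbh_assignment`: per-EA membership sets, per-VA
#'   multiplicities `m`, total VA count and the radius.
#' @export
assign_neighborhoods <- function(ea_vectors, va_vectors, radius, space) {
  stopifnot(radius >= 0)
  ea_vectors <- as.matrix(ea_vectors)
  va_vectors <- as.matrix(va_vectors)
  if (nrow(ea_vectors) == 0L) stop("empty EA input")
  if (nrow(va_vectors) == 0L) stop("empty VA input")
  if (is.null(rownames(ea_vectors)))
    rownames(ea_vectors) <- paste0("EA_", seq_len(nrow(ea_vectors)))
  if (is.null(rownames(va_vectors)))
    rownames(va_vectors) <- paste0("VA_", seq_len(nrow(va_vectors)))
  E <- standardize(ea_vectors, space)
  V <- standardize(va_vectors, space)
  D <- cross_distances(E, V)
  inside <- D <= radius
  membership <- lapply(seq_len(nrow(E)), function(i) {
    rownames(va_vectors)[inside[i, ]]
  })
  names(membership) <- rownames(ea_vectors)
  m <- colSums(inside)
  names(m) <- rownames(va_vectors)
  structure(list(radius = radius, membership = membership,
                 multiplicity = m, va_count_total = nrow(va_vectors),
                 inside = inside),
            class = "nbh_assignment")
}

#' @export
print.nbh_assignment <- function(x, ...) {
  cat("<nbh_assignment> ", length(x$membership), " EAs, ",
      x$va_count_total, " VAs, radius ", format(x$radius), "; covered VAs: ",
      sum(x$multiplicity >= 1), "\n", sep = "")
  invisible(x)
}

#' Coverage score C
#'
#' Fraction of projected VAs that fall into at least one EA neighborhood.
#'
#' @param a An `nbh_assignment`.
#' @return C in \[0, 1\].
#' @export
coverage_score <- function(a) {
  stopifnot(inherits(a, "nbh_assignment"))
  if (a$va_count_total == 0L) stop("no VAs in assignment")
  sum(a$multiplicity >= 1) / a$va_count_total
}

#' Density score D
#'
#' `D = 1 - 1/d_mean` with `d_mean` the mean NBH-membership multiplicity
#' over covered VAs (VAs inside at least one NBH), so `d_mean >= 1` and
#' `D` lies in \[0, 1). When no VA is covered there is no overlap
#' information and D is defined as 0.
#'
#' @param a An `nbh_assignment`.
#' @return D in \[0, 1).
#' @export
density_score <- function(a) {
  stopifnot(inherits(a, "nbh_assignment"))
  m <- a$multiplicity[a$multiplicity >= 1]
  if (length(m) == 0L) return(0)
  d_mean <- mean(m)
  1 - 1 / d_mean
}

#' Saturation score S
#'
#' Harmonic mean of the coverage and density scores; 0 when both are 0.
#'
#' @param C,D Coverage and density scores in \[0, 1\].
#' @return S between min(C, D) and max(C, D).
#' @export
saturation_score <- function(C, D) {
  stopifnot(C >= 0, C <= 1, D >= 0, D <= 1)
  if (C + D == 0) return(0)
  2 * C * D / (C + D)
}

#' SAR progression score P
#'
#' For each covered VA i with multiplicity m_i, the mean absolute pairwise
#' potency difference over the m_i EAs whose NBHs contain it is computed;
#' the P score is the weighted mean of these per-VA terms with weights
#' w_i = 1/m_i for m_i > 1 and w_i = 0 for m_i = 1. P = 0 when no VA lies
#' in overlapping neighborhoods.
#'
#' @param a An `nbh_assignment`.
#' @param potencies Named numeric vector: pIC50 per EA id.
#' @return P >= 0 (pIC50 units).
#' @export
progression_score <- function(a, potencies) {
  stopifnot(inherits(a, "nbh_assignment"))
  ea_ids <- names(a$membership)
  overl <- which(a$multiplicity > 1)
  if (length(overl) == 0L) return(0)
  needed <- ea_ids[rowSums(a$inside[, overl, drop = FALSE]) > 0]
  missing_pot <- needed[!(needed %in% names(potencies)) |
                          !is.finite(potencies[needed])]
  if (length(missing_pot))
    stop("missing potency for EA(s): ", paste(missing_pot, collapse = ", "))
  num <- 0
  den <- 0
  for (v in overl) {
    eas <- ea_ids[a$inside[, v]]
    pots <- potencies[eas]
    m <- length(pots)
    delta_bar <- mean(abs(outer(pots, pots, "-"))[upper.tri(diag(m))])
    w <- 1 / m
    num <- num + w * delta_bar
    den <- den + w
  }
  num / den
}

#' Calibrate the NBH radius from a distance quantile
#'
#' Sets the radius to a quantile of all EA-VA standardized distances, so
#' that coverage responds predictably: quantiles near 1 give C near 1.
#'
#' @param ea_vectors,va_vectors Descriptor matrices.
#' @param space A `chem_space`.
#' @param target_quantile Quantile in (0, 1).
#' @return Radius (standardized distance units).
#' @export
calibrate_radius <- function(ea_vectors, va_vectors, space,
                             target_quantile = 0.05) {
  stopifnot(target_quantile > 0, target_quantile < 1)
  E <- standardize(as.matrix(ea_vectors), space)
  V <- standardize(as.matrix(va_vectors), space)
  d <- as.vector(cross_distances(E, V))
  unname(stats::quantile(d, target_quantile))
}

#' Scoring run configuration
#'
#' @param radius Fixed NBH radius, or `NULL` to calibrate from
#'   `auto_radius_quantile`.
#' @param auto_radius_quantile Distance quantile used when `radius` is
#'   `NULL` (default 0.05).
#' @param n_resamples Number of independent VA resamples (default 10).
#' @param sample_size VAs drawn per resample, without replacement
#'   (default 1000).
#' @param seed Integer seed; every stochastic step derives from it.
#' @param descriptors Descriptor names defining the reference space.
#' @return A `run_config` list.
#' @export
run_config <- function(radius = NULL, auto_radius_quantile = 0.05,
                       n_resamples = 10L, sample_size = 1000L, seed = 1L,
                       descriptors = default_descriptors()) {
  stopifnot(is.null(radius) || radius >= 0,
            n_resamples >= 1L, sample_size >= 1L)
  unknown <- setdiff(descriptors, ls(descriptor_registry))
  if (length(unknown))
    stop("unregistered descriptor(s): ", paste(unknown, collapse = ", "))
  structure(list(radius = radius,
                 auto_radius_quantile = auto_radius_quantile,
                 n_resamples = as.integer(n_resamples),
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed), descriptors = descriptors),
            class = "run_config")
}

#' Diagnostic scoring with VA resampling
#'
#' Computes C, D, S and P on `n_resamples` independent samples of
#' `sample_size` VAs drawn without replacement from the pool (seeded), and
#' reports mean and sample standard deviation per score. VAs whose
#' canonical SMILES equals an EA are removed from the pool before sampling
#' (they would trivially inflate coverage). Standardization is fitted on
#' the union of the EAs and the VA pool of this run.
#'
#' @param series An `analog_series` or compound table of EAs with
#'   `smiles` and `potency` columns.
#' @param va_pool Character vector of VA SMILES, or a compound table.
#' @param config A [run_config()].
#' @return A `score_report`.
#' @export
score_with_resampling <- function(series, va_pool, config = run_config()) {
  eas <- if (inherits(series, "analog_series")) series$analogs else series
  stopifnot(is.data.frame(eas), all(c("smiles", "potency") %in% names(eas)))
  if (!"id" %in% names(eas)) eas$id <- paste0("EA_", seq_len(nrow(eas)))
  vas <- if (is.data.frame(va_pool)) va_pool$smiles else va_pool
  vas <- unique(vas)
  vas <- setdiff(vas, eas$smiles)
  if (length(vas) < config$sample_size)
    stop("VA pool (", length(vas), " after deduplication) smaller than ",
         "sample_size (", config$sample_size, ")")
  if (config$sample_size < 2L * nrow(eas))
    warning("sample_size < 2 x number of EAs; scores may be unstable")

  ea_X <- compute_descriptors(eas$smiles, config$descriptors)
  rownames(ea_X) <- eas$id
  va_X <- compute_descriptors(vas, config$descriptors)
  rownames(va_X) <- vas
  space <- fit_standardizer(rbind(ea_X, va_X), fitted_on = "EAs + VA pool")
  radius <- config$radius
  if (is.null(radius))
    radius <- calibrate_radius(ea_X, va_X, space, config$auto_radius_quantile)

  potencies <- stats::setNames(eas$potency, eas$id)
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, config$n_resamples)
  per <- matrix(NA_real_, nrow = config$n_resamples, ncol = 4,
                dimnames = list(NULL, c("C", "D", "S", "P")))
  for (r in seq_len(config$n_resamples)) {
    set.seed(sample_seeds[r])
    take <- sample.int(length(vas), config$sample_size)
    a <- assign_neighborhoods(ea_X, va_X[take, , drop = FALSE], radius, space)
    C <- coverage_score(a)
    D <- density_score(a)
    per[r, ] <- c(C, D, saturation_score(C, D),
                  progression_score(a, potencies))
  }
  structure(list(
    scores = data.frame(score = colnames(per),
                        mean = colMeans(per),
                        sd = apply(per, 2, stats::sd),
                        row.names = colnames(per)),
    per_resample = per,
    radius = radius, n_resamples = config$n_resamples,
    sample_size = config$sample_size, seed = config$seed,
    n_eas = nrow(eas), n_vas_pool = length(vas),
    descriptors = config$descriptors,
    standardized_on = "EAs + VA pool"),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Diagnostic score report\n")
  cat("  EAs: ", x$n_eas, "   VA pool: ", x$n_vas_pool,
      "   resamples: ", x$n_resamples, " x ", x$sample_size, "\n", sep = "")
  cat("  NBH radius: ", format(round(x$radius, 4)),
      " (standardized units), seed ", x$seed, "\n", sep = "")
  for (s in rownames(x$scores)) {
    cat(sprintf("  %s score  %.2f (+/- %.2f)\n", s,
                x$scores[s, "mean"], x$scores[s, "sd"]))
  }
  invisible(x)
}
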
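# Chemical reference space.
#
# Analog series and virtual analogs are compared in a low-dimensional space
# of physicochemical descriptors. The default space has seven descriptors
# commonly tracked during lead optimization; the set is fully configurable
# through a registry of named descriptor functions.

# Registry of descriptor functions. Each takes (smiles, props) where props
# is the Open Babel property table for the same molecules, and returns a
# numeric vector.
descriptor_registry <- new.env(parent = emptyenv())

register_descriptor <- function(name, fun) {
  assign(name, fun, envir = descriptor_registry)
}

register_descriptor("mw",    function(smiles, props) props$MW)
register_descriptor("logp",  function(smiles, props) props$logP)
register_descriptor("hbd",   function(smiles, props) props$HBD)
register_descriptor("hba",   function(smiles, props) props$HBA1)
register_descriptor("tpsa",  function(smiles, props) props$TPSA)
register_descriptor("rotatable_bonds", function(smiles, props) {
  smarts_count(smiles, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
})
register_descriptor("aromatic_rings", function(smiles, props) {
  # 5- and 6-membered aromatic rings (the sizes aromatic rings take in
  # organic lead-optimization chemistry)
  smarts_count(smiles, "a1aaaa1") + smarts_count(smiles, "a1aaaaa1")
})

#' The default seven-descriptor chemical reference space
#'
#' Molecular weight, computed logP, H-bond donor and acceptor counts,
#' topological polar surface area, rotatable-bond count and aromatic ring
#' count — a standard set of lead-optimization-relevant physicochemical
#' descriptors.
#'
#' @return Character vector of descriptor names.
#' @export
default_descriptors <- function() {
  c("mw", "logp", "hbd", "hba", "tpsa", "rotatable_bonds", "aromatic_rings")
}

#' Compute descriptor vectors for a set of molecules
#'
#' Deterministic and canonicalization-invariant: any SMILES form of the
#' same molecule yields the identical vector.
#'
#' @param smiles Character vector of valid SMILES.
#' @param descriptors Ordered character vector of registered descriptor
#'   names (default: [default_descriptors()]).
#' @return Numeric matrix, one row per molecule, one column per descriptor.
#' @export
compute_descriptors <- function(smiles, descriptors = default_descriptors()) {
  unknown <- setdiff(descriptors, ls(descriptor_registry))
  if (length(unknown))
    stop("unregistered descriptor(s): ", paste(unknown, collapse = ", "))
  if (length(smiles) == 0L)
    return(matrix(numeric(0), ncol = length(descriptors),
                  dimnames = list(NULL, descriptors)))
  props <- ob_properties(smiles)
  X <- vapply(descriptors, function(d) {
    as.numeric(get(d, envir = descriptor_registry)(smiles, props))
  }, numeric(length(smiles)))
  rn <- if (is.null(names(smiles))) smiles else names(smiles)
  X <- matrix(X, nrow = length(smiles), dimnames = list(rn, descriptors))
  if (any(!is.finite(X)))
    stop("descriptor failure (non-finite value) for molecule(s): ",
         paste(which(rowSums(!is.finite(X)) > 0), collapse = ", "))
  X
}

#' Fit a standardization (z-scoring) of descriptor space
#'
#' Centers and scales are the per-dimension mean and population standard
#' deviation of the fitted vectors. Constant dimensions get scale 1 (they
#' carry no distance information) with a warning.
#'
#' @param X Descriptor matrix (rows = molecules).
#' @param fitted_on Optional label recording which population was used.
#' @return A `chem_space` object with `center` and `scale` vectors.
#' @export
fit_standardizer <- function(X, fitted_on = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 vectors to fit a standardizer")
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  const <- scale <= .Machine$double.eps * 100
  if (any(const)) {
    warning("constant descriptor dimension(s): ",
            paste(colnames(X)[const], collapse = ", "),
            "; scale set to 1")
    scale[const] <- 1
  }
  structure(list(center = center, scale = scale,
                 descriptors = colnames(X), fitted_on = fitted_on),
            class = "chem_space")
}

#' Transform descriptor vectors into standardized coordinates
#'
#' @param X Descriptor matrix or single vector.
#' @param space A `chem_space` from [fit_standardizer()].
#' @return Matrix of standardized coordinates.
#' @export
standardize <- function(X, space) {
  stopifnot(inherits(space, "chem_space"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(space$center))
    stop("descriptor set mismatch: expected ", length(space$center),
         " dimensions, got ", ncol(X))
  if (!is.null(colnames(X)) && !is.null(space$descriptors) &&
      !identical(colnames(X), space$descriptors))
    stop("descriptor set mismatch: ",
         paste(colnames(X), collapse = ","), " vs ",
         paste(space$descriptors, collapse = ","))
  sweep(sweep(X, 2, space$center), 2, space$scale, "/")
}

#' Euclidean distance between two descriptor vectors
#'
#' @param a,b Descriptor vectors over the same descriptor set.
#' @param space A `chem_space` used to standardize both.
#' @return Nonnegative distance in standardized coordinates.
#' @export
chem_distance <- function(a, b, space) {
  za <- standardize(a, space)
  zb <- standardize(b, space)
  sqrt(sum((za - zb)^2))
}

# All pairwise Euclidean distances between the rows of two standardized
# matrices (rows of E x rows of V).
cross_distances <- function(E, V) {
  e2 <- rowSums(E^2)
  v2 <- rowSums(V^2)
  d2 <- outer(e2, v2, "+") - 2 * tcrossprod(E, V)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Principal component projection of descriptor vectors
#'
#' @param X Descriptor matrix (typically standardized beforehand, or raw —
#'   set `scale.` accordingly).
#' @param k Number of components.
#' @param scale. Passed to [stats::prcomp()]; default TRUE (correlation
#'   PCA), matching projection of heterogeneous descriptors.
#' @return List with `coordinates` (n x k), `explained` (variance
#'   fractions, non-increasing) and the `prcomp` fit.
#' @export
project_pca <- function(X, k = 2, scale. = TRUE) {
  X <- as.matrix(X)
  if (k > ncol(X)) stop("k exceeds dimensionality")
  if (nrow(X) < k + 1) stop("need at least k+1 vectors")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (scale. && any(const)) {
    # constant columns cannot be scaled to unit variance; drop from the fit
    warning("dropping constant dimension(s) from PCA: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = scale.)
  rank <- sum(fit$sdev > fit$sdev[1] * 1e-12)
  if (rank < k) {
    warning("input rank ", rank, " < k = ", k,
            "; returning ", rank, " components")
    k <- rank
  }
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(coordinates = fit$x[, seq_len(k), drop = FALSE],
       explained = explained[seq_len(k)],
       fit = fit)
}
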
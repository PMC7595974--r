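# Global potency prediction.
#
# Compounds are encoded as folded 2048-bit extended-connectivity
# fingerprints (bond diameter 4) and modeled either with epsilon-SVR
# under the Tanimoto kernel or with linear ridge regression on the bit
# vector. Hyper-parameters are selected by an inner 3-fold CV nested in
# an outer 3-fold CV (double cross-validation); the final model is refit
# on all training data.

#' ECFP4 fingerprints (2048-bit folded)
#'
#' Extended-connectivity fingerprints of bond diameter 4, folded from the
#' backend's 4096-bit output to 2048 bits by OR-ing halves.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Binary matrix, rows = molecules, 2048 columns.
#' @export
ecfp4_fingerprints <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  mols <- ob_apply(smiles, identity)
  if (!is.list(mols)) mols <- list(mols)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  folded <- (fp[, 1:2048, drop = FALSE] + fp[, 2049:4096, drop = FALSE]) > 0
  storage.mode(folded) <- "integer"
  rownames(folded) <- names(smiles)
  folded
}

#' Tanimoto kernel between two fingerprint vectors
#'
#' `|a AND b| / |a OR b|`; the degenerate all-zero/all-zero case is
#' defined as 0 with a warning.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto_kernel <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  inter / uni
}

#' Tanimoto kernel matrix between fingerprint sets
#'
#' @param A,B Binary matrices (rows = molecules). `B` defaults to `A`.
#' @return `nrow(A) x nrow(B)` kernel matrix (positive semi-definite for
#'   `B = A`).
#' @export
tanimoto_kernel_matrix <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  inter <- tcrossprod(A, B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  K <- ifelse(uni == 0, 0, inter / uni)
  K
}

default_svr_grid <- function() {
  expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 0.5))
}

default_ridge_grid <- function() c(0.01, 0.1, 1, 10, 100)

cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

fit_svr <- function(K_train, y, C, epsilon) {
  kernlab::ksvm(kernlab::as.kernelMatrix(K_train), y, type = "eps-svr",
                C = C, epsilon = epsilon, scaled = FALSE)
}

predict_svr <- function(model, K_test_train) {
  idx <- kernlab::SVindex(model)
  as.numeric(kernlab::predict(
    model, kernlab::as.kernelMatrix(K_test_train[, idx, drop = FALSE])))
}

fit_ridge <- function(X, y, lambda) {
  glmnet::glmnet(X, y, alpha = 0, lambda = lambda, standardize = FALSE)
}

#' Train a global potency model with double cross-validation
#'
#' Hyper-parameters are chosen on an inner 3-fold CV; generalization is
#' estimated on an outer 3-fold CV; the returned model is refit on all
#' training data with the hyper-parameters most often selected across
#' outer folds. Deterministic given the seed.
#'
#' @param smiles Training SMILES.
#' @param potency Training pIC50 values.
#' @param method `"svr"` (Tanimoto-kernel epsilon-SVR) or `"ridge"`
#'   (linear ridge on fingerprint bits).
#' @param n_folds Folds for both CV levels (default 3).
#' @param seed Integer seed for fold assignment.
#' @param svr_grid,ridge_grid Hyper-parameter grids.
#' @return A `potency_model` with `outer_cv` (per-fold R2/MAE) and the
#'   refit model.
#' @export
train_global_model <- function(smiles, potency, method = c("svr", "ridge"),
                               n_folds = 3L, seed = 1L,
                               svr_grid = default_svr_grid(),
                               ridge_grid = default_ridge_grid()) {
  method <- match.arg(method)
  stopifnot(length(smiles) == length(potency), all(is.finite(potency)))
  n <- length(smiles)
  if (stats::sd(potency) == 0) stop("degenerate training set: constant potency")
  if (n < 30L) warning("fewer than 30 training compounds; model may be weak")
  X <- ecfp4_fingerprints(smiles)
  K <- if (method == "svr") tanimoto_kernel_matrix(X) else NULL

  inner_select <- function(train_idx, fold_seed) {
    folds <- cv_folds(length(train_idx), n_folds, fold_seed)
    score_one <- function(par) {
      errs <- vapply(seq_len(n_folds), function(f) {
        tr <- train_idx[folds != f]; va <- train_idx[folds == f]
        pred <- if (method == "svr") {
          m <- fit_svr(K[tr, tr, drop = FALSE], potency[tr],
                       par$C, par$epsilon)
          predict_svr(m, K[va, tr, drop = FALSE])
        } else {
          m <- fit_ridge(X[tr, , drop = FALSE], potency[tr], par$lambda)
          as.numeric(stats::predict(m, X[va, , drop = FALSE]))
        }
        mean((pred - potency[va])^2)
      }, numeric(1))
      mean(errs)
    }
    if (method == "svr") {
      scores <- vapply(seq_len(nrow(svr_grid)), function(i) {
        score_one(svr_grid[i, ])
      }, numeric(1))
      svr_grid[which.min(scores), ]
    } else {
      scores <- vapply(ridge_grid, function(l) score_one(list(lambda = l)),
                       numeric(1))
      list(lambda = ridge_grid[which.min(scores)])
    }
  }

  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, n_folds + 1L)
  outer <- cv_folds(n, n_folds, fold_seeds[n_folds + 1L])
  outer_rows <- list()
  chosen <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(outer != f); te <- which(outer == f)
    par <- inner_select(tr, fold_seeds[f])
    chosen[[f]] <- par
    pred <- if (method == "svr") {
      m <- fit_svr(K[tr, tr, drop = FALSE], potency[tr], par$C, par$epsilon)
      predict_svr(m, K[te, tr, drop = FALSE])
    } else {
      m <- fit_ridge(X[tr, , drop = FALSE], potency[tr], par$lambda)
      as.numeric(stats::predict(m, X[te, , drop = FALSE]))
    }
    outer_rows[[f]] <- data.frame(
      fold = f, n_test = length(te),
      r_squared = r_squared(potency[te], pred),
      mae = mean(abs(pred - potency[te])))
  }
  outer_cv <- do.call(rbind, outer_rows)
  # refit on everything with the modal hyper-parameter choice
  key <- vapply(chosen, function(p) paste(unlist(p), collapse = "_"),
                character(1))
  par <- chosen[[which.max(ave(seq_along(key), key, FUN = length))]]
  final <- if (method == "svr") {
    fit_svr(K, potency, par$C, par$epsilon)
  } else {
    fit_ridge(X, potency, par$lambda)
  }
  structure(list(method = method, model = final, params = par,
                 train_fingerprints = X, train_potency = potency,
                 outer_cv = outer_cv, seed = seed),
            class = "potency_model")
}

#' @export
print.potency_model <- function(x, ...) {
  cat("<potency_model> ", x$method, ", n_train = ",
      length(x$train_potency), "\n", sep = "")
  cat(sprintf("  outer-CV R2 %.2f (+/- %.2f), MAE %.2f (+/- %.2f)\n",
              mean(x$outer_cv$r_squared), stats::sd(x$outer_cv$r_squared),
              mean(x$outer_cv$mae), stats::sd(x$outer_cv$mae)))
  invisible(x)
}

# Coefficient of determination (R^2): 1 - SS_res / SS_tot.
r_squared <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}

predict_potency <- function(model, smiles) {
  stopifnot(inherits(model, "potency_model"))
  if (length(smiles) == 0L) return(numeric(0))
  X <- ecfp4_fingerprints(smiles)
  if (model$method == "svr") {
    K <- tanimoto_kernel_matrix(X, model$train_fingerprints)
    predict_svr(model$model, K)
  } else {
    as.numeric(stats::predict(model$model, X))
  }
}

#' Evaluate a potency model on a held-out test set
#'
#' @param model A `potency_model`.
#' @param smiles,potency Test compounds and observed pIC50 values.
#' @return A `model_evaluation`: coefficient of determination `r_squared`,
#'   `mae` (pIC50 units) and `n_test`.
#' @export
evaluate_model <- function(model, smiles, potency) {
  stopifnot(length(smiles) == length(potency), length(smiles) > 0L)
  pred <- predict_potency(model, smiles)
  structure(list(r_squared = r_squared(potency, pred),
                 mae = mean(abs(pred - potency)),
                 n_test = length(potency), predictions = pred),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> R2 = %.3f, MAE = %.3f (n = %d)\n",
              x$r_squared, x$mae, x$n_test))
  invisible(x)
}

#' Predict and rank a virtual-analog population
#'
#' @param model A `potency_model`.
#' @param vas Compound table of VAs (any mix of origins).
#' @return data.frame sorted by descending predicted pIC50 (stable
#'   canonical-SMILES tie-break) with columns id, smiles, origin,
#'   predicted, rank; per-origin quartiles in `attr(x, "quantiles")`.
#' @export
predict_population <- function(model, vas) {
  if (is.null(vas) || nrow(vas) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      origin = character(0), predicted = numeric(0),
                      rank = integer(0)))
  pred <- predict_potency(model, vas$smiles)
  out <- data.frame(id = vas$id, smiles = vas$smiles, origin = vas$origin,
                    predicted = pred, stringsAsFactors = FALSE)
  out <- out[order(-out$predicted, out$smiles, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  qs <- do.call(rbind, lapply(split(out$predicted, out$origin), function(p) {
    stats::quantile(p, c(0, 0.25, 0.5, 0.75, 1))
  }))
  attr(out, "quantiles") <- qs
  out
}

#' Stratified 50/50 split of a series for external validation
#'
#' Splits existing analogs into training and held-out halves, stratified
#' by potency quartile so both halves span the potency range.
#'
#' @param series An `analog_series` or compound table with potencies.
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed.
#' @return List with `train` and `test` compound tables.
#' @export
split_series <- function(series, fraction = 0.5, seed = 1L) {
  eas <- if (inherits(series, "analog_series")) series$analogs else series
  stopifnot(all(is.finite(eas$potency)))
  q <- stats::quantile(eas$potency, c(0.25, 0.5, 0.75))
  stratum <- findInterval(eas$potency, q)
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_len(nrow(eas)), stratum), function(i) {
    sample(i, round(length(i) * fraction))
  }))
  list(train = eas[sort(train_idx), , drop = FALSE],
       test = eas[-sort(train_idx), , drop = FALSE])
}
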
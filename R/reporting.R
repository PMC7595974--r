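# Diagnostic narrative: development-stage classification, strategy
# recommendation and standard figures.

#' Default stage-classification thresholds
#'
#' The saturation/progression scores only support relative staging; these
#' cutoffs formalize it and are fully configurable. `s_floor` marks a
#' series with essentially no chemical-space saturation; `s_high` splits
#' moderately from highly saturated series; `p_high` marks strong SAR
#' progression (large potency swings in overlapping neighborhoods).
#'
#' @return Named list of thresholds.
#' @export
default_stage_thresholds <- function() {
  list(s_floor = 0.15, s_high = 0.5, p_high = 0.8)
}

#' Classify the development stage of a series
#'
#' Deterministic 2x2 rule over (S, P): saturation below `s_floor` is
#' `early` regardless of P; moderate saturation is `early_mid` under
#' strong progression, else `mid`; high saturation is `mid` under strong
#' progression, else `late`. Increasing S (P fixed) never yields an
#' earlier label.
#'
#' @param report A `score_report` (or list with `scores` containing S
#'   and P means).
#' @param thresholds See [default_stage_thresholds()].
#' @return A `stage_assessment` with `stage`, the scores and thresholds
#'   used, and a one-line rationale.
#' @export
classify_stage <- function(report, thresholds = default_stage_thresholds()) {
  s <- report$scores["S", "mean"]
  p <- report$scores["P", "mean"]
  stage <- if (s < thresholds$s_floor) "early"
  else if (s < thresholds$s_high) {
    if (p >= thresholds$p_high) "early_mid" else "mid"
  } else {
    if (p >= thresholds$p_high) "mid" else "late"
  }
  rationale <- sprintf(
    "S = %.2f (%s saturation), P = %.2f (%s SAR progression)",
    s, if (s >= thresholds$s_high) "high" else if (s >= thresholds$s_floor)
      "moderate" else "minimal",
    p, if (p >= thresholds$p_high) "strong" else "balanced")
  structure(list(stage = stage, s_score = s, p_score = p,
                 thresholds = thresholds, rationale = rationale),
            class = "stage_assessment")
}

#' @export
print.stage_assessment <- function(x, ...) {
  cat("<stage_assessment> ", x$stage, " (", x$rationale, ")\n",
      "  thresholds: s_floor = ", x$thresholds$s_floor,
      ", s_high = ", x$thresholds$s_high,
      ", p_high = ", x$thresholds$p_high, "\n", sep = "")
  invisible(x)
}

#' Default mapping from development stage to design strategies
#'
#' @return Named list: stage -> character vector of strategies, best
#'   first.
#' @export
default_strategy_map <- function() {
  list(
    early = c("diverse", "sampled", "close_in", "fw"),
    early_mid = c("diverse", "sampled", "close_in", "fw"),
    mid = c("close_in", "sampled", "fw", "diverse"),
    late = c("fw", "close_in", "sampled", "diverse"))
}

#' Rank virtual-analog design strategies for an assessed series
#'
#' Late-stage series favor conservative designs (Free-Wilson, close-in);
#' early-stage series favor explorative ones (diverse, sampled).
#'
#' @param assessment A `stage_assessment`.
#' @param strategy_map Override of [default_strategy_map()].
#' @return Character vector of strategies, best first.
#' @export
recommend_strategy <- function(assessment,
                               strategy_map = default_strategy_map()) {
  stopifnot(inherits(assessment, "stage_assessment"),
            assessment$stage %in% names(strategy_map))
  strategy_map[[assessment$stage]]
}

#' Quantiles of predicted potency per population
#'
#' The boxplot-ready summary backing the prediction figures.
#'
#' @param predictions Output of [predict_population()].
#' @return Matrix of quantiles (rows = origins).
#' @export
prediction_quantiles <- function(predictions) {
  do.call(rbind, lapply(split(predictions$predicted, predictions$origin),
                        function(p) {
                          stats::quantile(p, c(0, 0.25, 0.5, 0.75, 1))
                        }))
}

#' Render the standard diagnostic figures
#'
#' Produces whichever figures the inputs support: PCA scatter of EAs vs
#' VA populations (axes annotated with explained variance), per-epoch
#' sampling curves, score bars with error bars, and predicted-potency
#' boxplots per population. Missing inputs skip the corresponding figure
#' with a log message.
#'
#' @param dir Output directory (created if needed).
#' @param populations Optional named list of compound tables (first
#'   entry is treated as the reference/EA population).
#' @param epoch_metrics Optional metrics from [transfer_learn()].
#' @param report Optional `score_report`.
#' @param predictions Optional output of [predict_population()].
#' @param descriptors Descriptor set for the PCA projection.
#' @return Character vector of written files (invisibly).
#' @export
render_figures <- function(dir, populations = NULL, epoch_metrics = NULL,
                           report = NULL, predictions = NULL,
                           descriptors = default_descriptors()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save_plot <- function(name, p) {
    path <- file.path(dir, name)
    grDevices::png(path, width = 900, height = 700, res = 120)
    print(p)
    grDevices::dev.off()
    written <<- c(written, path)
  }

  if (!is.null(populations)) {
    smi <- unlist(lapply(populations, function(p) p$smiles), use.names = FALSE)
    grp <- rep(names(populations),
               vapply(populations, nrow, integer(1)))
    X <- compute_descriptors(smi, descriptors)
    pca <- project_pca(X, k = 2)
    df <- data.frame(PC1 = pca$coordinates[, 1], PC2 = pca$coordinates[, 2],
                     population = grp)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          color = .data$population)) +
      ggplot2::geom_point(alpha = 0.6, size = 1.3) +
      ggplot2::labs(
        x = sprintf("PC1 (%.1f%% of variance)", 100 * pca$explained[1]),
        y = sprintf("PC2 (%.1f%% of variance)", 100 * pca$explained[2])) +
      ggplot2::theme_bw()
    save_plot("chemical_space_pca.png", p)
  } else message("render_figures: no populations; skipping PCA plot")

  if (!is.null(epoch_metrics)) {
    long <- do.call(rbind, lapply(
      c("n_valid", "n_unique", "n_with_core", "n_reproduced_eas"),
      function(v) data.frame(epoch = epoch_metrics$epoch,
                             count = epoch_metrics[[v]], metric = v)))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$count,
                                            color = .data$metric)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "fine-tuning epoch", y = "sampled VAs") +
      ggplot2::theme_bw()
    save_plot("tl_epoch_curves.png", p)
  } else message("render_figures: no epoch metrics; skipping curves")

  if (!is.null(report)) {
    df <- report$scores
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$mean)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             width = 0.2) +
      ggplot2::labs(x = NULL, y = "score (mean +/- sd over resamples)") +
      ggplot2::theme_bw()
    save_plot("diagnostic_scores.png", p)
  } else message("render_figures: no score report; skipping score bars")

  if (!is.null(predictions) && nrow(predictions) > 0) {
    p <- ggplot2::ggplot(predictions,
                         ggplot2::aes(.data$origin, .data$predicted)) +
      ggplot2::geom_boxplot(fill = "grey80") +
      ggplot2::labs(x = NULL, y = "predicted pIC50") +
      ggplot2::theme_bw()
    save_plot("predicted_potency.png", p)
  } else message("render_figures: no predictions; skipping boxplots")

  invisible(written)
}
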
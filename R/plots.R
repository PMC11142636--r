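#' Plot a study result
#'
#' One panel per metric: per-instance values (jittered points) with the
#' mean and twice the standard error overlaid.
#'
#' @param object An `ego_study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ego_study_result
#' @export
autoplot.ego_study_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$instances,
    cols = -dplyr::any_of(c("instance", "seed", "condition")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(
      fun.data = ggplot2::mean_se, fun.args = list(mult = 2),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf(
        "Study %d (%s, %s): per-instance metrics",
        object$study, object$condition, object$model
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a smoothed accuracy curve from a per-trial log
#'
#' Moving-average accuracy over trials, with phase boundaries marked. The
#' smoothing is for display only; statistics elsewhere use the raw values.
#'
#' @param log A per-trial log tibble with `correct` and a `phase` column
#'   (from a `study2_run`, `study2_baseline_run`, or `study3_run`).
#' @param window Moving-average window in trials.
#' @return A ggplot object.
#' @export
plot_accuracy_curve <- function(log, window = 25) {
  acc <- as.numeric(log$correct)
  sm <- stats::filter(acc, rep(1 / window, window), sides = 1)
  df <- tibble::tibble(
    trial = seq_along(acc), accuracy = as.numeric(sm),
    phase = log$phase
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$trial, .data$accuracy, colour = .data$phase)
  ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "trial", y = sprintf("accuracy (%d-trial moving average)", window)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a context-similarity matrix
#'
#' @param sim A similarity matrix from [context_similarity_matrix()].
#' @return A ggplot object.
#' @export
plot_context_similarity <- function(sim) {
  df <- tidyr::expand_grid(i = seq_len(nrow(sim)), j = seq_len(ncol(sim)))
  df$similarity <- sim[cbind(df$i, df$j)]
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$j, .data$i, fill = .data$similarity)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      low = "black", mid = "grey50",
      high = "white", limits = c(-1, 1)
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine") +
    ggplot2::theme_minimal()
}

#' Scatter of a two-dimensional MDS embedding of hidden representations
#'
#' @param run A `study3_run`.
#' @return A ggplot object: one point per stimulus-by-context condition,
#'   coloured by the two feature values, shaped by context.
#' @export
plot_mds_representations <- function(run) {
  stopifnot(inherits(run, "study3_run"))
  coords <- mds_embed(run$reps, 2)
  df <- dplyr::bind_cols(run$conditions, coords)
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$dim1, .data$dim2,
      colour = .data$f2, size = .data$f1,
      shape = factor(.data$context)
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(
      shape = "context", colour = "feature 2", size = "feature 1",
      title = "Hidden-layer geometry (classical MDS)"
    ) +
    ggplot2::theme_minimal()
}
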
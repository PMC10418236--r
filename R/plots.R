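#' Plot normalized pairwise distance trajectories
#'
#' @param dtraj Output of [distance_trajectories()].
#' @return A ggplot.
#' @export
plot_distance_trajectories <- function(dtraj) {
  ggplot2::ggplot(dtraj, ggplot2::aes(x = .data$time_s,
                                      y = .data$distance_norm,
                                      colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = 0, xmax = 2, ymin = -Inf, ymax = Inf,
                      alpha = 0.1) +
    ggplot2::labs(x = "time from odor onset (s)",
                  y = "normalized population distance", colour = "odor pair") +
    ggplot2::theme_minimal()
}

#' Plot a cross-pair generalization matrix
#'
#' @param gm Output of [generalization_matrix()].
#' @return A ggplot heat map (rows = training pair, columns = testing pair).
#' @export
plot_generalization_matrix <- function(gm) {
  tbl <- tibble::as_tibble(gm$accuracy, rownames = "train")
  long <- tidyr::pivot_longer(tbl, -"train", names_to = "test",
                              values_to = "accuracy")
  long$train <- factor(long$train, levels = rev(rownames(gm$accuracy)))
  long$test <- factor(long$test, levels = colnames(gm$accuracy))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$test, y = .data$train,
                                     fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1)) +
    ggplot2::labs(x = "testing pair", y = "training pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the valence/identity auROC quadrants
#'
#' @param labelled Output of [categorize_quadrants()].
#' @return A ggplot scatter with the threshold lines.
#' @export
plot_quadrants <- function(labelled) {
  theta <- attr(labelled, "theta") %||% 0.75
  ggplot2::ggplot(labelled,
                  ggplot2::aes(x = .data$auroc_intervalence,
                               y = .data$auroc_intravalence,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = theta, linetype = 2) +
    ggplot2::geom_hline(yintercept = theta, linetype = 2) +
    ggplot2::coord_fixed(xlim = c(0.4, 1), ylim = c(0.4, 1)) +
    ggplot2::labs(x = "intervalence auROC", y = "intravalence auROC") +
    ggplot2::theme_minimal()
}

#' Heat map of trial-averaged responses
#'
#' @param object A `trial_tensor`.
#' @param ... Unused.
#' @return A ggplot: neurons x time, faceted by odor.
#' @export
autoplot.trial_tensor <- function(object, ...) {
  labs <- object$trials
  odors <- sort(unique(labs$contingency))
  long <- purrr::map_dfr(odors, function(o) {
    j <- which(labs$contingency == o)
    m <- apply(object$values[, j, , drop = FALSE], c(1, 3), mean)
    tibble::tibble(
      contingency = o,
      neuron = rep(seq_len(nrow(m)), times = ncol(m)),
      time_s = rep(object$rel_frames / object$frame_rate_hz,
                   each = nrow(m)),
      dff = as.numeric(m)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$neuron,
                                     fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~contingency, nrow = 1) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time from odor onset (s)", y = "neuron",
                  fill = "dF/F") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
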
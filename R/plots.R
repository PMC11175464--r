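#' Plot the outcome walks of a task session
#'
#' @param task Tibble from [generate_task()].
#' @return A ggplot of both walks with the win/loss threshold.
#' @export
plot_walks <- function(task) {
  long <- tidyr::pivot_longer(task, c("p", "q"), names_to = "walk",
                              values_to = "points")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$points,
                                     color = .data$walk)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::facet_wrap(~block, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial", y = "outcome walk (points)",
                  color = "decision") +
    ggplot2::theme_minimal()
}

#' Plot the arbitration-weight trajectory
#'
#' @param latents Latent trace from [simulate_agent()] or [model_nll()].
#' @return A ggplot of the weight on the correct policy across trials.
#' @export
plot_arbitration <- function(latents) {
  d <- dplyr::distinct(latents, .data$block, .data$trial, .data$weight)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~block, labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "trial", y = "weight on correct policy") +
    ggplot2::theme_minimal()
}

#' Plot stay-regression effects
#'
#' Group-level win-stay/lose-shift coefficients with per-participant
#' estimates overlaid — the standard display for checking that the
#' relevant outcome, and not the irrelevant one, drives staying.
#'
#' @param x A `bandit_stay_fit` from [stay_regression()].
#' @return A ggplot.
#' @export
plot_stay_effects <- function(x) {
  terms <- c("relevant", "irrelevant", "relevant:irrelevant")
  g <- dplyr::filter(x$group, .data$term %in% terms)
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::labs(x = NULL, y = "regression weight on staying") +
    ggplot2::theme_minimal()
  if (!is.null(x$participants)) {
    pp <- dplyr::filter(x$participants, .data$term %in% terms)
    p <- p + ggplot2::geom_jitter(data = pp, width = 0.08, alpha = 0.4,
                                  size = 0.8)
  }
  p
}

#' Heatmap of a cluster-permutation t-map
#'
#' @param object A `bandit_clusters`.
#' @param ... Unused.
#' @return A ggplot of the channels x time t-map with family-wise
#'   significant clusters outlined by points.
#' @export
autoplot.bandit_clusters <- function(object, ...) {
  n_ch <- nrow(object$tmap); n_t <- ncol(object$tmap)
  tt <- object$times %||% seq_len(n_t)
  d <- tibble::tibble(
    channel = factor(rep(object$channels, n_t), levels = object$channels),
    time = rep(tt, each = n_ch),
    t = as.vector(object$tmap),
    label = as.vector(object$labels))
  sig <- object$clusters$cluster[object$clusters$p.value <= 0.05]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$channel,
                                       fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", high = "firebrick",
                                  mid = "white") +
    ggplot2::labs(x = if (is.null(object$times)) "sample" else "time (s)",
                  y = NULL, fill = "t") +
    ggplot2::theme_minimal()
  if (length(sig) > 0)
    p <- p + ggplot2::geom_point(data = dplyr::filter(d, .data$label %in% sig),
                                 size = 0.3, color = "black")
  p
}
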
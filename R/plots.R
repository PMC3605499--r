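#' Raster plot of a spike train
#'
#' Units on the vertical axis, time on the horizontal; cue spikes highlighted.
#' Optionally sorts units by the phases of a stored pattern, which makes a
#' successful replay appear as repeated diagonal stripes.
#'
#' @param object a `spike_train`.
#' @param sort_by optional [phase_pattern()] used to order the units.
#' @param max_units subsample to at most this many (evenly spaced) units for
#'   readability.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spike_train <- function(object, sort_by = NULL, max_units = 50, ...) {
  N <- attr(object, "n_units")
  ord <- if (is.null(sort_by)) seq_len(N) else order(sort_by$phases)
  keep <- ord[unique(round(seq(1, N, length.out = min(max_units, N))))]
  rank <- match(object$unit, keep)
  df <- object[!is.na(rank), , drop = FALSE]
  df$row <- rank[!is.na(rank)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$row,
                                   colour = .data$source)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_colour_manual(values = c(net = "black", cue = "deeppink")) +
    ggplot2::labs(x = "time (ms)",
                  y = if (is.null(sort_by)) "unit" else "unit (sorted by stored phase)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.spike_train
#' @param x a `spike_train`.
#' @param y ignored.
#' @export
plot.spike_train <- function(x, y, ...) print(autoplot.spike_train(x, ...))

#' Overlap trajectories plot
#'
#' One line per stored pattern; successful retrieval shows the cued pattern
#' near 1 and the others at the `1/sqrt(N)` floor.
#'
#' @param object an `overlap_series`.
#' @param ... unused.
#' @export
autoplot.overlap_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$overlap,
                                       colour = factor(.data$pattern_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (ms)", y = "|m(t)|", colour = "pattern") +
    ggplot2::theme_minimal()
}

#' Persistence-sweep plot
#'
#' The `P(S_tot > n)` curves for `n = 0, N/2, N` against the spiking
#' threshold, with the critical threshold marked.
#'
#' @param object a `persistence_sweep`.
#' @param ... unused.
#' @export
autoplot.persistence_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$sweep,
                              cols = c("p_s_gt_0", "p_s_gt_half_n", "p_s_gt_n"),
                              names_to = "curve", values_to = "probability")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$theta,
                                           y = .data$probability,
                                           colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_discrete(
      labels = c(p_s_gt_0 = "n = 0", p_s_gt_half_n = "n = N/2",
                 p_s_gt_n = "n = N")) +
    ggplot2::labs(x = expression(theta[th]), y = expression(P(S[tot] > n)),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$theta_crit)) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$theta_crit,
                                   linetype = "dashed")
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
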
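#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_abline facet_wrap labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Positional variance heatmap
#'
#' One panel per subtype; rows are events ordered by their
#' maximum-likelihood position, columns are sequence positions, fill is the
#' fraction of MCMC samples placing the event at that position. A tight
#' diagonal means a confidently ordered sequence.
#'
#' @param object A `positional_variance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.positional_variance <- function(object, ...) {
  d <- tidy(object)
  d$event <- factor(d$event, levels = rev(rownames(object[[1]])))
  ggplot(d, aes(x = .data$position, y = .data$event,
                fill = .data$probability)) +
    geom_tile() +
    facet_wrap(~ subtype, labeller = ggplot2::label_both) +
    scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    labs(x = "Sequence position", y = NULL,
         fill = "P(position)") +
    theme_minimal()
}

#' Expected z-score trajectories of a fitted model
#'
#' Piecewise-linear expected z per biomarker across stages, one panel per
#' subtype.
#'
#' @param object A `sustain_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sustain_fit <- function(object, ...) {
  grid <- object$grid
  d <- purrr::map_dfr(seq_along(object$sequences), function(c) {
    G <- traj_matrix(object$sequences[[c]], grid)
    tibble::tibble(
      subtype = c,
      biomarker = rep(rownames(G), times = ncol(G)),
      stage = rep(0:(ncol(G) - 1), each = nrow(G)),
      z = as.vector(G)
    )
  })
  ggplot(d, aes(x = .data$stage, y = .data$z, colour = .data$biomarker)) +
    geom_line() +
    facet_wrap(~ subtype, labeller = ggplot2::label_both) +
    labs(x = "Model stage", y = "Expected z-score", colour = NULL) +
    theme_minimal()
}

#' Baseline-versus-follow-up stage scatter plot
#'
#' Stage at the later scan against stage at the earlier scan per visit
#' pair; points on or above the identity line progressed or held their
#' stage.
#'
#' @param pairs A `visit_pairs` table.
#' @return A ggplot.
#' @export
plot_stage_progression <- function(pairs) {
  d <- dplyr::count(tibble::as_tibble(pairs),
                    .data$stage_earlier, .data$stage_later,
                    .data$subtype_earlier)
  ggplot(d, aes(x = .data$stage_earlier, y = .data$stage_later,
                size = .data$n)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_point(alpha = 0.6) +
    facet_wrap(~ subtype_earlier, labeller = ggplot2::label_both) +
    labs(x = "Stage at earlier scan", y = "Stage at follow-up",
         size = "Scans") +
    theme_minimal()
}
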
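#' Plot an efficiency frontier
#'
#' Utility-information view of a frontier: expected utility against mutual
#' information in bits.
#'
#' @param object A `br_frontier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.br_frontier <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mutual_info_bits, .data$expected_utility)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "I(W;A) [bits]", y = "expected utility",
                  title = "Utility-information efficiency frontier") +
    ggplot2::theme_minimal()
}

#' Plot a constrained-model curve
#'
#' @param object A `br_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.br_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mutual_info_bits, .data$expected_utility)) +
    ggplot2::geom_line(linewidth = 0.8, color = "darkgreen") +
    ggplot2::labs(x = "I(W;A) [bits]", y = "expected utility",
                  title = paste0("Constrained curve: ", attr(object, "family"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a stimulus-response channel
#'
#' @param object A `br_channel`.
#' @param ... Unused.
#' @return A ggplot object: world state on the abscissa, action on the
#'   ordinate, probability as fill.
#' @export
autoplot.br_channel <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$world_state, .data$action, fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "world state", y = "action", fill = "p(a|w)") +
    ggplot2::theme_minimal()
}

#' Plot mean abstraction level along a frontier
#'
#' Mean selected level (with the directed-standard-deviation band) as a
#' function of mutual information.
#'
#' @param frontier A `br_frontier`.
#' @return A ggplot object.
#' @export
plot_level_selection <- function(frontier) {
  ggplot2::ggplot(frontier, ggplot2::aes(.data$mutual_info_bits, .data$mean_level)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_level - .data$sigma_minus,
      ymax = .data$mean_level + .data$sigma_plus
    ), alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "I(W;A) [bits]", y = "mean abstraction level") +
    ggplot2::theme_minimal()
}
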
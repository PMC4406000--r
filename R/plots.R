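# ggplot2 displays for the main result types.

#' Plot a per-level decision summary
#'
#' Mean contribution per others'-average level with a +/- 1 SD ribbon;
#' the unconditional decision is drawn as a dashed reference line.
#'
#' @param object A `decision_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decision_summary <- function(object, ...) {
  per_level <- dplyr::filter(object, !is.na(.data$level))
  uc <- dplyr::filter(object, .data$decision == "UC")
  p <- ggplot2::ggplot(per_level, ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Others' average contribution (points)",
                  y = "Conditional contribution (points)")
  if (nrow(uc) == 1) {
    p <- p + ggplot2::geom_hline(yintercept = uc$mean, linetype = "dashed")
  }
  p
}

#' Plot cumulative score-payoff correlation curves
#'
#' One line per decision score; solid lines are Spearman correlations with
#' the cumulative mean payoff per round, dotted lines the partial
#' correlations controlling for the other scores.
#'
#' @param object A `pgg_curves` tibble from [payoff_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgg_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("rho", "partial_rho"),
                              names_to = "kind", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$value,
                                     colour = .data$score,
                                     linetype = .data$kind)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_linetype_manual(values = c(rho = "solid", partial_rho = "dotted")) +
    ggplot2::labs(x = "Rounds included", y = "Rank correlation with payoff/round",
                  colour = "Score", linetype = NULL)
}

#' Trace and posterior-density plot for an ACE fit
#'
#' @param object An `ace_fit`.
#' @param pars Parameters to display (default: the standardized shares).
#' @param ... Unused.
#' @return A ggplot object (traces faceted by parameter).
#' @export
autoplot.ace_fit <- function(object, pars = c("a2", "c2", "e2"), ...) {
  long <- tidyr::pivot_longer(object$draws, dplyr::all_of(pars),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Retained draw", y = "Value", colour = "Chain")
}
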
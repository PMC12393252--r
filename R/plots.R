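# ggplot2 displays for the main result types.

#' Plot probe placements along the target
#'
#' @param object A `fish_selection`.
#' @param ... Unused.
#' @return A ggplot: one rectangle per selected probe, coloured by phase.
#' @export
autoplot.fish_selection <- function(object, ...) {
  sel <- object$selected
  ggplot2::ggplot(sel) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$start + .data$length,
      ymin = 0, ymax = 1, fill = .data$phase)) +
    ggplot2::facet_wrap(~target_id, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "target position (nt)", y = NULL,
                  title = "Selected probe placements") +
    ggplot2::theme_minimal()
}

#' Plot on/off-target bound-count spectra
#'
#' @param object A `fish_specificity`.
#' @param ... Unused.
#' @return A ggplot of expected molecules per cell with n probes bound.
#' @export
autoplot.fish_specificity <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("n_on", "n_off"), names_to = "class",
                        values_to = "molecules")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$molecules,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "probes bound (n)",
                  y = "expected molecules per cell",
                  title = paste0("Bound-count spectra (", object$mode,
                                 " expression)")) +
    ggplot2::theme_minimal()
}

#' Plot the cumulative off-target accumulation curve
#'
#' @param report A `fish_specificity` (or the accumulation tibble from
#'   [offtarget_accumulation()]).
#' @return A ggplot of cumulative expected off-target bindings in selection
#'   order.
#' @export
plot_offtarget_accumulation <- function(report) {
  acc <- if (inherits(report, "fish_specificity")) report$accumulation
  else report
  acc$index <- seq_len(nrow(acc))
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$index, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "probes (selection order)",
                  y = "cumulative expected off-target bindings/cell",
                  title = "Off-target accumulation") +
    ggplot2::theme_minimal()
}

#' Plot per-site bound probabilities
#'
#' @param object A `fish_equilibrium`.
#' @param ... Unused.
#' @return A ggplot of site occupancy probabilities per target.
#' @export
autoplot.fish_equilibrium <- function(object, ...) {
  p <- site_bound_probability(object)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$site_id, y = .data$p)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~target_id, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "P(site bound)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
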
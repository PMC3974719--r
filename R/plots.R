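#' Plot relative error in spawning biomass over time
#'
#' One panel per scenario: per-iteration relative-error trajectories in
#' grey, the cross-iteration median in colour, and a zero reference line.
#'
#' @param ts A time-series results tibble (from [get_results_all()] or
#'   [get_results_scenario()]) containing `SSB_re`.
#' @return A ggplot object.
#' @export
plot_ssb_error <- function(ts) {
  stopifnot("SSB_re" %in% names(ts))
  med <- dplyr::summarise(dplyr::group_by(ts, .data$scenario, .data$year),
                          SSB_re = stats::median(.data$SSB_re, na.rm = TRUE),
                          .groups = "drop")
  ggplot2::ggplot(ts, ggplot2::aes(.data$year, .data$SSB_re)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$iteration),
                       colour = "grey70", linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line(data = med, colour = "steelblue",
                       linewidth = 0.9, na.rm = TRUE) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Year", y = "Relative error in SSB") +
    ggplot2::theme_bw()
}

#' Plot scalar relative-error distributions across scenarios
#'
#' Violin + jitter of the relative error of selected scalar quantities,
#' one panel per quantity.
#'
#' @param scalars A scalar results tibble with `_re` columns.
#' @param quantities Quantities to show (default depletion, M, SSB_MSY and
#'   terminal F).
#' @return A ggplot object.
#' @export
plot_scalar_error <- function(scalars,
                              quantities = c("depletion", "M", "SSB_MSY",
                                             "F_terminal")) {
  cols <- paste0(quantities, "_re")
  cols <- cols[cols %in% names(scalars)]
  long <- tidyr::pivot_longer(
    scalars[c("scenario", "iteration", cols)],
    dplyr::all_of(cols), names_to = "quantity", values_to = "re")
  long$quantity <- sub("_re$", "", long$quantity)
  ggplot2::ggplot(long, ggplot2::aes(.data$scenario, .data$re)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, na.rm = TRUE) +
    ggplot2::geom_jitter(width = 0.08, size = 0.6, alpha = 0.5,
                         na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Relative error") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
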
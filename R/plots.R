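# ggplot2 displays for the three result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_bw
NULL

#' Plot a simulated trajectory
#'
#' Time courses of the five g/L observables, faceted by variable.
#'
#' @param object a `succ_trajectory` from [simulate_batch()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.succ_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time_h", "glucose_gL", "biomass_gL", "SA_gL", "AA_gL", "FA_gL")],
    -"time_h", names_to = "variable", values_to = "gL")
  cfg <- attr(object, "config")
  ggplot(long, aes(x = .data$time_h, y = .data$gL)) +
    geom_line() +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "time (h)", y = "concentration (g/L)",
         title = if (!is.null(cfg)) paste("Batch", cfg$name) else NULL) +
    theme_bw()
}

#' Plot an initial-glucose sweep
#'
#' @param object a `succ_sweep` from [sweep_initial_glucose()].
#' @param ... unused.
#' @export
autoplot.succ_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"initial_glucose_gL",
                              names_to = "response", values_to = "gL")
  ggplot(long, aes(x = .data$initial_glucose_gL, y = .data$gL)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~response, scales = "free_y") +
    labs(x = "initial glucose (g/L)", y = "g/L") +
    theme_bw()
}

#' Plot a sensitivity table
#'
#' Total variation per parameter, faceted by experiment and coloured by
#' process group.
#'
#' @param object a `succ_sensitivity` from [sensitivity_table()].
#' @param ... unused.
#' @export
autoplot.succ_sensitivity <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$parameter, -.data$total),
                     y = .data$total, fill = .data$group)) +
    geom_col() +
    facet_wrap(~experiment, scales = "free_y") +
    labs(x = NULL, y = "total variation", fill = "process") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
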
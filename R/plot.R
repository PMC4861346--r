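# ggplot2 views of the result objects.

#' Plot a pump-leak trajectory
#'
#' Faceted time courses of the intracellular concentrations, membrane
#' potential and cell water content.
#'
#' @param object An `ion_trajectory`.
#' @param vars Which columns to facet; defaults to the four concentrations,
#'   potential and water content.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ion_trajectory <- function(object,
                                    vars = c("na", "k", "l", "cl",
                                             "U", "VA1000"), ...) {
  labels <- c(na = "[Na]i (mM)", k = "[K]i (mM)", l = "[Li]i (mM)",
              cl = "[Cl]i (mM)", U = "U (mV)",
              VA1000 = "(V/A) x 1000 (ml/mmol)",
              mun = "mu_Na (mV)", muk = "mu_K (mV)", mul = "mu_Li (mV)",
              mucl = "mu_Cl (mV)")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", vars)],
    -"t", names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars,
                          labels = ifelse(vars %in% names(labels),
                                          labels[vars], vars))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
}

#' Plot a flux decomposition
#'
#' Bars of the unidirectional influx and efflux (and the net flux marker)
#' per pathway, faceted by ion. Pathways with no traffic are dropped.
#'
#' @param object A [flux_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_table <- function(object, ...) {
  x <- tibble::as_tibble(object)
  active <- x$influx != 0 | x$efflux != 0
  x <- x[active, ]
  long <- tidyr::pivot_longer(x, c("influx", "efflux"),
                              names_to = "side", values_to = "flux")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pathway, y = .data$flux,
                                     fill = .data$side)) +
    ggplot2::geom_col(position = "identity") +
    ggplot2::geom_point(data = x, inherit.aes = FALSE,
                        mapping = ggplot2::aes(x = .data$pathway,
                                               y = .data$net)) +
    ggplot2::facet_wrap(~ion, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "flux (umol/min per ml cell water)",
                  fill = NULL)
}

#' Plot a tracer equilibration curve
#'
#' @param object A `tracer_curve` from [simulate_tracer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tracer_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$content)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "tracer content (mM)",
                  subtitle = paste0("direction: ",
                                    attr(object, "direction")))
}
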
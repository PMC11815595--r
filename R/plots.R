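#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Biomass and both substrates against time, one panel per variable (volume
#' is shown only when it changes, i.e. for fed-batch runs).
#'
#' @param object A `vk_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vk_trajectory <- function(object, ...) {
  keep <- c("biomass_gDW_L", "sucrose_g_L", "kno3_g_L")
  if (diff(range(object$volume_L)) > 1e-12) keep <- c(keep, "volume_L")
  long <- tidyr::pivot_longer(as.data.frame(object)[, c("time_d", keep)],
                              -"time_d", names_to = "variable")
  long$variable <- factor(long$variable, levels = keep)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_d, .data$value)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = NULL,
                  title = sprintf("%s model trajectory",
                                  attr(object, "model_type"))) +
    ggplot2::theme_minimal()
}

#' Plot a fit overlay: data points and model prediction
#'
#' @param object A `vk_fit`.
#' @param dt Integration step for the prediction curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vk_fit <- function(object, dt = 0.01, ...) {
  dat <- object$residuals
  tr <- simulate_batch(object$params, object$model_type, object$init,
                       tf = max(dat$time_d), dt = dt)
  curves <- tidyr::pivot_longer(
    as.data.frame(tr)[, c("time_d", "biomass_gDW_L", "sucrose_g_L",
                          "kno3_g_L")],
    -"time_d", names_to = "column", values_to = "predicted")
  map <- c(biomass_gDW_L = "biomass", sucrose_g_L = "sucrose",
           kno3_g_L = "kno3")
  curves$species <- map[curves$column]
  ggplot2::ggplot() +
    ggplot2::geom_point(data = dat,
                        ggplot2::aes(.data$time_d, .data$value),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$time_d, .data$predicted),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = "concentration (g L⁻¹)",
                  title = sprintf("%s fit (weighted SSE %.3g)",
                                  object$model_type, object$objective)) +
    ggplot2::theme_minimal()
}

#' Bar chart of a sensitivity ranking
#'
#' @param table A tibble from [sensitivity_table()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(table) {
  tbl <- dplyr::mutate(table,
                       parameter = stats::reorder(.data$parameter,
                                                  abs(.data$rps)))
  ggplot2::ggplot(tbl, ggplot2::aes(abs(.data$rps), .data$parameter)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|relative sensitivity|", y = NULL,
                  title = "Parameter sensitivity ranking") +
    ggplot2::theme_minimal()
}
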
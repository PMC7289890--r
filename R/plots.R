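#' Plot a fitted light response
#'
#' Daytime NEE against global radiation with the fitted rectangular
#' hyperbola overlaid.
#'
#' @param object A [fit_light_response()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.light_response <- function(object, ...) {
  grid <- tibble(rg = seq(0, max(object$data$rg), length.out = 200))
  grid$nee <- predict(object, grid$rg)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$rg, y = .data$nee)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.9) +
    ggplot2::labs(x = expression(R[g] ~ (W ~ m^-2)),
                  y = expression(NEE ~ (mu * mol ~ m^-2 ~ s^-1)),
                  title = "Light response of daytime NEE") +
    ggplot2::theme_minimal()
}

#' Plot daily cumulative carbon fluxes
#'
#' Daily sums of NEE, GPP and ecosystem respiration through the year
#' (uptake negative), the standard view of seasonal carbon dynamics.
#'
#' @param summary A [daily_and_seasonal_sums()] result (its `daily`
#'   attribute is used).
#' @return A ggplot object.
#' @export
plot_daily_fluxes <- function(summary) {
  daily <- attr(summary, "daily")
  if (is.null(daily)) abort("`summary` carries no daily table")
  ggplot2::ggplot(daily, ggplot2::aes(x = .data$date, y = .data$sum_gC,
                                      colour = .data$variable)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = expression(g ~ C ~ m^-2 ~ d^-1),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation heat map of fluxes and drivers
#'
#' @param cors A [correlation_matrix()] long tibble.
#' @param season Season to display (default first present).
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cors, season = cors$season[1]) {
  d <- cors[cors$season == season, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(d$r), "", sprintf("%.2f%s", d$r,
                                             ifelse(d$sig_05, "*", "")))),
      size = 2.8) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1),
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = paste("Pearson correlations,", season)) +
    ggplot2::theme_minimal()
}
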
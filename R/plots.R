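#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   facet_wrap labs theme_minimal geom_col coord_flip
#' @export
ggplot2::autoplot

#' Plot estimated prevalence trajectories with uncertainty
#'
#' Ribbon-and-line plot of the posterior mean and 95% interval per country and
#' indicator, with the survey observations overlaid when available.
#'
#' @param object A [bf_estimate_prevalence()] result.
#' @param countries Countries to show (default: first 4 of the grid).
#' @param indicators Indicators to show (default `exclusive_0_5`).
#' @param observations Optional observation tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bf_prevalence_fit
#' @export
autoplot.bf_prevalence_fit <- function(object,
                                       countries = NULL,
                                       indicators = "exclusive_0_5",
                                       observations = NULL, ...) {
  countries <- countries %||% head(unique(object$cells$country_id), 4)
  est <- dplyr::filter(object$estimates,
                       .data$country_id %in% countries,
                       .data$indicator %in% indicators)
  p <- ggplot(est, aes(x = .data$year, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$lower_95, ymax = .data$upper_95),
                fill = "steelblue", alpha = 0.25) +
    geom_line(colour = "steelblue") +
    facet_wrap(~ .data$country_id + .data$indicator) +
    labs(x = NULL, y = "prevalence") +
    theme_minimal()
  if (!is.null(observations)) {
    obs <- dplyr::filter(observations,
                         .data$country_id %in% countries,
                         .data$indicator %in% indicators)
    p <- p + geom_point(data = obs, aes(y = .data$value,
                                        shape = .data$subnational),
                        size = 1.5)
  }
  p
}

#' Plot per-quintile prevalence series and fitted trends
#'
#' @param object A [bf_quintile_trends()] object or the
#'   [bf_quintile_prevalence()] tibble it was fitted to.
#' @param quintile_prevalence The series tibble (required when `object` is a
#'   trends object).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bf_quintile_trends
#' @export
autoplot.bf_quintile_trends <- function(object, quintile_prevalence, ...) {
  qp <- dplyr::mutate(quintile_prevalence, quintile = factor(.data$quintile))
  ggplot(qp, aes(x = .data$year, y = .data$prevalence,
                 colour = .data$quintile)) +
    geom_point() +
    geom_line() +
    labs(x = NULL, y = "prevalence", colour = "wealth quintile",
         subtitle = sprintf("verdict: %s", object$verdict)) +
    theme_minimal()
}

#' Plot attributable burden by country
#'
#' Horizontal bar chart of mean attributable burden (one metric) for the
#' latest year, all ages and outcomes combined.
#'
#' @param object A [bf_burden_cra()] result.
#' @param metric `"DALYs"` (default) or `"deaths"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bf_burden
#' @export
autoplot.bf_burden <- function(object, metric = "DALYs", ...) {
  yr <- max(object$year)
  df <- object |>
    dplyr::filter(.data$metric == .env$metric, .data$year == yr) |>
    dplyr::group_by(.data$country_id) |>
    dplyr::summarise(attributable = sum(.data$attributable_mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$attributable) |>
    dplyr::mutate(country_id = factor(.data$country_id, levels = .data$country_id))
  ggplot(df, aes(x = .data$country_id, y = .data$attributable)) +
    geom_col(fill = "firebrick", alpha = 0.8) +
    coord_flip() +
    labs(x = NULL, y = sprintf("attributable %s, %d", metric, yr)) +
    theme_minimal()
}
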
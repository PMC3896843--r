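#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stage-1 covariate regression
#'
#' One row per coefficient with country-cluster-robust standard errors and
#' confidence intervals on t quantiles with (clusters - 1) degrees of
#' freedom.
#'
#' @param x A [bf_fit_stage1()] object.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @method tidy bf_stage1
#' @export
tidy.bf_stage1 <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  df <- x$n_clusters - 1
  tcrit <- qt(1 - (1 - conf.level) / 2, df)
  stat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pt(abs(stat), df, lower.tail = FALSE)),
    conf.low = unname(x$coefficients - tcrit * se),
    conf.high = unname(x$coefficients + tcrit * se)
  )
}

#' Glance at a stage-1 covariate regression
#'
#' @param x A [bf_fit_stage1()] object.
#' @param ... Unused.
#' @return One-row tibble `r.squared`, `adj.r.squared`, `sigma`, `nobs`,
#'   `n_clusters`.
#' @method glance bf_stage1
#' @export
glance.bf_stage1 <- function(x, ...) {
  sm <- summary(x$model)
  tibble::tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    nobs = nrow(x$residuals),
    n_clusters = x$n_clusters
  )
}

#' Tidy a quintile trend comparison
#'
#' @param x A [bf_quintile_trends()] object.
#' @param ... Unused.
#' @return Tibble `quintile`, `slope`, `se`, `z_excess`.
#' @method tidy bf_quintile_trends
#' @export
tidy.bf_quintile_trends <- function(x, ...) x$slopes

#' Glance at a quintile trend comparison
#'
#' @param x A [bf_quintile_trends()] object.
#' @param ... Unused.
#' @return One-row tibble `common_slope`, `f_statistic`, `p_value`, `verdict`.
#' @method glance bf_quintile_trends
#' @export
glance.bf_quintile_trends <- function(x, ...) {
  tibble::tibble(common_slope = x$common_slope, f_statistic = x$f_statistic,
                 p_value = x$p_value, verdict = x$verdict)
}
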
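#' Relative-risk table for suboptimal breastfeeding
#'
#' Ships the meta-analytic effect sizes used in the burden calculations:
#' relative risks (with 95% CIs) of diarrhea and pneumonia incidence and
#' mortality for predominant, partial and no breastfeeding in the 0-5 month
#' band (reference: exclusive breastfeeding) and for discontinued
#' breastfeeding in the 6-23 month band (reference: continued breastfeeding;
#' diarrhea only - no statistically significant published relative risks link
#' discontinued breastfeeding with pneumonia, so that pair is excluded).
#' Where no separate incidence estimate exists the mortality effect size is
#' assumed to apply equally to incidence. Reference categories are included
#' with RR 1.
#'
#' @return Tibble `exposure_category`, `age_group`, `outcome`, `metric`,
#'   `rr_mean`, `rr_lower`, `rr_upper`.
#' @export
bf_effect_sizes <- function() {
  rr <- tibble::tribble(
    ~exposure_category, ~age_group, ~outcome,    ~metric,     ~rr_mean, ~rr_lower, ~rr_upper,
    "predominant", "0-5mo",  "diarrhea",  "incidence",  1.26,  0.81,   1.95,
    "predominant", "0-5mo",  "diarrhea",  "mortality",  2.28,  0.85,   6.13,
    "predominant", "0-5mo",  "pneumonia", "incidence",  1.79,  1.29,   2.48,
    "predominant", "0-5mo",  "pneumonia", "mortality",  1.75,  0.48,   6.43,
    "partial",     "0-5mo",  "diarrhea",  "incidence",  1.68,  1.03,   2.76,
    "partial",     "0-5mo",  "diarrhea",  "mortality",  4.62,  1.81,  11.76,
    "partial",     "0-5mo",  "pneumonia", "incidence",  2.48,  0.23,  27.15,
    "partial",     "0-5mo",  "pneumonia", "mortality",  2.49,  1.03,   6.04,
    "none",        "0-5mo",  "diarrhea",  "incidence",  2.65,  1.72,   4.07,
    "none",        "0-5mo",  "diarrhea",  "mortality", 10.52,  2.79,  39.60,
    "none",        "0-5mo",  "pneumonia", "incidence",  2.07,  0.19,  22.64,
    "none",        "0-5mo",  "pneumonia", "mortality", 15.13,  0.61, 373.84,
    # no separate incidence estimate: mortality RR applied equally
    "discontinued", "6-23mo", "diarrhea", "incidence",  2.18,  1.14,   4.16,
    "discontinued", "6-23mo", "diarrhea", "mortality",  2.18,  1.14,   4.16
  )
  refs <- tidyr::expand_grid(
    tibble::tibble(exposure_category = c("exclusive", "continued"),
                   age_group = c("0-5mo", "6-23mo")),
    outcome = c("diarrhea", "pneumonia"),
    metric = c("incidence", "mortality")
  ) |>
    # continued breastfeeding is the 6-23mo reference; its pneumonia rows are
    # dropped along with the excluded (discontinued, pneumonia) pair
    dplyr::filter(!(.data$exposure_category == "continued" &
                      .data$outcome == "pneumonia")) |>
    dplyr::mutate(rr_mean = 1, rr_lower = 1, rr_upper = 1)
  bf_validate_effect_sizes(dplyr::bind_rows(rr, refs))
}

#' Validate an effect-size table
#'
#' Rejects tables with non-positive relative risks, confidence intervals that
#' do not bracket the mean, any (discontinued breastfeeding, pneumonia) row,
#' or any breastfeeding-initiation exposure (late initiation is excluded from
#' the attributable burden).
#'
#' @param effects Tibble with the [bf_effect_sizes()] schema.
#' @return The validated tibble, invisibly classed `bf_effect_sizes`.
#' @export
bf_validate_effect_sizes <- function(effects) {
  req <- c("exposure_category", "age_group", "outcome", "metric",
           "rr_mean", "rr_lower", "rr_upper")
  if (!all(req %in% names(effects))) {
    abort("effect-size table missing required columns", class = "bf_validation_error")
  }
  if (any(effects$rr_mean <= 0 | effects$rr_lower <= 0 | effects$rr_upper <= 0)) {
    abort("relative risks must be positive", class = "bf_validation_error")
  }
  if (any(effects$rr_lower > effects$rr_mean | effects$rr_mean > effects$rr_upper)) {
    abort("confidence interval does not bracket the mean RR",
          class = "bf_validation_error")
  }
  if (any(effects$exposure_category == "discontinued" &
            effects$outcome == "pneumonia")) {
    abort("(discontinued breastfeeding, pneumonia) is an excluded risk-outcome pair",
          class = "bf_validation_error")
  }
  if (any(grepl("initiation", effects$exposure_category))) {
    abort("late initiation is excluded from attributable burden",
          class = "bf_validation_error")
  }
  structure(effects, class = c("bf_effect_sizes", class(tibble::as_tibble(effects))))
}

#' Sample relative-risk draws from a published 95% CI
#'
#' Log-normal draws with median `rr_mean` and 2.5th/97.5th percentiles at
#' (`rr_lower`, `rr_upper`): `sigma = log(rr_upper / rr_lower) / (2 * 1.96)`.
#' A degenerate CI (`rr_lower == rr_upper`) yields constant draws. Intervals
#' crossing 1 are sampled as printed, without truncation.
#'
#' @param rr_mean,rr_lower,rr_upper Scalar RR and CI bounds.
#' @param n_draws Number of draws.
#' @param seed Seed.
#' @return Numeric vector of `n_draws` relative risks.
#' @export
bf_rr_draws <- function(rr_mean, rr_lower, rr_upper, n_draws = 1000L,
                        seed = 1L) {
  stopifnot(rr_lower <= rr_mean, rr_mean <= rr_upper, rr_lower > 0)
  sigma <- log(rr_upper / rr_lower) / (2 * qnorm(0.975))
  if (sigma == 0) return(rep(rr_mean, n_draws))
  with_seed(seed, rlnorm(n_draws, meanlog = log(rr_mean), sdlog = sigma))
}

#' Population attributable fraction for a categorical exposure
#'
#' Computes `(sum_i P_i RR_i - sum_i P'_i RR_i) / (sum_i P_i RR_i)`, the
#' proportional reduction in burden if the exposure distribution `P` were
#' shifted to the counterfactual `P'` (here 100% compliance with breastfeeding
#' recommendations, i.e. degenerate at the reference category). The exact
#' formula is used, with no approximation; with all `RR >= 1` and a
#' reference-category counterfactual the PAF lies in `[0, 1)`, but negative
#' values from RR draws below 1 are allowed and propagate.
#'
#' @param p Named vector of category prevalences summing to 1.
#' @param rr Named vector of relative risks for the same categories.
#' @param p_counterfactual Named vector of counterfactual prevalences summing
#'   to 1; default is degenerate at `reference`.
#' @param reference Reference category used for the default counterfactual.
#' @return Scalar PAF.
#' @export
bf_paf <- function(p, rr, p_counterfactual = NULL, reference = names(p)[1]) {
  cats <- names(p)
  if (is.null(cats) || is.null(names(rr))) {
    abort("p and rr must be named by exposure category", class = "bf_validation_error")
  }
  if (!setequal(cats, names(rr))) {
    abort("exposure categories of p and rr do not match", class = "bf_validation_error")
  }
  if (is.null(p_counterfactual)) {
    p_counterfactual <- stats::setNames(as.numeric(cats == reference), cats)
  }
  if (!setequal(cats, names(p_counterfactual))) {
    abort("counterfactual categories do not match", class = "bf_validation_error")
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(p_counterfactual) - 1) > 1e-6) {
    abort("exposure distributions must sum to 1", class = "bf_validation_error")
  }
  rr <- rr[cats]
  p_counterfactual <- p_counterfactual[cats]
  num <- sum(p * rr) - sum(p_counterfactual * rr)
  num / sum(p * rr)
}

#' Draw-level attributable burden for one cell
#'
#' Multiplies PAF draws by a non-negative background burden value, per draw,
#' and summarizes with the draw mean and 2.5th/97.5th percentiles.
#'
#' @param paf_draws Numeric vector of PAF draws.
#' @param background Scalar non-negative background burden (deaths or DALYs).
#' @return Tibble `paf_mean`, `paf_lower`, `paf_upper`, `attributable_mean`,
#'   `attributable_lower`, `attributable_upper`; attribute `draws` carries the
#'   attributable draws.
#' @export
bf_attributable_burden <- function(paf_draws, background) {
  if (background < 0) {
    abort("background burden must be non-negative", class = "bf_validation_error")
  }
  att <- paf_draws * background
  out <- tibble::tibble(
    paf_mean = mean(paf_draws),
    paf_lower = quantile(paf_draws, 0.025, names = FALSE),
    paf_upper = quantile(paf_draws, 0.975, names = FALSE),
    attributable_mean = mean(att),
    attributable_lower = quantile(att, 0.025, names = FALSE),
    attributable_upper = quantile(att, 0.975, names = FALSE)
  )
  attr(out, "draws") <- att
  out
}

# Map a burden metric to the RR metric used for its PAF. Child diarrhea and
# pneumonia DALYs are dominated by years of life lost, so DALY envelopes use
# the mortality effect sizes by default.
metric_rr_map <- function() c(deaths = "mortality", DALYs = "mortality")

#' Attributable burden across all countries, years and outcomes
#'
#' Runs the comparative risk assessment: for every (country, year, age band,
#' outcome, metric) background cell, builds the draw-level exposure
#' distribution from the prevalence fit (the 0-5 month composition for the
#' 0-5 month band; the duration-weighted continued/discontinued mix of the
#' 6-11 and 12-23 month indicators for the 6-23 month band), pairs it by draw
#' index with log-normal relative-risk draws, computes the PAF against the
#' 100%-compliance counterfactual, and multiplies by the background burden.
#' Initiation never enters, and no (discontinued, pneumonia) cell is ever
#' produced.
#'
#' @param fit A [bf_estimate_prevalence()] result.
#' @param background Background burden tibble (`country_id`, `year`, `cause`,
#'   `age_group`, `metric`, `value`), ages `0-5mo` and `6-23mo`, metrics
#'   `deaths` and `DALYs`.
#' @param effects Effect-size table (default [bf_effect_sizes()]).
#' @param counterfactual Either `"default"` (100% exclusive / 100% continued)
#'   or a named list with elements `"0-5mo"` and `"6-23mo"`, each a named
#'   prevalence vector summing to 1.
#' @param seed Seed for the RR draws.
#' @return Tibble of class `bf_burden`: one row per cell with PAF and
#'   attributable summaries; attribute `draws` holds the draw-level
#'   attributable matrix for aggregation.
#' @export
bf_burden_cra <- function(fit, background, effects = bf_effect_sizes(),
                          counterfactual = "default", seed = 1L) {
  effects <- bf_validate_effect_sizes(effects)
  n_draws <- ncol(fit$draws[[1]])
  cells <- fit$cells

  # exposure draws per age band, list of category -> matrix
  w11 <- 6 / 18; w23 <- 12 / 18  # band durations: 6-11mo (6 mo), 12-23mo (12 mo)
  cont <- w11 * fit$draws$continued_6_11 + w23 * fit$draws$continued_12_23
  exposure <- list(
    "0-5mo" = list(exclusive = fit$draws$exclusive_0_5,
                   predominant = fit$draws$predominant_0_5,
                   partial = fit$draws$partial_0_5,
                   none = fit$draws$none_0_5),
    "6-23mo" = list(continued = cont, discontinued = 1 - cont)
  )
  cf_default <- list(
    "0-5mo" = c(exclusive = 1, predominant = 0, partial = 0, none = 0),
    "6-23mo" = c(continued = 1, discontinued = 0)
  )
  cf <- if (identical(counterfactual, "default")) cf_default else counterfactual

  grid <- tidyr::expand_grid(
    age_group = names(exposure),
    outcome = c("diarrhea", "pneumonia"),
    metric = c("deaths", "DALYs")
  ) |>
    # pneumonia is not an outcome of discontinued breastfeeding
    dplyr::filter(!(.data$age_group == "6-23mo" & .data$outcome == "pneumonia"))

  results <- purrr::pmap_dfr(grid, function(age_group, outcome, metric) {
    cats <- names(exposure[[age_group]])
    rr_metric <- metric_rr_map()[[metric]]
    rrd <- vapply(cats, function(cat) {
      row <- effects[effects$exposure_category == cat &
                       effects$age_group == age_group &
                       effects$outcome == outcome &
                       effects$metric == rr_metric, ]
      if (nrow(row) != 1) {
        abort(sprintf("effect size missing for (%s, %s, %s, %s)",
                      cat, age_group, outcome, rr_metric),
              class = "bf_validation_error")
      }
      bf_rr_draws(row$rr_mean, row$rr_lower, row$rr_upper, n_draws,
                  seed = substream_seed(seed, paste(cat, age_group, outcome,
                                                    rr_metric)))
    }, numeric(n_draws))  # n_draws x cats

    # draw-level PAF for all cells at once
    num <- matrix(0, nrow(cells), n_draws)
    cf_term <- rep(0, n_draws)
    for (j in seq_along(cats)) {
      num <- num + exposure[[age_group]][[cats[j]]] *
        matrix(rrd[, j], nrow(cells), n_draws, byrow = TRUE)
      cf_term <- cf_term + cf[[age_group]][[cats[j]]] * rrd[, j]
    }
    paf <- sweep(num, 2, cf_term, "-") / num

    bg <- background[background$age_group == age_group &
                       background$cause == outcome &
                       background$metric == metric, ]
    idx <- match(paste(bg$country_id, bg$year),
                 paste(cells$country_id, cells$year))
    if (any(is.na(idx))) {
      abort("background cells outside the estimated grid",
            class = "bf_validation_error")
    }
    att <- paf[idx, , drop = FALSE] * bg$value
    tibble::tibble(
      country_id = bg$country_id, year = bg$year,
      age_group = age_group, outcome = outcome, metric = metric,
      background = bg$value,
      paf_mean = rowMeans(paf[idx, , drop = FALSE]),
      paf_lower = apply(paf[idx, , drop = FALSE], 1, quantile, 0.025, names = FALSE),
      paf_upper = apply(paf[idx, , drop = FALSE], 1, quantile, 0.975, names = FALSE),
      attributable_mean = rowMeans(att),
      attributable_lower = apply(att, 1, quantile, 0.025, names = FALSE),
      attributable_upper = apply(att, 1, quantile, 0.975, names = FALSE),
      .draws = lapply(seq_len(nrow(att)), function(i) att[i, ])
    )
  })
  class(results) <- c("bf_burden", class(results))
  results
}

#' Aggregate attributable burden at the draw level
#'
#' Sums attributable-burden cells over any grouping (e.g. global per year,
#' per region, all ages and outcomes combined) at the draw level, then
#' summarizes; mixing deaths and DALYs in one sum is an error.
#'
#' @param burden A [bf_burden_cra()] result (must still carry its `.draws`
#'   list column).
#' @param by Character vector of grouping columns (must include `metric` or
#'   the input must contain a single metric).
#' @return Tibble with grouping columns, `attributable_mean`,
#'   `attributable_lower`, `attributable_upper`, `background` (summed), and a
#'   `.draws` list column of summed draws.
#' @export
bf_aggregate_burden <- function(burden, by = c("year", "metric")) {
  if (!"metric" %in% by && dplyr::n_distinct(burden$metric) > 1) {
    abort("cannot sum deaths and DALYs together; include 'metric' in `by`",
          class = "bf_validation_error")
  }
  burden |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      background = sum(.data$background),
      .draws = list(Reduce(`+`, .data$.draws)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      attributable_mean = purrr::map_dbl(.data$.draws, mean),
      attributable_lower = purrr::map_dbl(.data$.draws, quantile, 0.025,
                                          names = FALSE),
      attributable_upper = purrr::map_dbl(.data$.draws, quantile, 0.975,
                                          names = FALSE),
      percent_of_total = 100 * .data$attributable_mean / .data$background
    )
}

#' Rank risk factors by attributable burden within countries
#'
#' Dense-ranks risks by descending attributable burden within each country
#' (ties broken deterministically by risk name, and flagged), and counts in
#' how many countries each risk ranks first.
#'
#' @param risk_burden Tibble `country_id`, `risk`, `value` (same metric and
#'   year throughout).
#' @return List of class `bf_risk_ranking`: `ranks` (tibble with `rank` and
#'   `tied` flag), `leading_counts` (tibble `risk`, `n_countries_leading`).
#' @export
bf_rank_risks <- function(risk_burden) {
  counts <- dplyr::count(risk_burden, .data$country_id)
  if (any(counts$n < 2)) {
    abort("need at least 2 risks per country to rank", class = "bf_validation_error")
  }
  ranks <- risk_burden |>
    dplyr::group_by(.data$country_id) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$risk, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::dense_rank(dplyr::desc(.data$value)),
      tied = duplicated(.data$value) | duplicated(.data$value, fromLast = TRUE)
    ) |>
    dplyr::ungroup()
  leading <- ranks |>
    dplyr::filter(.data$rank == 1, !duplicated(paste(.data$country_id, .data$rank))) |>
    dplyr::count(.data$risk, name = "n_countries_leading")
  leading <- dplyr::left_join(
    tibble::tibble(risk = unique(risk_burden$risk)), leading, by = "risk"
  ) |>
    dplyr::mutate(n_countries_leading = dplyr::coalesce(.data$n_countries_leading, 0L))
  structure(list(ranks = ranks, leading_counts = leading),
            class = "bf_risk_ranking")
}
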
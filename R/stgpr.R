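#' Screen candidate covariates by correlation with logit prevalence
#'
#' For each indicator-covariate pair with at least three paired points,
#' computes the Pearson correlation between the logit of the observed
#' prevalence and the covariate, and ranks candidates by absolute correlation
#' within indicator. This is a report only: the stage-1 regression always uses
#' the four fixed covariates (female education, log GDP per capita, child
#' underweight, total fertility rate) regardless of ranking.
#'
#' @param observations Survey observation tibble.
#' @param covariates Country-year covariate tibble; all non-key columns are
#'   treated as candidates.
#' @return Tibble `indicator`, `covariate`, `r`, `n`, `rank` (1 = strongest).
#' @export
bf_screen_covariates <- function(observations, covariates) {
  cand <- setdiff(names(covariates), c("country_id", "year"))
  obs <- observations |>
    dplyr::mutate(logit_value = logit(clamp_proportion(.data$value,
                                                       .data$sample_size))) |>
    dplyr::left_join(covariates, by = c("country_id", "year"))
  rows <- purrr::map_dfr(unique(obs$indicator), function(ind) {
    sub <- obs[obs$indicator == ind, ]
    purrr::map_dfr(cand, function(cv) {
      ok <- complete.cases(sub$logit_value, sub[[cv]])
      n <- sum(ok)
      if (n < 3) {
        warn(sprintf("covariate %s skipped for %s: fewer than 3 paired points",
                     cv, ind))
        return(tibble::tibble())
      }
      if (sd(sub[[cv]][ok]) == 0 || sd(sub$logit_value[ok]) == 0) {
        warn(sprintf("covariate %s skipped for %s: constant values", cv, ind))
        return(tibble::tibble())
      }
      tibble::tibble(indicator = ind, covariate = cv,
                     r = cor(sub$logit_value[ok], sub[[cv]][ok]), n = n)
    })
  })
  rows |>
    dplyr::group_by(.data$indicator) |>
    dplyr::mutate(rank = rank(-abs(.data$r), ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$indicator, .data$rank)
}

#' Stage 1: covariate regression of logit prevalence
#'
#' Ordinary least squares of the logit of the observed prevalence on the four
#' fixed country-year covariates. Coefficient uncertainty is reported with
#' country-cluster-robust standard errors (observations from the same country
#' share unmodelled country effects, which is exactly what stages 2 and 3
#' exploit; classical OLS intervals would be anti-conservative). Predictions
#' are produced for every country-year in the covariate table, including
#' country-years without data.
#'
#' @param observations Observation tibble for a single indicator or modelling
#'   target (columns `country_id`, `year`, `value`, `sample_size`, and
#'   optionally `variance`).
#' @param covariates Country-year covariate tibble containing the columns in
#'   `covariate_names`.
#' @param covariate_names Covariates to use (default the four fixed ones).
#' @return Object of class `bf_stage1`: list with `model` (the `lm`),
#'   `vcov` (cluster-robust), `coefficients`, `predictions` (tibble
#'   `country_id`, `year`, `stage1_logit`), `residuals` (per observation, with
#'   metadata carried through), `n_clusters`.
#' @export
bf_fit_stage1 <- function(observations, covariates,
                          covariate_names = bf_covariate_names()) {
  if (nrow(observations) < 10) {
    abort("stage-1 regression needs at least 10 observations",
          class = "bf_model_error")
  }
  obs <- observations |>
    dplyr::mutate(logit_value = logit(clamp_proportion(.data$value,
                                                       .data$sample_size))) |>
    dplyr::left_join(covariates, by = c("country_id", "year"))
  miss <- !complete.cases(obs[covariate_names])
  if (any(miss)) {
    abort(sprintf("covariates missing for %d observation country-year(s)",
                  sum(miss)), class = "bf_model_error")
  }
  X <- as.matrix(obs[covariate_names])
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(cbind(`(Intercept)` = 1, X)),
                       colnames(cbind(`(Intercept)` = 1, X))[keep])
    abort(paste0("rank-deficient stage-1 design; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "bf_model_error")
  }
  fml <- stats::reformulate(covariate_names, response = "logit_value")
  fit <- lm(fml, data = obs)
  vc <- sandwich::vcovCL(fit, cluster = obs$country_id, type = "HC3")
  preds <- covariates |>
    dplyr::mutate(stage1_logit = as.numeric(predict(fit, newdata = covariates))) |>
    dplyr::select("country_id", "year", "stage1_logit")
  resids <- obs |>
    dplyr::mutate(residual = .data$logit_value - as.numeric(stats::fitted(fit)))
  structure(list(
    model = fit,
    vcov = vc,
    coefficients = coef(fit),
    predictions = preds,
    residuals = resids,
    n_clusters = dplyr::n_distinct(obs$country_id)
  ), class = "bf_stage1")
}

#' @export
print.bf_stage1 <- function(x, ...) {
  cat("Stage-1 covariate regression (logit scale)\n")
  cat(sprintf("  %d observations in %d countries\n",
              nrow(x$residuals), x$n_clusters))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Spatio-temporal smoothing weights
#'
#' Parameters of the stage-2 locally weighted residual smoother. The time
#' weight is `(1 - u^e)^e` with `u = |year difference| / time_bandwidth`
#' (tricube for `e = 3`), zero beyond the bandwidth. The space weight is 1 for
#' the country's own residuals, `space_weight_region` for residuals from other
#' countries in the same region, `space_weight_super_region` for the rest of
#' the super-region, and 0 elsewhere. When a country's local pool contains
#' both nationally representative and subnational residuals, the subnational
#' contribution is renormalized to `1 - national_data_share` of that country's
#' pooled value.
#'
#' @param time_bandwidth Years.
#' @param time_exponent Exponent of the time kernel (3 = tricube).
#' @param space_weight_region,space_weight_super_region Spatial borrowing
#'   weights in (0, 1).
#' @param national_data_share Share of a mixed country pool carried by
#'   nationally representative residuals (default 0.9).
#' @return List of class `bf_st_weights`.
#' @export
bf_st_weights <- function(time_bandwidth = 10,
                          time_exponent = 3,
                          space_weight_region = 0.5,
                          space_weight_super_region = 0.25,
                          national_data_share = 0.9) {
  stopifnot(time_bandwidth > 0,
            space_weight_region > 0, space_weight_region < 1,
            space_weight_super_region > 0, space_weight_super_region < 1,
            national_data_share > 0.5, national_data_share <= 1)
  structure(as.list(environment()), class = "bf_st_weights")
}

time_weight <- function(dt, w) {
  u <- abs(dt) / w$time_bandwidth
  ifelse(u < 1, (1 - u^w$time_exponent)^w$time_exponent, 0)
}

#' Stage 2: locally weighted spatio-temporal residual smoothing
#'
#' Predicts, for every target country-year, a residual from the stage-1
#' residuals of nearby observations. Within each source country the residuals
#' are first combined into a time-weighted mean (with the national /
#' subnational 90/10 renormalization when both kinds are present in the local
#' pool); the country pools are then combined with spatial weights that shrink
#' borrowed residuals toward zero:
#' `pred(c, t) = sum_j ws_cj * pi_j * rbar_j(t) / sum_j pi_j`, where `pi_j` is
#' country `j`'s time-weight mass and the sums run over countries with
#' positive spatial weight. A country-year whose pool is empty gets residual
#' zero; if there are no residuals at all, the surface is all zero with a
#' warning. The smoothed residual is added to the stage-1 prediction to give
#' the stage-2 (prior mean) surface.
#'
#' @param stage1 A [bf_fit_stage1()] object (its `residuals` must carry a
#'   `subnational` logical column; absent means all national).
#' @param geo Geography tibble (`country_id`, `region_id`, `super_region_id`).
#' @param weights A [bf_st_weights()] object.
#' @return Tibble `country_id`, `year`, `stage1_logit`, `st_residual`,
#'   `prior_logit`.
#' @export
bf_fit_stage2 <- function(stage1, geo, weights = bf_st_weights()) {
  res <- stage1$residuals
  if (!"subnational" %in% names(res)) res$subnational <- FALSE
  targets <- stage1$predictions
  if (nrow(res) == 0) {
    warn("no residuals available; stage-2 surface is zero")
    return(dplyr::mutate(targets, st_residual = 0,
                         prior_logit = .data$stage1_logit))
  }
  years <- sort(unique(targets$year))
  src <- unique(res$country_id)
  share <- weights$national_data_share

  # per source country: time-weight mass pi_j(t) and pooled residual
  # rbar_j(t) (with the national/subnational renormalization when both kinds
  # carry mass at t), vectorized over target years
  group_mean <- function(W, r) {
    # W: years x obs, r: obs; returns (mass, mean) with mean NaN at zero mass
    mass <- rowSums(W)
    list(mass = mass, mean = as.numeric(W %*% r) / mass)
  }
  pool <- lapply(src, function(j) {
    sub <- res[res$country_id == j, ]
    W <- time_weight(outer(years, sub$year, "-"), weights)
    all_g <- group_mean(W, sub$residual)
    nat <- !sub$subnational
    if (all(nat) || all(!nat)) {
      rbar <- all_g$mean
    } else {
      gn <- group_mean(W[, nat, drop = FALSE], sub$residual[nat])
      gs <- group_mean(W[, !nat, drop = FALSE], sub$residual[!nat])
      both <- gn$mass > 0 & gs$mass > 0
      rbar <- ifelse(both, share * gn$mean + (1 - share) * gs$mean,
                     ifelse(gn$mass > 0, gn$mean, gs$mean))
    }
    list(mass = all_g$mass, rbar = ifelse(all_g$mass > 0, rbar, 0))
  })
  mass <- do.call(cbind, lapply(pool, `[[`, "mass"))   # years x src
  rbar <- do.call(cbind, lapply(pool, `[[`, "rbar"))

  src_geo <- geo[match(src, geo$country_id), ]
  smooth_country <- function(cid) {
    crow <- geo[geo$country_id == cid, ]
    ws <- ifelse(src == cid, 1,
                 ifelse(src_geo$region_id == crow$region_id,
                        weights$space_weight_region,
                        ifelse(src_geo$super_region_id == crow$super_region_id,
                               weights$space_weight_super_region, 0)))
    in_scope <- ws > 0
    if (!any(in_scope)) return(stats::setNames(rep(0, length(years)), years))
    num <- as.numeric((mass[, in_scope, drop = FALSE] *
                         rbar[, in_scope, drop = FALSE]) %*% ws[in_scope])
    den <- rowSums(mass[, in_scope, drop = FALSE])
    stats::setNames(ifelse(den > 0, num / den, 0), years)
  }
  by_country <- lapply(unique(targets$country_id), smooth_country)
  names(by_country) <- unique(targets$country_id)
  targets$st_residual <- purrr::map2_dbl(
    targets$country_id, targets$year,
    function(c, y) by_country[[c]][[as.character(y)]]
  )
  dplyr::mutate(targets, prior_logit = .data$stage1_logit + .data$st_residual)
}

#' Gaussian process configuration for stage 3
#'
#' @param length_scale Matern-5/2 length scale in years (default 10).
#' @param amplitude Optional fixed kernel amplitude (logit-scale SD). By
#'   default the amplitude is estimated per region as 1.4826 times the median
#'   absolute deviation of the stage-2 residuals (observation minus prior
#'   mean) in that region, floored at `amplitude_floor`.
#' @param amplitude_floor Lower bound on the amplitude.
#' @param nsv_floor Non-sampling variance added to every observation's
#'   logit-scale sampling variance. Kept small relative to the kernel
#'   amplitude so the posterior places greater weight on existing data than on
#'   the prior mean.
#' @param nsv_subnational Extra non-sampling variance added to subnational
#'   (non-nationally-representative) observations, reflecting their
#'   systematic deviation from the national quantity.
#' @param n_draws Number of posterior draws (default 1000).
#' @param seed Root seed for the draws.
#' @return List of class `bf_gpr_config`.
#' @export
bf_gpr_config <- function(length_scale = 10, amplitude = NULL,
                          amplitude_floor = 0.05, nsv_floor = 0.01,
                          nsv_subnational = 0.1, n_draws = 1000L, seed = 1L) {
  stopifnot(length_scale > 0, amplitude_floor >= 0, nsv_floor >= 0,
            nsv_subnational >= 0, n_draws >= 2)
  structure(list(length_scale = length_scale, amplitude = amplitude,
                 amplitude_floor = amplitude_floor, nsv_floor = nsv_floor,
                 nsv_subnational = nsv_subnational,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "bf_gpr_config")
}

matern52 <- function(d, ell) {
  r <- sqrt(5) * abs(d) / ell
  (1 + r + r^2 / 3) * exp(-r)
}

chol_jitter <- function(S) {
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    out <- tryCatch(chol(S + diag(j, nrow(S))), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  abort("covariance not positive definite after jitter escalation",
        class = "bf_model_error")
}

# GP posterior for one country: prior mean m over grid years, observations
# (year, y, v). Returns list(mean, draws [years x n_draws]) on the logit scale.
gp_posterior_draws <- function(years, m, obs_year, obs_y, obs_v, amplitude,
                               config, seed) {
  K <- amplitude^2 * outer(years, years, function(a, b) {
    matern52(a - b, config$length_scale)
  })
  if (length(obs_year) == 0) {
    post_mean <- m
    post_cov <- K
  } else {
    Ko <- amplitude^2 * outer(obs_year, obs_year, function(a, b) {
      matern52(a - b, config$length_scale)
    }) + diag(obs_v + config$nsv_floor + 1e-12, length(obs_year))
    Kto <- amplitude^2 * outer(years, obs_year, function(a, b) {
      matern52(a - b, config$length_scale)
    })
    m_obs <- m[match(obs_year, years)]
    sol <- solve(Ko, cbind(obs_y - m_obs, t(Kto)))
    post_mean <- m + as.numeric(Kto %*% sol[, 1])
    post_cov <- K - Kto %*% sol[, -1, drop = FALSE]
    post_cov <- (post_cov + t(post_cov)) / 2
  }
  L <- chol_jitter(post_cov)
  z <- with_seed(seed, matrix(rnorm(length(years) * config$n_draws),
                              nrow = length(years)))
  draws <- post_mean + crossprod(L, z)
  list(mean = post_mean, draws = draws)
}

#' Stage 3: Gaussian process regression with posterior draws
#'
#' Fits, per country, a one-dimensional Gaussian process over years on the
#' logit scale with the stage-2 surface as mean function and a Matern-5/2
#' kernel, conditioned on the country's own observations with noise equal to
#' their logit-scale sampling variance plus a small non-sampling floor. The
#' posterior is sampled `n_draws` times; draws are transformed back to the
#' probability scale, and the mean and 95% interval are the draw mean and
#' 2.5th/97.5th draw quantiles. Countries without data get the prior mean and
#' prior kernel uncertainty, so the estimate grid is always complete.
#'
#' @param prior Stage-2 output tibble (`country_id`, `year`, `prior_logit`).
#' @param observations Observation tibble (`country_id`, `year`, `value`,
#'   `sample_size`, `variance`); may be empty.
#' @param geo Geography tibble (used to pool amplitude estimation by region).
#' @param config A [bf_gpr_config()].
#' @return List of class `bf_gpr_fit`: `cells` (tibble `country_id`, `year`),
#'   `draws` (matrix cells x n_draws, probability scale), `summary` (tibble
#'   with `mean`, `lower_95`, `upper_95`), `amplitudes` (per country).
#' @export
bf_fit_stage3 <- function(prior, observations, geo, config = bf_gpr_config()) {
  obs <- observations
  if (nrow(obs) > 0) {
    if (!"subnational" %in% names(obs)) obs$subnational <- FALSE
    obs <- obs |>
      dplyr::mutate(
        logit_value = logit(clamp_proportion(.data$value, .data$sample_size)),
        variance = .data$variance +
          ifelse(.data$subnational, config$nsv_subnational, 0)
      ) |>
      dplyr::left_join(prior, by = c("country_id", "year")) |>
      dplyr::mutate(resid2 = .data$logit_value - .data$prior_logit) |>
      dplyr::left_join(geo[c("country_id", "region_id")], by = "country_id")
    if (any(obs$variance <= 0)) {
      abort("observation variances must be > 0", class = "bf_model_error")
    }
  }

  # kernel amplitude: regional MAD of stage-2 residuals, global fallback
  if (!is.null(config$amplitude)) {
    amp_by_country <- stats::setNames(rep(config$amplitude, nrow(geo)),
                                      geo$country_id)
  } else {
    global_mad <- if (nrow(obs) > 0) mad(obs$resid2, constant = 1.4826) else 0
    reg <- if (nrow(obs) > 0) {
      obs |>
        dplyr::group_by(.data$region_id) |>
        dplyr::summarise(amp = mad(.data$resid2, constant = 1.4826),
                         n = dplyr::n(), .groups = "drop")
    } else tibble::tibble(region_id = character(), amp = numeric(), n = integer())
    amp_tbl <- geo |>
      dplyr::left_join(reg, by = "region_id") |>
      dplyr::mutate(amp = dplyr::if_else(is.na(.data$amp) | .data$n < 3 |
                                           .data$amp == 0,
                                         global_mad, .data$amp, global_mad),
                    amp = pmax(.data$amp, config$amplitude_floor))
    amp_by_country <- stats::setNames(amp_tbl$amp, amp_tbl$country_id)
  }

  years <- sort(unique(prior$year))
  countries <- unique(prior$country_id)
  cells <- tidyr::expand_grid(country_id = countries, year = years)
  draws <- matrix(NA_real_, nrow(cells), config$n_draws)
  prior_wide <- prior |> dplyr::arrange(.data$country_id, .data$year)

  for (cid in countries) {
    m <- prior_wide$prior_logit[prior_wide$country_id == cid]
    co <- if (nrow(obs) > 0) obs[obs$country_id == cid, ] else obs
    gp <- gp_posterior_draws(
      years, m,
      obs_year = if (nrow(co)) co$year else numeric(0),
      obs_y = if (nrow(co)) co$logit_value else numeric(0),
      obs_v = if (nrow(co)) co$variance else numeric(0),
      amplitude = amp_by_country[[cid]],
      config = config,
      seed = substream_seed(config$seed, paste0("gpr_", cid))
    )
    draws[cells$country_id == cid, ] <- expit(as.matrix(gp$draws))
  }

  summ <- tibble::tibble(
    cells,
    mean = rowMeans(draws),
    lower_95 = apply(draws, 1, quantile, 0.025, names = FALSE),
    upper_95 = apply(draws, 1, quantile, 0.975, names = FALSE)
  )
  structure(list(cells = cells, draws = draws, summary = summ,
                 amplitudes = amp_by_country),
            class = "bf_gpr_fit")
}

#' Enforce the 0-5 month feeding composition on posterior draws
#'
#' Takes aligned draws of the three nested cumulative quantities - exclusive,
#' exclusive-or-predominant, and any breastfeeding - on the probability scale
#' and returns coherent category shares. Any draw where the nesting order is
#' violated (the cumulatives are modelled marginally) is repaired by sorting
#' the three values, after which the categories are obtained by differencing:
#' exclusive, predominant, partial, and none (= 1 - any). By construction all
#' four shares are non-negative and sum to exactly 1 in every draw.
#'
#' @param cum_exclusive,cum_excl_pred,cum_any Numeric vectors or matrices of
#'   identical shape (cells x draws), values in `[0, 1]`.
#' @return List with elements `exclusive_0_5`, `predominant_0_5`,
#'   `partial_0_5`, `none_0_5`, same shape as the inputs.
#' @export
bf_enforce_composition <- function(cum_exclusive, cum_excl_pred, cum_any) {
  stopifnot(length(cum_exclusive) == length(cum_excl_pred),
            length(cum_excl_pred) == length(cum_any))
  c1 <- pmin(cum_exclusive, cum_excl_pred, cum_any)
  c3 <- pmax(cum_exclusive, cum_excl_pred, cum_any)
  c2 <- cum_exclusive + cum_excl_pred + cum_any - c1 - c3
  list(
    exclusive_0_5 = c1,
    predominant_0_5 = c2 - c1,
    partial_0_5 = c3 - c2,
    none_0_5 = 1 - c3
  )
}

#' Pipeline configuration
#'
#' @param st_weights A [bf_st_weights()] object.
#' @param gpr A [bf_gpr_config()] object; its `seed` is overwritten by `seed`.
#' @param harmonize Run the definition-correction step first (default TRUE).
#' @param seed Root seed for all pipeline randomness.
#' @return List of class `bf_pipeline_config`.
#' @export
bf_pipeline_config <- function(st_weights = bf_st_weights(),
                               gpr = bf_gpr_config(),
                               harmonize = TRUE,
                               seed = 1L) {
  gpr$seed <- as.integer(seed)
  structure(list(st_weights = st_weights, gpr = gpr, harmonize = harmonize,
                 seed = as.integer(seed)),
            class = "bf_pipeline_config")
}

# Build the six modelling-target observation tables from harmonized
# per-indicator observations. The 0-5 month trio is pivoted per survey onto
# the nested cumulative scale.
build_target_observations <- function(obs) {
  trio <- c("exclusive_0_5", "predominant_0_5", "partial_0_5")
  singles <- list(initiation_24h = "initiation_24h",
                  continued_6_11 = "continued_6_11",
                  continued_12_23 = "continued_12_23")
  out <- purrr::imap(singles, function(ind, nm) {
    dplyr::filter(obs, .data$indicator == ind)
  })
  wide <- obs |>
    dplyr::filter(.data$indicator %in% trio) |>
    tidyr::pivot_wider(
      id_cols = c("survey_id", "country_id", "year", "sample_size",
                  "subnational"),
      names_from = "indicator",
      values_from = c("value", "variance_inflation"),
      values_fill = list(variance_inflation = 0)
    )
  need <- paste0("value_", trio)
  if (nrow(wide) > 0 && all(need %in% names(wide))) {
    wide <- wide[complete.cases(wide[need]), ]
    infl <- rowMeans(wide[paste0("variance_inflation_", trio)])
    cum <- list(
      cum_exclusive = wide$value_exclusive_0_5,
      cum_excl_pred = wide$value_exclusive_0_5 + wide$value_predominant_0_5,
      cum_any_0_5 = wide$value_exclusive_0_5 + wide$value_predominant_0_5 +
        wide$value_partial_0_5
    )
    for (nm in names(cum)) {
      v <- clamp_proportion(cum[[nm]], wide$sample_size)
      out[[nm]] <- tibble::tibble(
        survey_id = wide$survey_id,
        country_id = wide$country_id,
        year = wide$year,
        indicator = nm,
        value = v,
        sample_size = wide$sample_size,
        subnational = wide$subnational,
        variance = logit_sampling_variance(v, wide$sample_size) + infl
      )
    }
  } else {
    for (nm in c("cum_exclusive", "cum_excl_pred", "cum_any_0_5")) {
      out[[nm]] <- tibble::tibble()
    }
  }
  out[bf_model_targets()]
}

#' Run the full three-stage prevalence pipeline
#'
#' Harmonizes the observations, then for each of six modelling targets (the
#' initiation and continued indicators, and the three nested cumulative
#' quantities of the 0-5 month composition) fits the covariate regression,
#' the spatio-temporal residual smoother, and the Gaussian process posterior
#' with draws; finally differences the cumulative draws into coherent
#' exclusive / predominant / partial / none shares. Produces a complete
#' country x year x indicator estimate grid with no missing cells.
#'
#' @param observations Survey observation tibble (see [bf_sim_surveys()]).
#' @param covariates Country-year covariate tibble covering every country-year
#'   to be estimated.
#' @param geo Geography tibble.
#' @param config A [bf_pipeline_config()].
#' @return Object of class `bf_prevalence_fit`: `estimates` (tibble
#'   `country_id`, `year`, `indicator`, `mean`, `lower_95`, `upper_95`),
#'   `cells`, `draws` (named list of cells x n_draws matrices per indicator,
#'   plus `none_0_5`), `stage1` and `stage2` per-target artifacts,
#'   `correction_models`, `config`.
#' @export
bf_estimate_prevalence <- function(observations, covariates, geo,
                                   config = bf_pipeline_config()) {
  obs <- observations
  corr_models <- NULL
  if (isTRUE(config$harmonize)) {
    obs <- bf_harmonize(obs)
    corr_models <- attr(obs, "correction_models")
  } else {
    if (!"variance_inflation" %in% names(obs)) obs$variance_inflation <- 0
  }
  targets <- build_target_observations(obs)

  stage1 <- list(); stage2 <- list(); gpr <- list()
  for (nm in names(targets)) {
    tob <- targets[[nm]]
    if (nrow(tob) < 10) {
      abort(sprintf("stage 1 (%s): fewer than 10 observations", nm),
            class = "bf_model_error")
    }
    s1 <- tryCatch(bf_fit_stage1(tob, covariates),
                   error = function(e) abort(sprintf("stage 1 (%s): %s", nm,
                                                     conditionMessage(e)),
                                             class = "bf_model_error"))
    s2 <- bf_fit_stage2(s1, geo, config$st_weights)
    gcfg <- config$gpr
    gcfg$seed <- substream_seed(config$seed, paste0("target_", nm))
    s3 <- bf_fit_stage3(s2, tob, geo, gcfg)
    stage1[[nm]] <- s1; stage2[[nm]] <- s2; gpr[[nm]] <- s3
  }

  cells <- gpr[[1]]$cells
  comp <- bf_enforce_composition(gpr$cum_exclusive$draws,
                                 gpr$cum_excl_pred$draws,
                                 gpr$cum_any_0_5$draws)
  draws <- list(
    initiation_24h = gpr$initiation_24h$draws,
    exclusive_0_5 = comp$exclusive_0_5,
    predominant_0_5 = comp$predominant_0_5,
    partial_0_5 = comp$partial_0_5,
    none_0_5 = comp$none_0_5,
    continued_6_11 = gpr$continued_6_11$draws,
    continued_12_23 = gpr$continued_12_23$draws
  )
  estimates <- purrr::imap_dfr(draws[bf_indicators()], function(d, nm) {
    tibble::tibble(
      cells,
      indicator = nm,
      mean = rowMeans(d),
      lower_95 = apply(d, 1, quantile, 0.025, names = FALSE),
      upper_95 = apply(d, 1, quantile, 0.975, names = FALSE)
    )
  }) |>
    dplyr::arrange(.data$country_id, .data$year, .data$indicator)

  structure(list(
    estimates = estimates,
    cells = cells,
    draws = draws,
    stage1 = stage1,
    stage2 = stage2,
    correction_models = corr_models,
    config = config
  ), class = "bf_prevalence_fit")
}

#' @export
print.bf_prevalence_fit <- function(x, ...) {
  cat(sprintf("Breastfeeding prevalence estimates: %d countries x %d years x %d indicators\n",
              dplyr::n_distinct(x$cells$country_id),
              dplyr::n_distinct(x$cells$year),
              length(bf_indicators())))
  cat(sprintf("  %d posterior draws per cell\n", ncol(x$draws[[1]])))
  invisible(x)
}

#' Write pipeline estimates and draws to CSV
#'
#' @param fit A [bf_estimate_prevalence()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
bf_write_estimates <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$estimates, file.path(dir, "estimates.csv"))
  for (nm in bf_indicators()) {
    d <- as.data.frame(fit$draws[[nm]])
    names(d) <- sprintf("draw_%d", seq_len(ncol(d)) - 1)
    readr::write_csv(dplyr::bind_cols(fit$cells, d),
                     file.path(dir, sprintf("draws_%s.csv", nm)))
  }
  invisible(dir)
}
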
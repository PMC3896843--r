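#' Configuration for the synthetic survey world
#'
#' Builds the configuration object consumed by [bf_sim_world()] and
#' [bf_sim_surveys()]. The defaults define a small, fully known world of
#' 3 super-regions x 2 regions x 4 countries (24 countries) observed 1990-2010,
#' with a survey data mix emulating the multi-source survey landscape the
#' estimation model is designed for: mostly national, standard-definition
#' surveys, plus subnational surveys with a systematic logit-scale bias and
#' non-standard-definition surveys with a systematic logit-scale distortion.
#'
#' A `paper_scale = TRUE` preset enlarges the world to 137 countries; it is not
#' used by the test suite.
#'
#' @param n_super_regions,n_regions_per,n_countries_per Hierarchy sizes.
#' @param years Integer vector of calendar years (inclusive grid).
#' @param surveys_per_country Mean number of survey events per country
#'   (Poisson).
#' @param survey_sample_size Children sampled per survey per indicator.
#' @param subnational_fraction Probability a survey is subnational (not
#'   nationally representative).
#' @param nonstandard_fraction Probability a survey reports non-standard
#'   indicator definitions.
#' @param crosswalk_overlap Fraction of non-standard surveys that also report a
#'   standard-definition re-analysis of the same microdata at the same
#'   country-year; these pairs are what makes the correction factors estimable.
#' @param subnational_bias_logit Additive logit-scale bias of subnational
#'   observations.
#' @param nonstandard_distortion_logit Additive logit-scale distortion of
#'   non-standard observations.
#' @param covariate_loadings Named numeric vector: logit-scale regression
#'   coefficient of each covariate in every trajectory's linear predictor.
#'   Names must be a subset of [bf_covariate_names()].
#' @param seed Root seed; all randomness flows from it via named substreams.
#' @param paper_scale If `TRUE`, use a 137-country hierarchy.
#' @return A list of class `bf_sim_config`.
#' @export
bf_sim_config <- function(n_super_regions = 3L,
                          n_regions_per = 2L,
                          n_countries_per = 4L,
                          years = 1990:2010,
                          surveys_per_country = 5,
                          survey_sample_size = 1000L,
                          subnational_fraction = 0.2,
                          nonstandard_fraction = 0.2,
                          crosswalk_overlap = 0.5,
                          subnational_bias_logit = 0.3,
                          nonstandard_distortion_logit = -0.4,
                          covariate_loadings = NULL,
                          seed = 1L,
                          paper_scale = FALSE) {
  if (paper_scale) {
    n_super_regions <- 7L
    n_regions_per <- 3L
    # 7 x 3 x 7 = 147 ~ paper scale; trimmed to 137 in bf_sim_world()
    n_countries_per <- 7L
  }
  fracs <- c(subnational_fraction, nonstandard_fraction, crosswalk_overlap)
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractions must lie in [0, 1]", class = "bf_config_error")
  }
  if (survey_sample_size < 1) {
    abort("survey_sample_size must be >= 1", class = "bf_config_error")
  }
  if (length(years) < 2 || any(diff(years) != 1)) {
    abort("years must be a consecutive inclusive range", class = "bf_config_error")
  }
  if (any(c(n_super_regions, n_regions_per, n_countries_per) < 1)) {
    abort("hierarchy counts must be >= 1", class = "bf_config_error")
  }
  default_loadings <- c(
    maternal_education = 0.10,
    log_gdp_pc = -0.20,
    child_underweight = -1.50,
    tfr = -0.10
  )
  if (!is.null(covariate_loadings)) {
    bad <- setdiff(names(covariate_loadings), bf_covariate_names())
    if (length(bad) > 0) {
      abort(paste0("unknown covariates in loadings: ", paste(bad, collapse = ", ")),
            class = "bf_config_error")
    }
    default_loadings[names(covariate_loadings)] <- covariate_loadings
  }
  structure(list(
    n_super_regions = as.integer(n_super_regions),
    n_regions_per = as.integer(n_regions_per),
    n_countries_per = as.integer(n_countries_per),
    n_countries_cap = if (paper_scale) 137L else NA_integer_,
    years = as.integer(years),
    surveys_per_country = surveys_per_country,
    survey_sample_size = as.integer(survey_sample_size),
    subnational_fraction = subnational_fraction,
    nonstandard_fraction = nonstandard_fraction,
    crosswalk_overlap = crosswalk_overlap,
    subnational_bias_logit = subnational_bias_logit,
    nonstandard_distortion_logit = nonstandard_distortion_logit,
    covariate_loadings = default_loadings,
    seed = as.integer(seed)
  ), class = "bf_sim_config")
}

# Nested random effects: one draw per super-region, region, country, summed to
# the country level. Returns a vector over countries.
nested_effect <- function(geo, sd_sr, sd_r, sd_c) {
  sr <- rnorm(length(unique(geo$super_region_id)), 0, sd_sr)
  names(sr) <- unique(geo$super_region_id)
  rg <- rnorm(length(unique(geo$region_id)), 0, sd_r)
  names(rg) <- unique(geo$region_id)
  cc <- rnorm(nrow(geo), 0, sd_c)
  sr[geo$super_region_id] + rg[geo$region_id] + cc
}

# Trajectory parameters for the six modelling targets. Intercepts are logit
# prevalences at year 2000 in a regime mirroring the global breastfeeding mix
# (any bf ~ 0.88, exclusive ~ 0.34 of all, initiation ~ 0.37, continued high at
# 6-11 months and lower at 12-23 months); slopes are slow secular trends.
target_trajectory_params <- function() {
  tibble::tribble(
    ~target,            ~mu,    ~gamma,
    "initiation_24h",   -0.55,   0.000,
    "cum_any_0_5",       2.00,   0.005,
    "ratio_excl_pred",   0.36,   0.000,  # logit of C2 / C3
    "ratio_exclusive",   0.66,   0.010,  # logit of C1 / C2
    "continued_6_11",    1.05,  -0.005,
    "continued_12_23",  -0.20,   0.020
  )
}

#' Generate a synthetic world with known ground truth
#'
#' Creates the geographic hierarchy, true logit-scale prevalence trajectories
#' for all six indicators, and the country-year covariate table. Trajectories
#' are logit-linear in time with country intercept/slope random effects nested
#' in region and super-region, so residual spatial correlation is real; the
#' covariates enter every trajectory's linear predictor with the configured
#' loadings, so a stage-1 covariate regression has real but partial explanatory
#' power. The 0-5 month composition is generated on the nested cumulative scale
#' (exclusive) <= (exclusive or predominant) <= (any breastfeeding), so
#' exclusive + predominant + partial + none = 1 exactly for every country-year.
#'
#' @param config A [bf_sim_config()] object.
#' @return A list of class `bf_world` with elements `geo` (country hierarchy
#'   plus annual births), `trajectories` (country x year x indicator true
#'   prevalence), `covariates` (country-year covariate table), `truth_logit`
#'   (true logit values of the internal modelling targets) and `config`.
#' @export
bf_sim_world <- function(config = bf_sim_config()) {
  stopifnot(inherits(config, "bf_sim_config"))
  seed <- substream_seed(config$seed, "world")
  with_seed(seed, {
    geo <- tidyr::expand_grid(
      sr = seq_len(config$n_super_regions),
      rg = seq_len(config$n_regions_per),
      cc = seq_len(config$n_countries_per)
    ) |>
      dplyr::mutate(
        super_region_id = sprintf("SR%d", .data$sr),
        region_id = sprintf("SR%d_R%d", .data$sr, .data$rg),
        country_id = sprintf("SR%d_R%d_C%02d", .data$sr, .data$rg, .data$cc)
      ) |>
      dplyr::select("country_id", "region_id", "super_region_id")
    if (!is.na(config$n_countries_cap)) {
      geo <- head(geo, config$n_countries_cap)
    }
    geo$births <- round(rlnorm(nrow(geo), meanlog = log(1e5), sdlog = 0.7))

    years <- config$years
    t0 <- (years - 2000)

    # --- covariates: exogenous smooth country trajectories -------------------
    cov_spec <- tibble::tribble(
      ~covariate,           ~mean, ~sd_sr, ~sd_r, ~sd_c, ~trend, ~slope_sd, ~lo,   ~hi,
      "maternal_education",  6.0,   0.5,    0.4,   1.6,   0.08,   0.030,     0.5,   15,
      "log_gdp_pc",          7.5,   0.25,   0.2,   0.7,   0.02,   0.010,     4,     11,
      "child_underweight",   0.22,  0.02,   0.02,  0.075, -0.003, 0.0015,    0.01,  0.6,
      "tfr",                 4.5,   0.35,   0.3,   1.1,  -0.05,   0.020,     1.0,   9
    )
    cov_long <- purrr::pmap_dfr(cov_spec, function(covariate, mean, sd_sr, sd_r,
                                                   sd_c, trend, slope_sd, lo, hi) {
      icpt <- mean + nested_effect(geo, sd_sr, sd_r, sd_c)
      slope <- trend + rnorm(nrow(geo), 0, slope_sd)
      tidyr::expand_grid(ci = seq_len(nrow(geo)), year = years) |>
        dplyr::mutate(
          country_id = geo$country_id[.data$ci],
          covariate = covariate,
          value = pmin(pmax(icpt[.data$ci] + slope[.data$ci] * (.data$year - 2000),
                            lo), hi)
        ) |>
        dplyr::select("country_id", "year", "covariate", "value")
    })
    covariates <- tidyr::pivot_wider(cov_long, names_from = "covariate",
                                     values_from = "value")

    # centered covariate contribution shared by all trajectories
    loadings <- config$covariate_loadings
    cov_mat <- as.matrix(covariates[bf_covariate_names()])
    cov_center <- c(maternal_education = 6, log_gdp_pc = 7.5,
                    child_underweight = 0.22, tfr = 4.5)
    xb <- as.numeric(sweep(cov_mat, 2, cov_center[colnames(cov_mat)]) %*%
                       loadings[colnames(cov_mat)])
    xb_tbl <- dplyr::mutate(covariates[c("country_id", "year")], xb = xb)

    # --- trajectories: logit-linear with nested random lines -----------------
    params <- target_trajectory_params()
    truth <- purrr::pmap_dfr(params, function(target, mu, gamma) {
      icpt <- mu + nested_effect(geo, sd_sr = 0.03, sd_r = 0.05, sd_c = 0.18)
      slope <- gamma + nested_effect(geo, sd_sr = 0.0015, sd_r = 0.002, sd_c = 0.007)
      tidyr::expand_grid(ci = seq_len(nrow(geo)), year = years) |>
        dplyr::mutate(
          country_id = geo$country_id[.data$ci],
          target = target,
          eta0 = icpt[.data$ci] + slope[.data$ci] * (.data$year - 2000)
        ) |>
        dplyr::select("country_id", "year", "target", "eta0")
    }) |>
      dplyr::left_join(xb_tbl, by = c("country_id", "year")) |>
      dplyr::mutate(logit_value = .data$eta0 + .data$xb) |>
      dplyr::select("country_id", "year", "target", "logit_value")

    wide <- tidyr::pivot_wider(truth, names_from = "target",
                               values_from = "logit_value") |>
      dplyr::mutate(
        c3 = expit(.data$cum_any_0_5),
        c2 = .data$c3 * expit(.data$ratio_excl_pred),
        c1 = .data$c2 * expit(.data$ratio_exclusive)
      )

    truth_logit <- wide |>
      dplyr::transmute(
        .data$country_id, .data$year,
        initiation_24h = .data$initiation_24h,
        cum_exclusive = logit(.data$c1),
        cum_excl_pred = logit(.data$c2),
        cum_any_0_5 = logit(.data$c3),
        continued_6_11 = .data$continued_6_11,
        continued_12_23 = .data$continued_12_23
      )

    trajectories <- wide |>
      dplyr::transmute(
        .data$country_id, .data$year,
        initiation_24h = expit(.data$initiation_24h),
        exclusive_0_5 = .data$c1,
        predominant_0_5 = .data$c2 - .data$c1,
        partial_0_5 = .data$c3 - .data$c2,
        continued_6_11 = expit(.data$continued_6_11),
        continued_12_23 = expit(.data$continued_12_23)
      ) |>
      tidyr::pivot_longer(-c("country_id", "year"), names_to = "indicator",
                          values_to = "true_prevalence")

    structure(list(
      geo = geo,
      trajectories = trajectories,
      covariates = covariates,
      truth_logit = truth_logit,
      config = config
    ), class = "bf_world")
  })
}

# Survey-level reported category probabilities for the 0-5 month trio after
# optional subnational bias (applied on the cumulative scale, preserving the
# nesting order) and non-standard distortion (applied per category, matching
# the additive-logit correction model the harmonizer assumes).
distort_trio <- function(c1, c2, c3, bias, distortion) {
  if (bias != 0) {
    c1 <- expit(logit(c1) + bias)
    c2 <- expit(logit(c2) + bias)
    c3 <- expit(logit(c3) + bias)
  }
  p <- c(exclusive_0_5 = c1, predominant_0_5 = c2 - c1, partial_0_5 = c3 - c2)
  if (distortion != 0) {
    p <- expit(logit(pmax(p, 1e-9)) + distortion)
    if (sum(p) > 0.995) p <- p * 0.995 / sum(p)
  }
  p
}

#' Simulate survey observations from a synthetic world
#'
#' Each survey event draws, at its country-year, a joint multinomial sample of
#' the 0-5 month feeding categories and binomial samples of the other
#' indicators, at the configured sample size. Subnational surveys carry an
#' additive logit-scale bias; non-standard-definition surveys an additive
#' logit-scale distortion per indicator (the quantity the harmonization module
#' estimates and removes). A configurable fraction of non-standard surveys also
#' report a standard re-analysis at the same country-year, providing the
#' definition pairs correction factors are estimated from.
#'
#' @param world A [bf_sim_world()] object.
#' @param config A [bf_sim_config()]; defaults to the world's own.
#' @return Tibble with one row per (survey, definition, indicator): columns
#'   `survey_id`, `country_id`, `year`, `indicator`, `value`, `sample_size`,
#'   `subnational`, `nonstandard`, `variance` (logit-scale sampling variance).
#' @export
bf_sim_surveys <- function(world, config = world$config) {
  stopifnot(inherits(world, "bf_world"))
  seed <- substream_seed(config$seed, "surveys")
  truth <- world$truth_logit
  with_seed(seed, {
    events <- purrr::map_dfr(world$geo$country_id, function(cid) {
      n_sv <- rpois(1, config$surveys_per_country)
      if (n_sv == 0) return(tibble::tibble())
      tibble::tibble(
        country_id = cid,
        year = sample(config$years, n_sv, replace = TRUE),
        subnational = runif(n_sv) < config$subnational_fraction,
        nonstandard = runif(n_sv) < config$nonstandard_fraction
      )
    })
    if (nrow(events) == 0) {
      warn("no survey events drawn; increase surveys_per_country")
      return(tibble::tibble())
    }
    events$survey_id <- sprintf("SV%04d", seq_len(nrow(events)))
    events$paired_standard <- events$nonstandard &
      runif(nrow(events)) < config$crosswalk_overlap

    n <- config$survey_sample_size
    rows <- purrr::pmap_dfr(events, function(country_id, year, subnational,
                                             nonstandard, survey_id,
                                             paired_standard) {
      tr <- truth[truth$country_id == country_id & truth$year == year, ]
      bias <- if (subnational) config$subnational_bias_logit else 0
      draw_one <- function(distortion, suffix) {
        trio <- distort_trio(expit(tr$cum_exclusive), expit(tr$cum_excl_pred),
                             expit(tr$cum_any_0_5), bias, distortion)
        counts <- as.numeric(stats::rmultinom(1, n, c(trio, none = 1 - sum(trio))))
        singles <- vapply(c("initiation_24h", "continued_6_11", "continued_12_23"),
                          function(ind) {
                            p <- expit(tr[[ind]] + bias + distortion)
                            rbinom(1, n, p) / n
                          }, numeric(1))
        tibble::tibble(
          survey_id = paste0(survey_id, suffix),
          country_id = country_id, year = year,
          indicator = c(names(trio), names(singles)),
          value = c(counts[1:3] / n, singles),
          sample_size = n,
          subnational = subnational,
          nonstandard = distortion != 0
        )
      }
      out <- draw_one(if (nonstandard) config$nonstandard_distortion_logit else 0, "")
      if (paired_standard) out <- dplyr::bind_rows(out, draw_one(0, "s"))
      out
    })
    rows$variance <- logit_sampling_variance(rows$value, rows$sample_size)
    dplyr::arrange(rows, .data$country_id, .data$year, .data$survey_id,
                   .data$indicator)
  })
}

#' Simulate household asset ownership from latent permanent income
#'
#' Latent income is standard normal per household; asset `k` is owned with
#' probability `pnorm(d_k * (income - c_k))`, a probit with positive
#' discrimination `d_k` and cutpoint `c_k`. True income and true quintile are
#' recorded so the wealth model can be validated against ground truth.
#'
#' @param n_households Number of households.
#' @param n_assets Number of assets (>= 3; income is not identifiable below).
#' @param seed Seed.
#' @param discriminations Optional vector of true discriminations; default
#'   drawn uniform on (0.5, 1.5).
#' @param cutpoints Optional vector of true cutpoints; default spreads target
#'   ownership rates over (0.08, 0.92).
#' @return Tibble `household_id`, `true_income`, `true_quintile`,
#'   `asset_1 ... asset_K`; attribute `asset_truth` holds the generating
#'   parameters.
#' @export
bf_sim_households <- function(n_households = 2000L, n_assets = 12L, seed = 1L,
                              discriminations = NULL, cutpoints = NULL) {
  if (n_assets < 3) {
    abort("n_assets must be >= 3 (income not identifiable)",
          class = "bf_config_error")
  }
  with_seed(substream_seed(seed, "households"), {
    d <- discriminations %||% runif(n_assets, 0.5, 1.5)
    cp <- cutpoints %||% qnorm(1 - seq(0.08, 0.92, length.out = n_assets))
    stopifnot(length(d) == n_assets, length(cp) == n_assets)
    y <- rnorm(n_households)
    own <- vapply(seq_len(n_assets), function(k) {
      as.integer(runif(n_households) < pnorm(d[k] * (y - cp[k])))
    }, integer(n_households))
    colnames(own) <- sprintf("asset_%d", seq_len(n_assets))
    const <- apply(own, 2, function(a) length(unique(a)) == 1)
    if (any(const)) {
      warn(paste0("constant asset columns (never/always owned): ",
                  paste(colnames(own)[const], collapse = ", ")))
    }
    out <- tibble::tibble(
      household_id = sprintf("H%05d", seq_len(n_households)),
      true_income = y,
      true_quintile = as.integer(ceiling(5 * rank(y, ties.method = "first") /
                                           n_households))
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(own))
    attr(out, "asset_truth") <- tibble::tibble(
      asset_id = colnames(own), discrimination = d, cutpoint = cp,
      ownership_rate = colMeans(own)
    )
    out
  })
}

#' Simulate background disease-burden envelopes
#'
#' Stand-in cause-specific envelopes: deaths and DALYs for diarrhea and
#' pneumonia by country-year and age band, proportional to the country's
#' annual births with slowly declining cause-specific death rates. DALYs are
#' `deaths * yll_per_death` plus a small morbidity component, so
#' `DALYs >= deaths * yll_per_death` always holds.
#'
#' @param world A [bf_sim_world()] object.
#' @param yll_per_death Years of life lost per child death (default 80).
#' @param seed Seed; defaults to the world's root seed.
#' @return Tibble `country_id`, `year`, `cause`, `age_group`, `metric`,
#'   `value`.
#' @export
bf_sim_burden_background <- function(world, yll_per_death = 80,
                                     seed = world$config$seed) {
  stopifnot(inherits(world, "bf_world"))
  with_seed(substream_seed(seed, "burden"), {
    base_rate <- tibble::tribble(
      ~cause,      ~age_group, ~rate0,
      "diarrhea",  "0-5mo",     0.006,
      "diarrhea",  "6-23mo",    0.010,
      "pneumonia", "0-5mo",     0.008,
      "pneumonia", "6-23mo",    0.009
    )
    cells <- tidyr::expand_grid(
      world$geo[c("country_id", "births")],
      year = world$config$years,
      base_rate
    )
    country_mult <- stats::setNames(rlnorm(nrow(world$geo), 0, 0.4),
                                    world$geo$country_id)
    cells <- cells |>
      dplyr::mutate(
        decline = exp(-0.02 * (.data$year - min(.data$year))),
        deaths = .data$births * .data$rate0 * .data$decline *
          country_mult[.data$country_id],
        dalys = .data$deaths * yll_per_death + .data$deaths * 2.5
      ) |>
      dplyr::select("country_id", "year", "cause", "age_group",
                    deaths = "deaths", DALYs = "dalys") |>
      tidyr::pivot_longer(c("deaths", "DALYs"), names_to = "metric",
                          values_to = "value")
    cells
  })
}

#' Simulate child breastfeeding records by wealth quintile
#'
#' Generates child-level records for the inequality analysis: for each survey
#' year and quintile, `n_per_cell` children with a binary breastfeeding status
#' drawn at the quintile-year prevalence
#' `base_prev + gradient * (quintile - 3) + slope_q * (year - min(year))`,
#' where `slope_q` is `trend_per_year` for quintiles in `trend_quintiles` and 0
#' otherwise. Prevalences are clamped to (0.01, 0.99).
#'
#' @param years Survey years.
#' @param n_per_cell Children per quintile-year cell.
#' @param base_prev Prevalence at quintile 3 in the first year.
#' @param gradient Additive prevalence step per quintile.
#' @param trend_per_year Prevalence change per year in the trending quintiles.
#' @param trend_quintiles Quintiles that carry the trend (default all).
#' @param seed Seed.
#' @return Tibble `child_id`, `year`, `quintile`, `bf_status` (0/1).
#' @export
bf_sim_quintile_records <- function(years = c(1995, 2000, 2005, 2010),
                                    n_per_cell = 600L,
                                    base_prev = 0.30,
                                    gradient = 0,
                                    trend_per_year = 0,
                                    trend_quintiles = 1:5,
                                    seed = 1L) {
  with_seed(substream_seed(seed, "quintile_records"), {
    grid <- tidyr::expand_grid(year = years, quintile = 1:5)
    rows <- purrr::pmap_dfr(grid, function(year, quintile) {
      slope <- if (quintile %in% trend_quintiles) trend_per_year else 0
      p <- base_prev + gradient * (quintile - 3) + slope * (year - min(years))
      p <- min(max(p, 0.01), 0.99)
      tibble::tibble(
        year = year, quintile = quintile,
        bf_status = rbinom(n_per_cell, 1, p)
      )
    })
    rows$child_id <- sprintf("K%06d", seq_len(nrow(rows)))
    dplyr::select(rows, "child_id", "year", "quintile", "bf_status")
  })
}

#' Link simulated children to simulated households
#'
#' Draws `n_children` children uniformly over households and assigns a binary
#' breastfeeding status at a prevalence given per true household quintile,
#' producing linked records for the household-based inequality pathway.
#'
#' @param households Output of [bf_sim_households()].
#' @param n_children Number of children.
#' @param prev_by_quintile Numeric length-5 vector of prevalences by true
#'   quintile.
#' @param year Survey year stamped on the records.
#' @param seed Seed.
#' @return Tibble `child_id`, `household_id`, `year`, `bf_status`.
#' @export
bf_sim_children <- function(households, n_children = 3000L,
                            prev_by_quintile = rep(0.3, 5),
                            year = 2010L, seed = 1L) {
  stopifnot(length(prev_by_quintile) == 5)
  with_seed(substream_seed(seed, "children"), {
    idx <- sample(nrow(households), n_children, replace = TRUE)
    q <- households$true_quintile[idx]
    tibble::tibble(
      child_id = sprintf("K%06d", seq_len(n_children)),
      household_id = households$household_id[idx],
      year = year,
      bf_status = rbinom(n_children, 1, prev_by_quintile[q])
    )
  })
}

#' Write the synthetic world to plain CSV files
#'
#' Writes `world.csv` (true trajectories), `covariates.csv`, `geo.csv`,
#' `surveys.csv`, `households.csv` and `burden_background.csv` into `dir`.
#'
#' @param world A [bf_sim_world()] object.
#' @param dir Output directory (created if missing).
#' @param surveys,households,burden Optional pre-simulated tables; simulated
#'   from the world's config when `NULL`.
#' @return `dir`, invisibly.
#' @export
bf_write_world <- function(world, dir, surveys = NULL, households = NULL,
                           burden = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(world$trajectories, file.path(dir, "world.csv"))
  readr::write_csv(world$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(world$geo, file.path(dir, "geo.csv"))
  readr::write_csv(surveys %||% bf_sim_surveys(world),
                   file.path(dir, "surveys.csv"))
  readr::write_csv(households %||% bf_sim_households(seed = world$config$seed),
                   file.path(dir, "households.csv"))
  readr::write_csv(burden %||% bf_sim_burden_background(world),
                   file.path(dir, "burden_background.csv"))
  invisible(dir)
}
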
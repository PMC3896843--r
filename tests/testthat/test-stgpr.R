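toy_geo <- function() {
  tibble::tibble(
    country_id = c("A1", "A2", "B1", "B2"),
    region_id = c("RA", "RA", "RB", "RB"),
    super_region_id = c("S", "S", "S", "S")
  )
}

toy_covariates <- function(countries, years = 1995:2005, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(country_id = countries, year = years) |>
    dplyr::mutate(
      maternal_education = 6 + as.integer(factor(country_id)) + 0.05 * (year - 2000),
      log_gdp_pc = 7.5 + rnorm(dplyr::n(), 0, 0.3),
      child_underweight = 0.2 + 0.02 * sin(year) + rnorm(dplyr::n(), 0, 0.01),
      tfr = 4 + rnorm(dplyr::n(), 0, 0.5)
    )
}

test_that("covariate screening ranks by absolute correlation and skips constants", {
  cv <- toy_covariates(c("A1", "A2", "B1", "B2"))
  cv$flatline <- 1
  set.seed(2)
  obs <- cv |>
    dplyr::slice_sample(n = 30) |>
    dplyr::mutate(indicator = "initiation_24h",
                  value = expit(0.5 * maternal_education - 3 +
                                  rnorm(dplyr::n(), 0, 0.05)),
                  sample_size = 1000) |>
    dplyr::select(country_id, year, indicator, value, sample_size)
  expect_warning(sc <- bf_screen_covariates(obs, cv), "constant")
  expect_false("flatline" %in% sc$covariate)
  expect_identical(sc$covariate[sc$rank == 1], "maternal_education")
  expect_true(all(abs(sc$r) <= 1))
  expect_equal(sort(sc$rank), seq_len(nrow(sc)))
})

test_that("stage 1 recovers an exact logit-linear relationship", {
  cv <- toy_covariates(c("A1", "A2", "B1", "B2"))
  beta <- c(`(Intercept)` = -1, maternal_education = 0.2, log_gdp_pc = -0.3,
            child_underweight = -1.2, tfr = 0.1)
  obs <- cv |>
    dplyr::mutate(
      value = expit(beta[1] + beta[2] * maternal_education +
                      beta[3] * log_gdp_pc + beta[4] * child_underweight +
                      beta[5] * tfr),
      sample_size = 1000, subnational = FALSE
    ) |>
    dplyr::select(country_id, year, value, sample_size, subnational)
  # the noiseless construction makes the robust-variance code warn about a
  # perfect fit; the point here is exact coefficient recovery
  fit <- suppressWarnings(bf_fit_stage1(obs, cv))
  expect_s3_class(fit, "bf_stage1")
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-6)
  expect_equal(nrow(fit$predictions), nrow(cv))
  expect_lt(max(abs(fit$residuals$residual)), 1e-6)
  expect_equal(fit$n_clusters, 4)
})

test_that("stage 1 rejects small samples, missing covariates and collinearity", {
  cv <- toy_covariates(c("A1", "A2"))
  obs <- cv[1:12, ] |>
    dplyr::mutate(value = 0.4, sample_size = 500, subnational = FALSE) |>
    dplyr::select(country_id, year, value, sample_size, subnational)
  expect_error(bf_fit_stage1(obs[1:5, ], cv), class = "bf_model_error")
  cv2 <- dplyr::mutate(cv, tfr = 2 * log_gdp_pc)
  expect_error(bf_fit_stage1(obs, cv2), "collinear", class = "bf_model_error")
  obs3 <- dplyr::mutate(obs, year = year + 100)  # no covariate rows match
  expect_error(bf_fit_stage1(obs3, cv), class = "bf_model_error")
})

test_that("tidy and glance expose cluster-robust stage-1 inference", {
  w <- bf_sim_world(bf_sim_config(seed = 51))
  s <- bf_sim_surveys(w) |> dplyr::filter(indicator == "initiation_24h")
  fit <- bf_fit_stage1(s, w$covariates)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(nrow(td), 5)
  tcrit <- qt(0.975, fit$n_clusters - 1)
  expect_equal(td$conf.high - td$estimate, tcrit * td$std.error,
               tolerance = 1e-12)
  expect_equal(td$std.error, sqrt(diag(fit$vcov)), ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$n_clusters, fit$n_clusters)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})

test_that("the tricube time kernel has its textbook values", {
  w <- bf_st_weights()
  tw <- bfequity:::time_weight
  expect_equal(tw(0, w), 1)
  expect_equal(tw(5, w), (1 - 0.5^3)^3)
  expect_equal(tw(-5, w), (1 - 0.5^3)^3)
  expect_equal(tw(10, w), 0)
  expect_equal(tw(15, w), 0)
  expect_error(bf_st_weights(national_data_share = 0.4))
  expect_error(bf_st_weights(space_weight_region = 0))
})

fake_stage1 <- function(residuals, countries, years = 1995:2005) {
  list(
    residuals = residuals,
    predictions = tidyr::expand_grid(country_id = countries, year = years) |>
      dplyr::mutate(stage1_logit = 0)
  )
}

test_that("a single own-country residual passes through the smoother unchanged", {
  res <- tibble::tibble(country_id = "A1", year = 2000, residual = 0.7,
                        subnational = FALSE)
  s2 <- bf_fit_stage2(fake_stage1(res, toy_geo()$country_id), toy_geo())
  at <- s2[s2$country_id == "A1" & s2$year == 2000, ]
  expect_equal(at$st_residual, 0.7, tolerance = 1e-12)
  # within the bandwidth the single-point pool keeps its value
  near <- s2[s2$country_id == "A1" & abs(s2$year - 2000) < 10, ]
  expect_true(all(abs(near$st_residual - 0.7) < 1e-12))
})

test_that("borrowed residuals shrink by the spatial weight", {
  res <- tibble::tibble(country_id = "A2", year = 2000, residual = 0.6,
                        subnational = FALSE)
  s2 <- bf_fit_stage2(fake_stage1(res, toy_geo()$country_id), toy_geo())
  expect_equal(s2$st_residual[s2$country_id == "A1" & s2$year == 2000],
               0.5 * 0.6, tolerance = 1e-12)
  expect_equal(s2$st_residual[s2$country_id == "B1" & s2$year == 2000],
               0.25 * 0.6, tolerance = 1e-12)
})

test_that("an empty residual set yields a zero surface with a warning", {
  res <- tibble::tibble(country_id = character(), year = integer(),
                        residual = numeric(), subnational = logical())
  expect_warning(s2 <- bf_fit_stage2(fake_stage1(res, "A1"), toy_geo()),
                 "zero")
  expect_true(all(s2$st_residual == 0))
  expect_equal(s2$prior_logit, s2$stage1_logit)
})

test_that("the Matern kernel and jitter factorization behave at their limits", {
  expect_equal(bfequity:::matern52(0, 10), 1)
  expect_lt(bfequity:::matern52(30, 10), bfequity:::matern52(3, 10))
  S <- diag(2); S[1, 2] <- S[2, 1] <- 1  # singular but PSD: jitter succeeds
  expect_silent(bfequity:::chol_jitter(S))
  bad <- matrix(c(1, 2, 2, 1), 2)  # negative eigenvalue beyond jitter range
  expect_error(bfequity:::chol_jitter(bad), class = "bf_model_error")
  expect_error(bf_gpr_config(n_draws = 1))
  expect_error(bf_gpr_config(length_scale = 0))
})

test_that("stage 3 fills countries without data from the prior", {
  geo <- toy_geo()
  prior <- tidyr::expand_grid(country_id = geo$country_id, year = 1995:2005) |>
    dplyr::mutate(stage1_logit = 0, st_residual = 0, prior_logit = -0.5)
  obs <- tibble::tibble(
    country_id = "A1", year = c(1997, 2003), value = c(0.42, 0.47),
    sample_size = 1000, subnational = FALSE,
    variance = 1 / (1000 * 0.45 * 0.55)
  )
  fit <- bf_fit_stage3(prior, obs, geo,
                       bf_gpr_config(n_draws = 400, seed = 9))
  expect_equal(nrow(fit$summary), 4 * 11)
  expect_true(all(fit$summary$lower_95 <= fit$summary$mean))
  expect_true(all(fit$summary$mean <= fit$summary$upper_95))
  # the no-data countries share the prior-centered posterior
  nodata <- fit$summary[fit$summary$country_id == "B2", ]
  expect_true(all(abs(logit(nodata$mean) + 0.5) < 0.15))
  # data pull the observed country toward its observations
  a1 <- fit$summary[fit$summary$country_id == "A1" & fit$summary$year == 1997, ]
  expect_lt(abs(a1$mean - 0.42), 0.05)
  expect_error(
    bf_fit_stage3(prior, dplyr::mutate(obs, variance = 0), geo,
                  bf_gpr_config(n_draws = 10)),
    class = "bf_model_error"
  )
})

test_that("composition enforcement returns exact simplex shares for any draws", {
  set.seed(8)
  n <- 5000
  c1 <- runif(n); c2 <- runif(n); c3 <- runif(n)  # deliberately unordered
  comp <- bf_enforce_composition(c1, c2, c3)
  total <- comp$exclusive_0_5 + comp$predominant_0_5 + comp$partial_0_5 +
    comp$none_0_5
  expect_equal(total, rep(1, n), tolerance = 1e-12)
  expect_true(all(comp$exclusive_0_5 >= 0))
  expect_true(all(comp$predominant_0_5 >= -1e-15))
  expect_true(all(comp$partial_0_5 >= -1e-15))
  # already-ordered cumulatives are returned as their differences
  comp2 <- bf_enforce_composition(0.2, 0.5, 0.9)
  expect_equal(unlist(comp2),
               c(exclusive_0_5 = 0.2, predominant_0_5 = 0.3,
                 partial_0_5 = 0.4, none_0_5 = 0.1))
})

test_that("the full pipeline produces a complete, coherent, reproducible grid", {
  w <- bf_sim_world(bf_sim_config(seed = 61))
  s <- bf_sim_surveys(w)
  cfg <- bf_pipeline_config(gpr = bf_gpr_config(n_draws = 200), seed = 61)
  fit <- bf_estimate_prevalence(s, w$covariates, w$geo, cfg)
  est <- fit$estimates
  expect_equal(nrow(est), 24 * 21 * 6)
  expect_false(any(is.na(est$mean)))
  expect_true(all(est$lower_95 <= est$mean & est$mean <= est$upper_95))
  expect_true(all(est$mean > 0 & est$mean < 1))
  # the four 0-5 month shares sum to one, draw by draw and in the means
  sums <- fit$draws$exclusive_0_5 + fit$draws$predominant_0_5 +
    fit$draws$partial_0_5 + fit$draws$none_0_5
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
  # reproducibility under the same pipeline seed
  fit2 <- bf_estimate_prevalence(s, w$covariates, w$geo, cfg)
  expect_identical(fit$estimates, fit2$estimates)
})
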
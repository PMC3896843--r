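test_that("the shipped effect-size table satisfies its own validation contract", {
  eff <- bf_effect_sizes()
  expect_s3_class(eff, "bf_effect_sizes")
  expect_true(all(eff$rr_lower <= eff$rr_mean & eff$rr_mean <= eff$rr_upper))
  # reference categories carry RR 1 for every covered outcome-metric cell
  refs <- eff[eff$exposure_category %in% c("exclusive", "continued"), ]
  expect_true(all(refs$rr_mean == 1 & refs$rr_lower == 1 & refs$rr_upper == 1))
  expect_false(any(eff$exposure_category == "discontinued" &
                     eff$outcome == "pneumonia"))
  expect_false(any(grepl("initiation", eff$exposure_category)))
})

test_that("effect-size validation rejects each contract violation", {
  eff <- bf_effect_sizes()
  expect_error(bf_validate_effect_sizes(dplyr::select(eff, -rr_mean)),
               class = "bf_validation_error")
  bad_rr <- dplyr::mutate(eff, rr_mean = replace(rr_mean, 1, -2),
                          rr_lower = replace(rr_lower, 1, -3))
  expect_error(bf_validate_effect_sizes(bad_rr), class = "bf_validation_error")
  bad_ci <- dplyr::mutate(eff, rr_lower = replace(rr_lower, 1, 99))
  expect_error(bf_validate_effect_sizes(bad_ci), class = "bf_validation_error")
  with_excluded <- dplyr::bind_rows(eff, tibble::tibble(
    exposure_category = "discontinued", age_group = "6-23mo",
    outcome = "pneumonia", metric = "mortality",
    rr_mean = 2, rr_lower = 1, rr_upper = 4
  ))
  expect_error(bf_validate_effect_sizes(with_excluded),
               class = "bf_validation_error")
  with_initiation <- dplyr::bind_rows(eff, tibble::tibble(
    exposure_category = "late_initiation", age_group = "0-5mo",
    outcome = "diarrhea", metric = "mortality",
    rr_mean = 1.5, rr_lower = 1.1, rr_upper = 2
  ))
  expect_error(bf_validate_effect_sizes(with_initiation),
               class = "bf_validation_error")
})

test_that("relative-risk draws match the log-normal CI parameterization", {
  # symmetric-in-logs CI: the generating quantiles hit the printed bounds
  sigma <- log(4 / 1) / (2 * qnorm(0.975))
  expect_equal(qlnorm(0.025, log(2), sigma), 1, tolerance = 1e-12)
  expect_equal(qlnorm(0.975, log(2), sigma), 4, tolerance = 1e-12)
  d <- bf_rr_draws(2, 1, 4, n_draws = 40000, seed = 3)
  expect_equal(median(d), 2, tolerance = 0.03)
  expect_equal(unname(quantile(d, 0.975)), 4, tolerance = 0.1)
  # degenerate CI gives constant draws; draws never truncated at 1
  expect_equal(bf_rr_draws(3, 3, 3, n_draws = 10), rep(3, 10))
  d2 <- bf_rr_draws(1.26, 0.81, 1.95, n_draws = 5000, seed = 4)
  expect_gt(mean(d2 < 1), 0.05)
  expect_identical(bf_rr_draws(2, 1, 4, n_draws = 100, seed = 5),
                   bf_rr_draws(2, 1, 4, n_draws = 100, seed = 5))
  expect_error(bf_rr_draws(2, 3, 4))
})

test_that("the attributable fraction validates its exposure inputs", {
  p <- c(a = 0.6, b = 0.4); rr <- c(a = 1, b = 2)
  expect_error(bf_paf(unname(p), rr), class = "bf_validation_error")
  expect_error(bf_paf(p, c(a = 1, c = 2)), class = "bf_validation_error")
  expect_error(bf_paf(c(a = 0.6, b = 0.6), rr), class = "bf_validation_error")
  expect_error(bf_paf(p, rr, p_counterfactual = c(a = 0.5, b = 0.4)),
               class = "bf_validation_error")
  # category order never matters
  expect_equal(bf_paf(p, rr[c("b", "a")]), bf_paf(p, rr), tolerance = 1e-15)
  # protective draws (RR < 1) yield negative fractions, unclipped
  expect_lt(bf_paf(p, c(a = 1, b = 0.5)), 0)
})

test_that("attributable burden scales PAF draws by the background envelope", {
  paf <- c(0.2, 0.4, 0.6)
  out <- bf_attributable_burden(paf, 500)
  expect_equal(out$attributable_mean, mean(paf) * 500)
  expect_equal(attr(out, "draws"), paf * 500)
  expect_equal(out$paf_mean, 0.4)
  expect_error(bf_attributable_burden(paf, -1), class = "bf_validation_error")
})

make_fake_fit <- function(n_cells = 4, n_draws = 60, seed = 5) {
  set.seed(seed)
  cells <- tibble::tibble(country_id = sprintf("C%d", seq_len(n_cells)),
                          year = 2010)
  rmat <- function(lo, hi) {
    matrix(runif(n_cells * n_draws, lo, hi), n_cells, n_draws)
  }
  excl <- rmat(0.2, 0.4); pred <- rmat(0.1, 0.2); part <- rmat(0.2, 0.3)
  list(cells = cells,
       draws = list(
         exclusive_0_5 = excl, predominant_0_5 = pred, partial_0_5 = part,
         none_0_5 = 1 - excl - pred - part,
         continued_6_11 = rmat(0.6, 0.9), continued_12_23 = rmat(0.3, 0.6),
         initiation_24h = rmat(0.3, 0.5)
       ))
}

fake_background <- function(cells) {
  tidyr::expand_grid(
    cells,
    cause = c("diarrhea", "pneumonia"),
    age_group = c("0-5mo", "6-23mo"),
    metric = c("deaths", "DALYs")
  ) |>
    dplyr::mutate(value = 100 + 10 * seq_len(dplyr::n()))
}

test_that("the risk assessment pairs draws and excludes forbidden cells", {
  fit <- make_fake_fit()
  bg <- fake_background(fit$cells)
  b <- bf_burden_cra(fit, bg, seed = 11)
  expect_s3_class(b, "bf_burden")
  # excluded pair never produced, even though its background exists
  expect_false(any(b$age_group == "6-23mo" & b$outcome == "pneumonia"))
  expect_setequal(unique(b$outcome[b$age_group == "0-5mo"]),
                  c("diarrhea", "pneumonia"))
  # attributable draws are PAF draws times the matched background, per draw
  expect_true(all(vapply(seq_len(nrow(b)), function(i) {
    d <- b$.draws[[i]]
    abs(mean(d) - b$attributable_mean[i]) < 1e-9 &&
      abs(mean(d) / b$background[i] - b$paf_mean[i]) < 1e-9
  }, logical(1))))
  # the 6-23 month exposure is the duration-weighted continued mix
  cont <- (6 / 18) * fit$draws$continued_6_11 +
    (12 / 18) * fit$draws$continued_12_23
  rr <- bf_rr_draws(2.18, 1.14, 4.16, n_draws = 60,
                    seed = bfequity:::substream_seed(
                      11, paste("discontinued", "6-23mo", "diarrhea",
                                "mortality")))
  denom <- cont * 1 + (1 - cont) * matrix(rr, 4, 60, byrow = TRUE)
  paf_manual <- (denom - 1) / denom  # counterfactual: 100% continued, RR 1
  row <- b[b$age_group == "6-23mo" & b$metric == "deaths" &
             b$country_id == "C1", ]
  expect_equal(row$paf_mean, mean(paf_manual[1, ]), tolerance = 1e-9)
  # identical seeds reproduce the assessment exactly
  b2 <- bf_burden_cra(fit, bg, seed = 11)
  expect_equal(dplyr::select(b, -.draws), dplyr::select(b2, -.draws))
})

test_that("burden cells outside the estimated grid are rejected", {
  fit <- make_fake_fit()
  bg <- fake_background(fit$cells)
  bg$country_id[1] <- "ELSEWHERE"
  expect_error(bf_burden_cra(fit, bg, seed = 1),
               class = "bf_validation_error")
})

test_that("aggregation sums at the draw level and refuses to mix metrics", {
  fit <- make_fake_fit()
  b <- bf_burden_cra(fit, fake_background(fit$cells), seed = 7)
  agg <- bf_aggregate_burden(b, by = c("year", "metric"))
  expect_equal(nrow(agg), 2)
  deaths <- b[b$metric == "deaths", ]
  expect_equal(agg$attributable_mean[agg$metric == "deaths"],
               mean(Reduce(`+`, deaths$.draws)), tolerance = 1e-9)
  expect_equal(agg$background[agg$metric == "deaths"], sum(deaths$background))
  expect_equal(agg$percent_of_total,
               100 * agg$attributable_mean / agg$background)
  expect_error(bf_aggregate_burden(b, by = "year"),
               class = "bf_validation_error")
})

test_that("risk ranking flags ties and counts leading risks", {
  rb <- tibble::tibble(
    country_id = rep(c("A", "B", "C"), each = 3),
    risk = rep(c("r1", "r2", "r3"), 3),
    value = c(10, 5, 1,   7, 7, 2,   3, 8, 9)
  )
  rk <- bf_rank_risks(rb)
  ra <- rk$ranks[rk$ranks$country_id == "A", ]
  expect_equal(ra$rank[ra$risk == "r1"], 1L)
  expect_false(any(ra$tied))
  rbty <- rk$ranks[rk$ranks$country_id == "B", ]
  expect_true(all(rbty$tied[rbty$risk %in% c("r1", "r2")]))
  lead <- rk$leading_counts
  expect_equal(lead$n_countries_leading[lead$risk == "r1"], 2L)  # A and tied B
  expect_equal(lead$n_countries_leading[lead$risk == "r3"], 1L)
  expect_error(bf_rank_risks(rb[1, ]), class = "bf_validation_error")
})
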
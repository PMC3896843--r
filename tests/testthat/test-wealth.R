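test_that("asset selection drops constants, collapses duplicates, flips reverse goods", {
  hh <- bf_sim_households(n_households = 800, seed = 4)
  hh$asset_const <- 1L
  hh$asset_dup <- hh$asset_1
  hh$asset_rev <- 1L - hh$asset_2  # reverse good: ownership falls with wealth
  sel <- bf_select_assets(hh)
  info <- sel$info
  expect_false(info$kept[info$asset_id == "asset_const"])
  expect_identical(info$reason[info$asset_id == "asset_const"], "constant")
  expect_false(info$kept[info$asset_id == "asset_dup"])
  expect_identical(info$reason[info$asset_id == "asset_dup"], "duplicate")
  expect_true(info$flipped[info$asset_id == "asset_rev"])
  # after flipping, every retained column is increasing in the proxy
  expect_true(all(info$loading[info$kept] != 0, na.rm = TRUE))
  expect_equal(sel$assets[, "asset_rev"], as.numeric(hh$asset_2),
               ignore_attr = TRUE)
  expect_error(bf_select_assets(hh["household_id"]), class = "bf_model_error")
})

test_that("first-pass cutpoints invert the normal ownership rate", {
  A <- cbind(a = rep(c(1, 0), c(30, 70)), b = rep(c(1, 0), c(80, 20)),
             c = rep(c(0, 1), c(50, 50)))
  cp <- bf_fit_cutpoints(A)
  expect_equal(cp$cutpoint, qnorm(1 - c(0.3, 0.8, 0.5)), tolerance = 1e-12)
  expect_equal(cp$discrimination, rep(1, 3))
  bad <- cbind(A, d = rep(1, 100))
  expect_error(bf_fit_cutpoints(bad), class = "bf_contract_error")
})

test_that("the income posterior mode solves the score equation", {
  # one asset, d = 1, cutpoint 0: the owner's mode solves y = phi(y)/Phi(y)
  A <- matrix(c(1, 0), nrow = 2)
  y <- bfequity:::income_posterior_mode(A, cutpoint = 0, discrimination = 1)
  root_own <- uniroot(function(u) u - dnorm(u) / pnorm(u), c(0, 2),
                      tol = 1e-12)$root
  expect_equal(y[1], root_own, tolerance = 1e-8)
  expect_equal(y[2], -root_own, tolerance = 1e-8)  # symmetric for non-owner
  # general case: numerical gradient of the log posterior vanishes at the mode
  set.seed(6)
  A2 <- matrix(rbinom(40, 1, 0.5), nrow = 10)
  cp <- c(-0.5, 0, 0.3, 0.8); d <- c(0.8, 1.2, 1, 0.6)
  y2 <- bfequity:::income_posterior_mode(A2, cp, d)
  logpost <- function(u, i) {
    -u^2 / 2 + sum(ifelse(A2[i, ] == 1,
                          pnorm(d * (u - cp), log.p = TRUE),
                          pnorm(d * (u - cp), log.p = TRUE, lower.tail = FALSE)))
  }
  for (i in 1:10) {
    g <- (logpost(y2[i] + 1e-6, i) - logpost(y2[i] - 1e-6, i)) / 2e-6
    expect_lt(abs(g), 1e-4)
  }
})

test_that("quintile assignment is balanced, rank-based and stable under ties", {
  q <- bf_assign_quintiles(c(5, 1, 3, 2, 4, 10, 9, 8, 7, 6))
  expect_equal(sort(table(q)), rep(2, 5), ignore_attr = TRUE)
  expect_equal(q[2], 1L)   # smallest income -> poorest quintile
  expect_equal(q[6], 5L)   # largest income -> richest quintile
  # ties keep input order (stable)
  qt <- bf_assign_quintiles(rep(1, 10))
  expect_equal(qt, rep(1:5, each = 2))
  qna <- bf_assign_quintiles(c(1:9, NA))
  expect_true(is.na(qna[10]))
  expect_equal(sum(!is.na(qna)), 9)
  expect_error(bf_assign_quintiles(1:4), class = "bf_model_error")
})

test_that("income estimation is deterministic and carries asset parameters", {
  hh <- bf_sim_households(n_households = 600, seed = 7)
  sel <- bf_select_assets(hh)
  inc1 <- bf_estimate_income(sel)
  inc2 <- bf_estimate_income(sel)
  expect_equal(inc1$permanent_income, inc2$permanent_income, tolerance = 1e-12)
  expect_identical(inc1$quintile,
                   bf_assign_quintiles(inc1$permanent_income))
  ap <- attr(inc1, "asset_params")
  expect_true(all(c("asset_id", "cutpoint", "discrimination") %in% names(ap)))
  expect_true(all(ap$discrimination > 0))
})

test_that("households with all assets missing are excluded with a warning", {
  hh <- bf_sim_households(n_households = 300, seed = 8)
  sel <- bf_select_assets(hh)
  sel$assets[1, ] <- NA
  expect_warning(inc <- bf_estimate_income(sel), "excluded")
  expect_true(is.na(inc$permanent_income[1]))
  expect_true(is.na(inc$quintile[1]))
  expect_equal(sum(is.na(inc$permanent_income)), 1)
})

test_that("quintile prevalence matches a hand-computed weighted share", {
  rec <- tibble::tibble(
    year = 2000, quintile = c(1, 1, 1, 2, 2),
    bf_status = c(1, 0, 1, 1, 0), weight = c(2, 1, 1, 1, 3)
  )
  expect_warning(qp <- bf_quintile_prevalence(rec), "no children")
  q1 <- qp[qp$quintile == 1 & qp$year == 2000, ]
  expect_equal(q1$prevalence, 3 / 4)  # (2*1 + 1*0 + 1*1) / 4
  q2 <- qp[qp$quintile == 2 & qp$year == 2000, ]
  expect_equal(q2$prevalence, 1 / 4)  # (1*1 + 3*0) / 4
  expect_true(all(qp$empty_cell[qp$quintile %in% 3:5]))
  expect_error(bf_quintile_prevalence(dplyr::select(rec, -quintile)),
               class = "bf_model_error")
})

test_that("children link to estimated quintiles through the income table", {
  hh <- bf_sim_households(n_households = 500, seed = 9)
  inc <- bf_estimate_income(bf_select_assets(hh))
  kids <- bf_sim_children(hh, n_children = 2000,
                          prev_by_quintile = c(0.2, 0.3, 0.4, 0.5, 0.6),
                          seed = 9)
  qp <- bf_quintile_prevalence(kids, income = inc)
  expect_false(any(qp$empty_cell))
  # prevalence rises across estimated quintiles as built into the children
  expect_gt(qp$prevalence[qp$quintile == 5], qp$prevalence[qp$quintile == 1])
})

test_that("trend slopes, the common slope and z-excess follow their definitions", {
  set.seed(10)
  qp <- tidyr::expand_grid(year = c(1995, 2000, 2005, 2010), quintile = 1:5) |>
    dplyr::mutate(
      prevalence = 0.3 + 0.004 * (year - 1995) +
        ifelse(quintile == 5, 0.008 * (year - 1995), 0) +
        rnorm(20, 0, 0.004),
      se = 0.01, n = 500, empty_cell = FALSE
    )
  tr <- bf_quintile_trends(qp)
  # per-quintile slope equals a direct weighted regression (equal weights here)
  for (q in 1:5) {
    sub <- qp[qp$quintile == q, ]
    expect_equal(tr$slopes$slope[q], unname(coef(lm(prevalence ~ year, sub))[2]),
                 tolerance = 1e-10)
  }
  wts <- 1 / tr$slopes$se^2
  expect_equal(tr$common_slope, sum(wts * tr$slopes$slope) / sum(wts),
               tolerance = 1e-12)
  expect_equal(tr$slopes$z_excess,
               (tr$slopes$slope - tr$common_slope) / tr$slopes$se,
               tolerance = 1e-12)
  expect_true(tr$verdict %in% c("uniform", "top-concentrated",
                                "bottom-concentrated", "mixed"))
  td <- tidy(tr); gl <- glance(tr)
  expect_equal(nrow(td), 5)
  expect_identical(gl$verdict, tr$verdict)
})

test_that("series with too few time points are excluded, not silently classified", {
  qp <- tidyr::expand_grid(year = c(2000, 2005), quintile = 1:5) |>
    dplyr::mutate(prevalence = 0.3, se = 0.01, n = 500, empty_cell = FALSE)
  expect_error(bf_quintile_trends(qp), class = "bf_excluded")
})
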
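#' Select usable wealth assets
#'
#' Keeps assets whose ownership behaves as a normal or reverse-normal good
#' with respect to household wealth: constant columns (owned by nobody or
#' everybody) carry no information and are dropped; exact duplicate columns
#' are collapsed to one (they would otherwise double-count the same
#' information); assets whose ownership decreases in a crude wealth proxy (the
#' first principal axis of the centered asset matrix) are reverse goods and
#' are sign-flipped (ownership recoded as non-ownership) so that every
#' retained column is increasing in wealth.
#'
#' @param households Tibble with `household_id` and binary `asset_*` columns
#'   (any column whose name starts with `asset` is treated as an asset).
#' @return List of class `bf_asset_selection`: `assets` (households x assets
#'   0/1 matrix after filtering/flipping), `household_id`, `info` (tibble
#'   `asset_id`, `kept`, `flipped`, `reason`, `loading`).
#' @export
bf_select_assets <- function(households) {
  asset_cols <- grep("^asset", names(households), value = TRUE)
  if (length(asset_cols) < 3) {
    abort("need at least 3 asset columns", class = "bf_model_error")
  }
  A <- as.matrix(households[asset_cols])
  storage.mode(A) <- "double"
  info <- tibble::tibble(asset_id = asset_cols, kept = TRUE, flipped = FALSE,
                         reason = NA_character_, loading = NA_real_)

  const <- apply(A, 2, function(x) var(x) == 0)
  info$kept[const] <- FALSE
  info$reason[const] <- "constant"

  # collapse exact duplicates (keep the first of each duplicate set)
  keys <- apply(A, 2, paste, collapse = "")
  dup <- duplicated(keys) & !const
  info$kept[dup] <- FALSE
  info$reason[dup] <- "duplicate"

  use <- info$kept
  if (sum(use) < 3) {
    abort("fewer than 3 usable assets after filtering", class = "bf_model_error")
  }
  Au <- A[, use, drop = FALSE]
  # crude wealth proxy: first principal axis of the centered asset matrix
  pc <- stats::prcomp(Au, center = TRUE, scale. = FALSE)
  proxy <- pc$x[, 1]
  loadings <- as.numeric(cor(Au, proxy))
  # orient the proxy so that the majority of assets increase in it
  if (sum(loadings > 0) < sum(loadings < 0)) {
    proxy <- -proxy
    loadings <- -loadings
  }
  info$loading[use] <- loadings
  flip <- loadings < 0
  Au[, flip] <- 1 - Au[, flip]
  info$flipped[use] <- flip

  structure(list(assets = Au, household_id = households$household_id,
                 info = info),
            class = "bf_asset_selection")
}

#' First-pass asset cutpoints from ownership rates
#'
#' Under a standard-normal latent income, an asset owned by a fraction `p` of
#' households has probit cutpoint `qnorm(1 - p)`: rarer assets sit higher on
#' the income scale. These first-pass cutpoints (with unit discriminations)
#' are the starting point for the joint refinement in
#' [bf_estimate_income()].
#'
#' @param selection A [bf_select_assets()] object (or a 0/1 matrix).
#' @return Tibble `asset_id`, `ownership_rate`, `cutpoint`, `discrimination`.
#' @export
bf_fit_cutpoints <- function(selection) {
  A <- if (inherits(selection, "bf_asset_selection")) selection$assets else selection
  rates <- colMeans(A)
  if (any(rates <= 0 | rates >= 1)) {
    abort("ownership rate 0 or 1 reached the cutpoint fit; assets must be filtered first",
          class = "bf_contract_error")
  }
  tibble::tibble(
    asset_id = colnames(A) %||% sprintf("asset_%d", seq_along(rates)),
    ownership_rate = unname(rates),
    cutpoint = qnorm(1 - unname(rates)),
    discrimination = 1
  )
}

# Posterior mode of latent income for each household under a standard-normal
# prior and probit item likelihoods; solved by Newton iterations on the
# concave log posterior (probit log-likelihoods are concave in y).
income_posterior_mode <- function(A, cutpoint, discrimination) {
  y <- rep(0, nrow(A))
  d <- discrimination
  for (iter in 1:50) {
    grad <- -y
    hess <- rep(-1, length(y))
    for (k in seq_len(ncol(A))) {
      z <- d[k] * (y - cutpoint[k])
      # d/dy log Phi(z) = d * phi/Phi for owners; -d * phi/(1-Phi) otherwise
      mr_own <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
      mr_not <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE,
                                                 lower.tail = FALSE))
      own <- A[, k] == 1
      g <- ifelse(own, d[k] * mr_own, -d[k] * mr_not)
      h <- ifelse(own, -d[k]^2 * mr_own * (z + mr_own),
                  -d[k]^2 * mr_not * (mr_not - z))
      grad <- grad + g
      hess <- hess + h
    }
    step <- grad / pmin(hess, -1e-8)
    y <- y - step
    if (max(abs(step)) < 1e-10) break
  }
  y
}

#' Estimate household permanent income from assets
#'
#' Two-step latent-variable model: first-pass cutpoints are set from
#' ownership rates under a standard-normal income prior; cutpoints,
#' per-asset discriminations and household incomes are then refined by
#' alternating updates (given incomes, a per-asset probit of ownership on
#' income gives slope and cutpoint; given asset parameters, each household's
#' income is the posterior mode under the standard-normal prior times the
#' probit item likelihoods). Iteration stops after `max_iter` rounds or when
#' the relative change in incomes falls below `tol`. The returned income is a
#' deterministic function of the asset table.
#'
#' @param selection A [bf_select_assets()] object.
#' @param max_iter Maximum alternating updates (default 10).
#' @param tol Relative-change stopping tolerance (default 1e-4).
#' @return Tibble of class `bf_income`: `household_id`, `permanent_income`,
#'   `quintile`; attribute `asset_params` holds the refined cutpoints and
#'   discriminations.
#' @export
bf_estimate_income <- function(selection, max_iter = 10, tol = 1e-4) {
  stopifnot(inherits(selection, "bf_asset_selection"))
  A <- selection$assets
  miss_all <- apply(A, 1, function(x) all(is.na(x)))
  if (any(miss_all)) {
    warn(sprintf("%d household(s) with all assets missing excluded", sum(miss_all)))
  }
  Ause <- A[!miss_all, , drop = FALSE]
  cp_tbl <- bf_fit_cutpoints(structure(list(assets = Ause),
                                       class = "bf_asset_selection"))
  cutpoint <- cp_tbl$cutpoint
  d <- cp_tbl$discrimination

  y <- income_posterior_mode(Ause, cutpoint, d)
  for (it in seq_len(max_iter)) {
    # per-asset probit of ownership on current incomes
    for (k in seq_len(ncol(Ause))) {
      fit <- suppressWarnings(
        stats::glm(Ause[, k] ~ y, family = stats::binomial(link = "probit"))
      )
      b <- coef(fit)
      if (is.finite(b[2]) && b[2] > 0.05) {
        d[k] <- min(b[2], 10)
        cutpoint[k] <- -b[1] / b[2]
      }
    }
    # standardize the income scale against drift
    y_new <- income_posterior_mode(Ause, cutpoint, d)
    rel <- max(abs(y_new - y)) / max(max(abs(y)), 1e-8)
    y <- y_new
    if (rel < tol) break
  }

  income <- rep(NA_real_, length(selection$household_id))
  income[!miss_all] <- y
  out <- tibble::tibble(
    household_id = selection$household_id,
    permanent_income = income
  )
  out <- dplyr::bind_cols(out, quintile = bf_assign_quintiles(out))
  attr(out, "asset_params") <- tibble::tibble(
    asset_id = colnames(Ause) %||% sprintf("asset_%d", ncol(Ause)),
    cutpoint = cutpoint, discrimination = d
  )
  class(out) <- c("bf_income", class(out))
  out
}

#' Assign wealth quintiles by income rank
#'
#' Orders households by estimated permanent income (ties broken by stable
#' input order) and splits them into five groups whose sizes differ by at
#' most one household. Households with missing income get a missing quintile.
#'
#' @param income Tibble with a `permanent_income` column (e.g.
#'   [bf_estimate_income()] output), or a numeric vector.
#' @return Integer vector of quintiles, 1 = poorest.
#' @export
bf_assign_quintiles <- function(income) {
  y <- if (is.data.frame(income)) income$permanent_income else income
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < 5) abort("need at least 5 incomes to form quintiles",
                   class = "bf_model_error")
  q <- rep(NA_integer_, length(y))
  r <- rank(y[ok], ties.method = "first")  # stable: ties keep input order
  q[ok] <- as.integer(ceiling(5 * r / n))
  q
}

#' Breastfeeding prevalence by wealth quintile
#'
#' Computes, per survey year and quintile, the (optionally weighted) share of
#' children with positive breastfeeding status and its binomial standard
#' error. Children are linked to a household income table via `household_id`,
#' or carry a precomputed `quintile` column directly (pass-through mode, as
#' for surveys that ship their own wealth quintile variable).
#'
#' @param records Child-level tibble: `year`, `bf_status` (0/1), optional
#'   `weight`, and either `quintile` or `household_id`.
#' @param income Optional [bf_estimate_income()] output (required when
#'   `records` has no `quintile` column).
#' @return Tibble `year`, `quintile`, `prevalence`, `se`, `n`; quintile-year
#'   cells with no children are returned with missing prevalence and flagged.
#' @export
bf_quintile_prevalence <- function(records, income = NULL) {
  rec <- records
  if (!"quintile" %in% names(rec)) {
    if (is.null(income)) {
      abort("records carry no quintile; supply an income table",
            class = "bf_model_error")
    }
    rec <- dplyr::left_join(
      rec, dplyr::select(income, "household_id", "quintile"),
      by = "household_id"
    )
  }
  if (!"weight" %in% names(rec)) rec$weight <- 1
  out <- rec |>
    dplyr::filter(!is.na(.data$quintile)) |>
    dplyr::group_by(.data$year, .data$quintile) |>
    dplyr::summarise(
      prevalence = sum(.data$weight * .data$bf_status) / sum(.data$weight),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = sqrt(pmax(.data$prevalence * (1 - .data$prevalence), 1e-12) /
                              .data$n))
  full <- tidyr::expand_grid(year = unique(rec$year), quintile = 1:5)
  out <- dplyr::left_join(full, out, by = c("year", "quintile"))
  empty <- is.na(out$prevalence)
  if (any(empty)) {
    warn(sprintf("%d quintile-year cell(s) with no children", sum(empty)))
  }
  out$empty_cell <- empty
  dplyr::arrange(out, .data$year, .data$quintile)
}

#' Compare prevalence trends across wealth quintiles
#'
#' Fits, per quintile, an inverse-variance-weighted least-squares slope of
#' prevalence on year (percentage points per year on the proportion scale),
#' tests slope homogeneity across quintiles with an F-test of the
#' year-by-quintile interaction in the pooled weighted model, and classifies
#' the pattern: `uniform` when the interaction is not significant at
#' `alpha`; otherwise `top-concentrated` / `bottom-concentrated` when every
#' quintile with significantly positive slope excess (z >= 1.96 against the
#' precision-weighted common slope) lies in quintiles 4-5 / 1-2 respectively,
#' and `mixed` in all other cases. Requires at least `min_points` time points;
#' series below the threshold are excluded with an error of class
#' `bf_excluded`.
#'
#' @param quintile_prevalence Output of [bf_quintile_prevalence()] (a year x
#'   quintile series with `prevalence` and `se`).
#' @param alpha Homogeneity test level (default 0.05).
#' @param min_points Minimum number of distinct years (default 3).
#' @return List of class `bf_quintile_trends`: `slopes` (tibble `quintile`,
#'   `slope`, `se`, `z_excess`), `common_slope`, `f_statistic`, `p_value`,
#'   `verdict`.
#' @export
bf_quintile_trends <- function(quintile_prevalence, alpha = 0.05,
                               min_points = 3) {
  qp <- dplyr::filter(quintile_prevalence, !is.na(.data$prevalence))
  n_years <- dplyr::n_distinct(qp$year)
  if (n_years < min_points) {
    abort(sprintf("only %d time point(s); at least %d required", n_years,
                  min_points),
          class = "bf_excluded")
  }
  qp <- dplyr::mutate(qp, w = 1 / pmax(.data$se^2, 1e-12),
                      quintile = factor(.data$quintile, levels = 1:5))

  full <- lm(prevalence ~ quintile * year, data = qp, weights = w)
  reduced <- lm(prevalence ~ quintile + year, data = qp, weights = w)
  av <- anova(reduced, full)
  fstat <- av$F[2]
  pval <- av$`Pr(>F)`[2]

  slopes <- purrr::map_dfr(1:5, function(q) {
    sub <- qp[qp$quintile == q, ]
    fit <- lm(prevalence ~ year, data = sub, weights = w)
    sm <- summary(fit)
    tibble::tibble(quintile = q, slope = coef(fit)[["year"]],
                   se = sm$coefficients["year", "Std. Error"])
  })
  wts <- 1 / slopes$se^2
  common <- sum(wts * slopes$slope) / sum(wts)
  slopes$z_excess <- (slopes$slope - common) / slopes$se

  verdict <- if (is.na(pval) || pval >= alpha) {
    "uniform"
  } else {
    sig_pos <- slopes$quintile[slopes$z_excess >= 1.96]
    if (length(sig_pos) > 0 && all(sig_pos %in% 4:5)) {
      "top-concentrated"
    } else if (length(sig_pos) > 0 && all(sig_pos %in% 1:2)) {
      "bottom-concentrated"
    } else {
      "mixed"
    }
  }
  structure(list(slopes = slopes, common_slope = common, f_statistic = fstat,
                 p_value = pval, verdict = verdict, alpha = alpha),
            class = "bf_quintile_trends")
}

#' @export
print.bf_quintile_trends <- function(x, ...) {
  cat(sprintf("Quintile trend comparison: verdict '%s' (F = %.2f, p = %.3g)\n",
              x$verdict, x$f_statistic, x$p_value))
  print(dplyr::mutate(x$slopes, dplyr::across(dplyr::where(is.numeric),
                                              ~round(.x, 5))))
  invisible(x)
}
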
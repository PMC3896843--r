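#' Estimate definition-correction factors from paired observations
#'
#' Surveys analysed under a non-standard indicator definition are mapped onto
#' the standard WHO definition by an additive shift on the logit scale. The
#' shift is estimated, per indicator (or pooled across indicators), from
#' country-years observed under both definitions: it is the precision-weighted
#' mean of `logit(standard) - logit(nonstandard)` over pairs, weighted by the
#' inverse sampling variance of each pair difference. At least two pairs are
#' required; with fewer the model is flagged unusable and downstream code
#' drops (rather than corrects) that indicator's non-standard points.
#'
#' @param observations Survey observation tibble (see [bf_sim_surveys()] for
#'   the schema: `country_id`, `year`, `indicator`, `value`, `sample_size`,
#'   `nonstandard`, `variance`).
#' @param pool Either `"indicator"` (default: one shift per indicator) or
#'   `"all"` (a single shift pooled over indicators).
#' @return Tibble of class `bf_correction_models`: `indicator`,
#'   `additive_logit_shift`, `shift_se`, `n_pairs`, `usable`.
#' @export
bf_correction_factors <- function(observations, pool = c("indicator", "all")) {
  pool <- match.arg(pool)
  obs <- dplyr::mutate(
    observations,
    logit_value = logit(clamp_proportion(.data$value, .data$sample_size))
  )
  std <- dplyr::filter(obs, !.data$nonstandard)
  nst <- dplyr::filter(obs, .data$nonstandard)

  pairs <- dplyr::inner_join(
    dplyr::select(std, "country_id", "year", "indicator",
                  std_logit = "logit_value", std_var = "variance"),
    dplyr::select(nst, "country_id", "year", "indicator",
                  nst_logit = "logit_value", nst_var = "variance"),
    by = c("country_id", "year", "indicator"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      diff = .data$std_logit - .data$nst_logit,
      w = 1 / (.data$std_var + .data$nst_var)
    )

  key <- if (pool == "indicator") "indicator" else character(0)
  fit_group <- function(df) {
    n <- nrow(df)
    if (n < 2) {
      return(tibble::tibble(additive_logit_shift = NA_real_,
                            shift_se = NA_real_, n_pairs = n, usable = FALSE))
    }
    shift <- sum(df$w * df$diff) / sum(df$w)
    tibble::tibble(additive_logit_shift = shift,
                   shift_se = sqrt(1 / sum(df$w)),
                   n_pairs = n, usable = TRUE)
  }
  models <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::group_modify(~fit_group(.x)) |>
    dplyr::ungroup()
  # indicators with no pairs at all
  if (pool == "indicator") {
    missing <- setdiff(unique(obs$indicator), models$indicator)
    if (length(missing) > 0) {
      models <- dplyr::bind_rows(models, tibble::tibble(
        indicator = missing, additive_logit_shift = NA_real_,
        shift_se = NA_real_, n_pairs = 0L, usable = FALSE
      ))
    }
  } else {
    models$indicator <- "(pooled)"
  }
  structure(dplyr::arrange(models, .data$indicator),
            class = c("bf_correction_models", class(models)))
}

#' Apply definition corrections to survey observations
#'
#' Non-standard observations are shifted on the logit scale by the indicator's
#' estimated correction, their logit-scale sampling variance is inflated by
#' the squared standard error of the shift, and they are re-flagged as
#' corrected (`nonstandard = FALSE`, `corrected_flag = TRUE`). Standard and
#' already-corrected observations pass through unchanged, so the operation is
#' idempotent. Non-standard observations of an indicator whose correction
#' model is unusable are dropped with a warning naming the count.
#'
#' @param observations Survey observation tibble.
#' @param models Output of [bf_correction_factors()].
#' @return Corrected observation tibble with added columns `corrected_flag`
#'   and `variance_inflation`.
#' @export
bf_apply_corrections <- function(observations, models) {
  obs <- observations
  if (!"corrected_flag" %in% names(obs)) obs$corrected_flag <- FALSE
  if (!"variance_inflation" %in% names(obs)) obs$variance_inflation <- 0

  pooled <- identical(unique(models$indicator), "(pooled)")
  if (pooled) {
    obs$additive_logit_shift <- models$additive_logit_shift[1]
    obs$shift_se <- models$shift_se[1]
    obs$usable <- models$usable[1]
  } else {
    obs <- dplyr::left_join(
      obs,
      dplyr::select(models, "indicator", "additive_logit_shift", "shift_se",
                    "usable"),
      by = "indicator"
    )
    obs$usable[is.na(obs$usable)] <- FALSE
  }

  needs <- obs$nonstandard & !obs$corrected_flag
  drop <- needs & !obs$usable
  if (any(drop)) {
    warn(sprintf("dropping %d non-standard observation(s) with unusable correction model",
                 sum(drop)))
  }
  fix <- needs & obs$usable
  if (any(fix)) {
    lv <- logit(clamp_proportion(obs$value[fix], obs$sample_size[fix]))
    obs$value[fix] <- expit(lv + obs$additive_logit_shift[fix])
    obs$variance_inflation[fix] <- obs$shift_se[fix]^2
    obs$variance[fix] <- obs$variance[fix] + obs$shift_se[fix]^2
    obs$corrected_flag[fix] <- TRUE
    obs$nonstandard[fix] <- FALSE
  }
  dplyr::select(obs[!drop, ], -"additive_logit_shift", -"shift_se", -"usable")
}

#' Harmonize survey observations in one step
#'
#' Convenience wrapper: estimates correction factors from the definition pairs
#' in `observations` and applies them.
#'
#' @inheritParams bf_correction_factors
#' @return Corrected observation tibble; the fitted correction models are
#'   attached as attribute `correction_models`.
#' @export
bf_harmonize <- function(observations, pool = c("indicator", "all")) {
  models <- bf_correction_factors(observations, pool = pool)
  out <- bf_apply_corrections(observations, models)
  attr(out, "correction_models") <- models
  out
}
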
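#' @importFrom rlang .data .env abort warn %||%
#' @importFrom stats lm coef qnorm pnorm dnorm rnorm rbinom rpois runif rlnorm
#'   quantile median mad sd var cor optimize pf pt qt anova setNames predict
#'   complete.cases
#' @importFrom utils head
NULL

#' Logit and inverse-logit
#'
#' Plain log-odds transforms used throughout the package; all modelling is done
#' on the logit scale so prevalences stay in (0, 1).
#'
#' @param p Proportion in (0, 1).
#' @param x Real number.
#' @return `logit()` returns log(p / (1 - p)); `expit()` its inverse.
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Clamp a proportion away from 0 and 1 before taking logits
#'
#' Observed survey proportions of exactly 0 or 1 have infinite logits; they are
#' clamped to `[1/(4n), 1 - 1/(4n)]`, where `n` is the sample size behind the
#' proportion, before any logit transform.
#'
#' @param p Proportions.
#' @param n Sample sizes (recycled).
#' @return Clamped proportions.
#' @export
clamp_proportion <- function(p, n) {
  eps <- 1 / (4 * pmax(n, 1))
  pmin(pmax(p, eps), 1 - eps)
}

# Sampling variance of logit(p) for a binomial proportion: delta method.
logit_sampling_variance <- function(p, n) {
  p <- clamp_proportion(p, n)
  1 / (n * p * (1 - p))
}

# Deterministic substream seeds: one root seed, named substreams, so each
# component can be regenerated independently. Stays below 2^31.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Breastfeeding indicators modelled by the package
#'
#' Six WHO-definition indicators: timely initiation (within 24 hours of
#' birth), the exclusive/predominant/partial composition among children under
#' six months, and continued breastfeeding at 6-11 and 12-23 months.
#'
#' @return Character vector of indicator codes.
#' @export
bf_indicators <- function() {
  c("initiation_24h", "exclusive_0_5", "predominant_0_5", "partial_0_5",
    "continued_6_11", "continued_12_23")
}

# Internal modelling targets: the 0-5 month trio is modelled on the nested
# cumulative scale (exclusive) <= (exclusive or predominant) <= (any bf).
bf_model_targets <- function() {
  c("initiation_24h", "cum_exclusive", "cum_excl_pred", "cum_any_0_5",
    "continued_6_11", "continued_12_23")
}

bf_covariate_names <- function() {
  c("maternal_education", "log_gdp_pc", "child_underweight", "tfr")
}
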
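# Density- and frequency-dependent vital rates, evaluated at the current
# population state.

logistic <- function(x) stats::plogis(x)

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Summarize a population vector for rate evaluation
#'
#' Computes the aggregates that the density-dependent rate functions need:
#' per-state female totals and the intact/sterile split of adult
#' free-roaming cats.
#'
#' @param n A 16-entry population vector in stage-major order (see
#'   [population_vector()]).
#' @return A list with per-state totals (`owned`, `shelter`, `freeroaming`,
#'   `feral`), `intact_adult_freeroaming`, `sterile_adult_freeroaming`, and
#'   `prop_intact` (0 when no adult free-roaming cats are present).
#' @export
population_snapshot <- function(n) {
  n <- as_population_vector(n)
  idx <- function(state) 4L * (seq_len(4L) - 1L) + state
  intact <- n[pv_index(stage = 2, state = 3)]
  sterile <- n[pv_index(stage = 4, state = 3)]
  tot <- intact + sterile
  list(
    owned = sum(n[idx(1L)]),
    shelter = sum(n[idx(2L)]),
    freeroaming = sum(n[idx(3L)]),
    feral = sum(n[idx(4L)]),
    intact_adult_freeroaming = intact,
    sterile_adult_freeroaming = sterile,
    prop_intact = if (tot > 0) intact / tot else 0
  )
}

# Core exponential-decay survival family, by variant. N and K are female
# counts; area in hectares (used only by the "per_hectare" per-density forms).
# `a` is the curve's intercept; `decay_intercept` is the adult intercept the
# calibrated decay rate is solved from (juvenile curves share the adult
# decay, rescaled to their own intercept).
unowned_adult_curve <- function(N, K, a, params, state, decay_intercept = a) {
  if (K <= 0) stop("carrying capacity must be positive")
  if (N < 0) stop("abundance must be nonnegative")
  dd <- params$dd
  switch(dd$variant,
    calibrated = {
      # decay solved so adult survival(K) = 0.5 exactly and survival(0) = a
      if (a <= 0 || decay_intercept <= 0) return(0)
      b <- log(decay_intercept / 0.5)
      a * exp(-b * (N / K))
    },
    composite = {
      if (state == "freeroaming") {
        cf <- dd$composite_free
        a * exp(-cf[["b"]] * exp(cf[["c"]] * (N / K)))
      } else {
        cf <- dd$composite_feral
        a * exp(-cf[["b"]] * exp(cf[["c"]] * (N / K)))
      }
    },
    per_hectare = {
      dens <- N / params$city$area_ha
      if (dd$density_interpretation == "total") dens <- 2 * dens
      b <- if (state == "freeroaming") dd$per_hectare[["b_freeroaming"]]
           else dd$per_hectare[["b_feral"]]
      a * exp(-b * dens)
    },
    stop("unknown density-dependence variant: ", dd$variant)
  )
}

#' Annual survival of adult unowned cats
#'
#' Adult survival of free-roaming and feral cats declines with density. The
#' default `"calibrated"` variant uses exponential decay
#' \eqn{a e^{-b N/K}} with the decay rate solved from the calibration
#' constraint that annual adult survival equals 0.5 at carrying capacity;
#' `a` is the survival as density approaches zero (0.82 free-roaming, 0.65
#' feral). The `"composite"` and `"per_hectare"` variants evaluate the published
#' composite and per-hectare forms verbatim.
#'
#' @param N Female abundance of the state.
#' @param K Female carrying capacity of the state.
#' @param params A `cat_params` object (carries the variant and
#'   coefficients).
#' @param state `"freeroaming"` or `"feral"`.
#' @return Annual survival probability, clamped to [0, 1].
#' @export
adult_unowned_survival <- function(N, K, params, state = c("freeroaming", "feral")) {
  state <- match.arg(state)
  a <- if (state == "freeroaming") params$surv_max_freeroaming
       else params$surv_max_feral
  clamp01(unowned_adult_curve(N, K, a, params, state))
}

#' Annual survival of juvenile free-roaming cats
#'
#' First 6 months: a frequency-dependent linear function of the proportion
#' of adult free-roaming cats that are intact (aggression in intact
#' populations lowers kitten survival), \eqn{-0.587 p + 0.907}, clamped to
#' [0, 1]. Second 6 months: survival at the adult rate — by default the
#' square root of annual adult survival (6 months at the adult rate);
#' alternatively the full annual adult rate (`juvenile_rule =
#' "full_adult"`).
#'
#' @param prop_intact Proportion of adult free-roaming cats that are intact.
#' @param adult_annual Annual adult free-roaming survival at the same
#'   population state.
#' @param params A `cat_params` object.
#' @return Annual juvenile survival probability in [0, 1].
#' @export
juvenile_freeroaming_survival <- function(prop_intact, adult_annual, params) {
  stopifnot(prop_intact >= 0, prop_intact <= 1,
            adult_annual >= 0, adult_annual <= 1)
  six_month <- clamp01(params$juvfree_slope * prop_intact +
                         params$juvfree_intercept)
  second_half <- switch(params$dd$juvenile_rule,
                        sqrt_adult = sqrt(adult_annual),
                        full_adult = adult_annual,
                        stop("unknown juvenile rule: ", params$dd$juvenile_rule))
  clamp01(six_month * second_half)
}

#' Annual survival of juvenile feral cats
#'
#' The 6-month survival of feral kittens follows the adult density-dependent
#' decay curve rescaled to an intercept of 0.25, composed with the
#' second-half-year adult factor under the selected juvenile rule.
#'
#' @param N Female feral abundance.
#' @param K Female feral carrying capacity.
#' @param params A `cat_params` object.
#' @return Annual juvenile survival probability in [0, 1].
#' @export
juvenile_feral_survival <- function(N, K, params) {
  a0 <- params$surv_max_feral_juvenile
  six_month <- clamp01(unowned_adult_curve(N, K, a0, params, "feral",
                                           decay_intercept = params$surv_max_feral))
  adult <- adult_unowned_survival(N, K, params, "feral")
  second_half <- switch(params$dd$juvenile_rule,
                        sqrt_adult = sqrt(adult),
                        full_adult = adult)
  clamp01(six_month * second_half)
}

#' Shelter adoption rate
#'
#' The annual proportion of shelter cats adopted declines with the owned
#' population relative to its carrying capacity as a 2-term logistic,
#' \eqn{\mathrm{logit}^{-1}(a N_o/K_o + b)} with a = -12, b = 12, so that
#' half of shelter cats are adopted when the owned population is at
#' carrying capacity.
#'
#' @param N_owned Female owned abundance.
#' @param K_owned Female owned carrying capacity.
#' @param params A `cat_params` object.
#' @return Adoption probability in (0, 1).
#' @export
shelter_adoption_rate <- function(N_owned, K_owned, params) {
  if (K_owned <= 0) stop("owned carrying capacity must be positive")
  logistic(params$adoption_slope * (N_owned / K_owned) +
             params$adoption_intercept)
}

#' Off-street adoption rate of free-roaming cats
#'
#' The product of (i) the proportion of owners seeking to adopt a stray,
#' which decays exponentially in the owned population relative to carrying
#' capacity, and (ii) the availability of adoptable free-roaming cats, a
#' logistic function of free-roaming abundance relative to carrying
#' capacity.
#'
#' @param N_owned,K_owned Female owned abundance and carrying capacity.
#' @param N_free,K_free Female free-roaming abundance and carrying capacity.
#' @param params A `cat_params` object.
#' @return Off-street adoption probability in [0, 1).
#' @export
offstreet_adoption_rate <- function(N_owned, K_owned, N_free, K_free, params) {
  if (K_owned <= 0 || K_free <= 0) stop("carrying capacities must be positive")
  seeking <- exp(-params$offstreet_decay * (N_owned / K_owned))
  available <- logistic(params$availability_slope * (N_free / K_free) +
                          params$availability_intercept)
  clamp01(seeking * available)
}

#' Surrender rate of free-roaming cats to shelters
#'
#' The product of two logistic functions of free-roaming abundance relative
#' to carrying capacity: the propensity to surrender (shallow, increasing)
#' and the availability term shared with off-street adoption. Monotone
#' increasing in abundance.
#'
#' @param N_free,K_free Female free-roaming abundance and carrying capacity.
#' @param params A `cat_params` object.
#' @return Surrender probability in [0, 1).
#' @export
surrender_rate <- function(N_free, K_free, params) {
  if (K_free <= 0) stop("free-roaming carrying capacity must be positive")
  x <- N_free / K_free
  propensity <- logistic(params$surrender_slope * x +
                           params$surrender_intercept)
  available <- logistic(params$availability_slope * x +
                          params$availability_intercept)
  clamp01(propensity * available)
}
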
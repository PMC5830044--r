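# City-level parameterization: carrying capacities, breeding season,
# derived transition constants, and assembly of the full parameter set.

#' Describe a city for the cat population model
#'
#' The model needs only three census-derived inputs: latitude (which drives
#' breeding season length), number of dwellings (which drives the owned-cat
#' carrying capacity), and urban area in hectares (which, together with
#' equilibrium unowned-cat densities, drives the free-roaming and feral
#' carrying capacities). Everything else has literature-based defaults that
#' can be overridden.
#'
#' @param latitude Decimal degrees north, in (-90, 90).
#' @param dwellings Number of human dwellings in the urban area.
#' @param area_ha Urban area in hectares.
#' @param freeroaming_density Equilibrium density of free-roaming cats
#'   (both sexes, cats/ha). Default is the geometric mean of published
#'   density records, `exp(-0.752664)` = 0.4711098.
#' @param feral_density Equilibrium density of feral cats (cats/ha).
#'   Default `exp(-2.536883)` = 0.07911264.
#' @param shelter_capacity Number of shelter spaces for cats (default 187,
#'   the mean capacity of reporting Canadian humane societies).
#' @param mean_length_of_stay Mean shelter length of stay in days
#'   (default 30).
#' @param prop_dwellings_with_cats Proportion of dwellings owning at least
#'   one cat (Canadian polling default 0.377).
#' @param cats_per_dwelling Mean cats per cat-owning dwelling (default 1.85).
#' @return An object of class `city_inputs`.
#' @examples
#' guelph <- city_inputs(latitude = 43.55, dwellings = 52620, area_ha = 7885)
#' @export
city_inputs <- function(latitude, dwellings, area_ha,
                        freeroaming_density = exp(-0.752664),
                        feral_density = exp(-2.536883),
                        shelter_capacity = 187,
                        mean_length_of_stay = 30,
                        prop_dwellings_with_cats = 0.377,
                        cats_per_dwelling = 1.85) {
  stopifnot(is.numeric(latitude), length(latitude) == 1L, is.finite(latitude))
  if (latitude <= -90 || latitude >= 90)
    stop("latitude must lie strictly between -90 and 90 degrees")
  if (!is.finite(dwellings) || dwellings < 0)
    stop("dwellings must be a nonnegative count")
  if (!is.finite(area_ha) || area_ha <= 0)
    stop("area_ha must be positive")
  if (freeroaming_density <= 0 || feral_density <= 0)
    stop("unowned cat densities must be positive (cats/ha)")
  if (shelter_capacity < 0)
    stop("shelter_capacity must be nonnegative")
  if (mean_length_of_stay <= 0)
    stop("mean_length_of_stay must be positive (days)")
  if (prop_dwellings_with_cats < 0 || prop_dwellings_with_cats > 1)
    stop("prop_dwellings_with_cats must be a probability")
  if (cats_per_dwelling < 0)
    stop("cats_per_dwelling must be nonnegative")
  structure(list(
    latitude = latitude,
    dwellings = dwellings,
    area_ha = area_ha,
    freeroaming_density = freeroaming_density,
    feral_density = feral_density,
    shelter_capacity = shelter_capacity,
    mean_length_of_stay = mean_length_of_stay,
    prop_dwellings_with_cats = prop_dwellings_with_cats,
    cats_per_dwelling = cats_per_dwelling
  ), class = "city_inputs")
}

#' Default breeding-season logistic parameters
#'
#' Breeding season length (days) as a function of latitude follows a
#' 4-parameter logistic fitted to published breeding-season data. The upper
#' asymptote `a` is fixed at 365 days so the season can at most be
#' year-round. `days_per_litter` is the time needed to produce one litter:
#' 65 days gestation plus 84 days to wean.
#'
#' @return A list with elements `a`, `b`, `c`, `d`, `days_per_litter`.
#' @export
breeding_season_params <- function() {
  list(a = 365, b = 170.3539, c = 0.1351, d = 31.8447, days_per_litter = 149)
}

#' Breeding season length from latitude
#'
#' Evaluates the 4-parameter logistic
#' \deqn{y = a + (b - a) / (1 + e^{c (d - x)})}
#' where `x` is latitude. At low latitude the season approaches the
#' year-round maximum `a` = 365 days; at high latitude it approaches `b`.
#'
#' @param latitude Decimal degrees, in (-90, 90).
#' @param params Logistic parameters, see [breeding_season_params()].
#' @return Breeding season length in days.
#' @examples
#' breeding_season_length(43.55) # about 203.6 days
#' @export
breeding_season_length <- function(latitude, params = breeding_season_params()) {
  stopifnot(is.numeric(latitude), all(latitude > -90 & latitude < 90))
  with(params, a + (b - a) / (1 + exp(c * (d - latitude))))
}

#' Litters per female per year
#'
#' One litter takes 149 days (65 days gestation + 84 days weaning), so the
#' maximum number of litters per year is the breeding season length divided
#' by 149.
#'
#' @param season_days Breeding season length in days.
#' @param days_per_litter Days required to produce one litter (default 149).
#' @return Litters per female per year.
#' @export
litters_per_year <- function(season_days, days_per_litter = 149) {
  stopifnot(all(season_days >= 0), days_per_litter > 0)
  season_days / days_per_litter
}

#' Carrying capacity of owned female cats
#'
#' The number of dwellings times the proportion of dwellings with cats times
#' cats per cat-owning dwelling, halved for the female share under a 1:1 sex
#' ratio.
#'
#' @param dwellings Number of dwellings.
#' @param prop_with_cats Proportion of dwellings with one or more cats.
#' @param cats_per_dwelling Mean cats per cat-owning dwelling.
#' @return Female carrying capacity (count).
#' @export
carrying_capacity_owned <- function(dwellings, prop_with_cats = 0.377,
                                    cats_per_dwelling = 1.85) {
  stopifnot(dwellings >= 0, prop_with_cats >= 0, cats_per_dwelling >= 0)
  prop_with_cats * cats_per_dwelling * dwellings / 2
}

#' Annual female shelter carrying capacity
#'
#' Shelter capacity is an annual throughput: the number of spaces times the
#' number of stays that fit in a year (365 / mean length of stay), halved
#' for the female share.
#'
#' @param capacity Number of shelter spaces.
#' @param stay Mean length of stay in days.
#' @return Female annual throughput capacity.
#' @export
carrying_capacity_shelter <- function(capacity = 187, stay = 30) {
  if (stay <= 0) stop("mean length of stay must be positive")
  stopifnot(capacity >= 0)
  capacity * (365 / stay) / 2
}

#' Carrying capacity of unowned female cats
#'
#' Equilibrium density (cats/ha, both sexes) times urban area, halved for
#' the female share. Used for both the free-roaming and the feral state with
#' their respective densities.
#'
#' @param density Cats per hectare (both sexes).
#' @param area_ha Urban area in hectares.
#' @return Female carrying capacity (count).
#' @export
carrying_capacity_unowned <- function(density, area_ha) {
  stopifnot(density > 0, area_ha >= 0)
  density * area_ha / 2
}

#' Annual loss rate of owned cats
#'
#' Cumulative loss of owned cats follows a logarithmic model
#' \eqn{L = a \log(t + 1)} (natural log) calibrated so that 15% of cats are
#' lost over 5 years. The annual probability of loss is the model at t = 1.
#' Only a small fraction of lost cats re-enter the population via shelters
#' (6 of 69 in the source data); the remainder return home on their own, so
#' the shelter-routed loss rate is annual loss times 6/69.
#'
#' @param cumulative_loss Cumulative proportion lost by `horizon_years`
#'   (default 0.15).
#' @param horizon_years Horizon at which `cumulative_loss` applies
#'   (default 5).
#' @param shelter_return_fraction Fraction of lost cats returned via the
#'   shelter system (default 6/69).
#' @return A list with `a` (the log-model coefficient), `annual`
#'   (probability of loss at t = 1), and `l` (the shelter-routed annual loss
#'   probability used in the transition matrix).
#' @export
derive_loss_rate <- function(cumulative_loss = 0.15, horizon_years = 5,
                             shelter_return_fraction = 6 / 69) {
  stopifnot(cumulative_loss >= 0, cumulative_loss <= 1, horizon_years > 0,
            shelter_return_fraction >= 0, shelter_return_fraction <= 1)
  a <- cumulative_loss / log(horizon_years + 1)
  annual <- a * log(2)
  list(a = a, annual = annual, l = annual * shelter_return_fraction)
}

#' Return-to-owner (recovery) rates of shelter cats
#'
#' Recovery of a lost cat from a shelter depends on whether it carries
#' identification and on sterilization status:
#' \deqn{c = y_i i + y_n (1 - i)}
#' with `y_i` the return probability with identification, `y_n` without, and
#' `i` the proportion of lost cats carrying identification. Intact cats are
#' recovered at relative odds `o` = 0.25/0.57 compared to sterilized cats.
#'
#' @param y_id Return-to-owner probability with identification (0.385).
#' @param y_noid Return-to-owner probability without identification (0.018).
#' @param prop_id Proportion of lost cats with identification (0.19).
#' @param odds_intact Relative recovery odds, intact vs sterilized
#'   (0.25/0.57).
#' @return A list with `o`, `c_sterile`, `c_intact`.
#' @export
derive_recovery_rates <- function(y_id = 0.385, y_noid = 0.018,
                                  prop_id = 0.19,
                                  odds_intact = 0.25 / 0.57) {
  stopifnot(y_id >= 0, y_id <= 1, y_noid >= 0, y_noid <= 1,
            prop_id >= 0, prop_id <= 1, odds_intact >= 0)
  c_sterile <- y_id * prop_id + y_noid * (1 - prop_id)
  list(o = odds_intact,
       c_sterile = c_sterile,
       c_intact = odds_intact * c_sterile)
}

#' Decay coefficient of the off-street adoption function
#'
#' The proportion of owners willing to adopt a cat off the street declines
#' with the owned population as \eqn{e^{-a N_o / K_o}}; the coefficient is
#' solved so the proportion equals 0.3 when the owned population is at
#' carrying capacity.
#'
#' @param prop_at_k Owner-seeking proportion at carrying capacity
#'   (default 0.3).
#' @return The decay coefficient `a` (= 1.20397 at the default).
#' @export
derive_offstreet_decay <- function(prop_at_k = 0.3) {
  stopifnot(prop_at_k > 0, prop_at_k <= 1)
  -log(prop_at_k)
}

# Sterilization-rate presets for unowned cats. "table" is the model's
# default input set; "text" is the alternative set quoted in prose (an
# order of magnitude lower for feral cats).
sterilization_presets <- list(
  table = list(freeroaming = c(juvenile = 0.05, adult = 0.125),
               feral = c(juvenile = 0.01, adult = 0.025)),
  text = list(freeroaming = c(juvenile = 0.01, adult = 0.025),
              feral = c(juvenile = 0.001, adult = 0.0025))
)

#' Build the full parameter set for a city
#'
#' Assembles every vital rate and transition constant of the model from the
#' city inputs: carrying capacities for the four states, litters per year
#' from the latitude-driven breeding season, stage- and state-specific
#' survival baselines, fecundities, sterilization rates, and the constant
#' transition probabilities (relinquishment, loss, abandonment,
#' return-to-owner, feral surrender, kittens becoming feral). Any scalar
#' parameter can be overridden by name (see [parameter_names()]).
#'
#' @param city A [city_inputs()] object.
#' @param dd_variant Density-dependence variant for unowned survival, one of
#'   `"calibrated"` (default; exponential decay with the decay rate solved
#'   so adult survival is exactly 0.5 at carrying capacity), `"composite"`
#'   (the published double-exponential composite forms), or `"per_hectare"` (the
#'   published per-hectare density forms).
#' @param juvenile_rule How 6-month juvenile survival of unowned cats is
#'   composed into an annual rate: `"sqrt_adult"` (default; second half-year
#'   at the square root of annual adult survival) or `"full_adult"`
#'   (multiplied by full annual adult survival).
#' @param sterilization_preset `"table"` (default) or `"text"`, the two
#'   published sets of unowned-cat sterilization rates.
#' @param density_interpretation For the `"per_hectare"` variant only: whether
#'   the per-hectare density in the survival curves counts `"female"`
#'   (default, model units) or `"total"` cats.
#' @param offspring_sterilization How newborn kittens are split between the
#'   intact and sterile juvenile stages: `"kitten_rate"` (default; all
#'   kittens face the juvenile sterilization rate in their first year) or
#'   `"parent_stage"` (kittens face their mother's stage-specific rate).
#'   See [build_demography_block()].
#' @param overrides Named list of scalar parameter overrides; names must be
#'   in [parameter_names()] (unknown names are an error).
#' @return An object of class `cat_params`; its `K` element holds the
#'   carrying capacities (class `carrying_capacities`).
#' @examples
#' p <- build_parameter_set(city_inputs(43.55, 52620, 7885))
#' p$K$owned     # female owned-cat carrying capacity
#' p$litters     # litters per female per year
#' @export
build_parameter_set <- function(city,
                                dd_variant = c("calibrated", "composite", "per_hectare"),
                                juvenile_rule = c("sqrt_adult", "full_adult"),
                                sterilization_preset = c("table", "text"),
                                density_interpretation = c("female", "total"),
                                offspring_sterilization = c("kitten_rate",
                                                            "parent_stage"),
                                overrides = list()) {
  stopifnot(inherits(city, "city_inputs"))
  dd_variant <- match.arg(dd_variant)
  juvenile_rule <- match.arg(juvenile_rule)
  sterilization_preset <- match.arg(sterilization_preset)
  density_interpretation <- match.arg(density_interpretation)
  offspring_sterilization <- match.arg(offspring_sterilization)

  season <- breeding_season_length(city$latitude)
  k <- litters_per_year(season)
  loss <- derive_loss_rate()
  rec <- derive_recovery_rates()
  ster_un <- sterilization_presets[[sterilization_preset]]

  K <- structure(list(
    owned = carrying_capacity_owned(city$dwellings,
                                    city$prop_dwellings_with_cats,
                                    city$cats_per_dwelling),
    shelter = carrying_capacity_shelter(city$shelter_capacity,
                                        city$mean_length_of_stay),
    freeroaming = carrying_capacity_unowned(city$freeroaming_density,
                                            city$area_ha),
    feral = carrying_capacity_unowned(city$feral_density, city$area_ha)
  ), class = "carrying_capacities")

  params <- structure(list(
    city = city,
    K = K,
    season_days = season,
    litters = k,
    # demographic vital rates ------------------------------------------
    s0_owned = 0.7,
    s1_owned = 0.8,
    s0_shelter_base = 0.7,   # pre-euthanasia survival in shelters
    s1_shelter_base = 0.8,
    euthanasia = 0.519,      # fraction of shelter cats euthanized
    litter_size_owned = 3.8,        # kittens/litter, both sexes
    litter_size_freeroaming = 3.6,
    litter_size_feral = 3.5,
    juvenile_breeding_fraction = (365 - 212) / 365, # pre-pubertal discount
    n0_owned = 0.7,
    n1_owned = 0.1,
    n0_shelter = 1,
    n1_shelter = 1,
    n0_freeroaming = unname(ster_un$freeroaming["juvenile"]),
    n1_freeroaming = unname(ster_un$freeroaming["adult"]),
    n0_feral = unname(ster_un$feral["juvenile"]),
    n1_feral = unname(ster_un$feral["adult"]),
    # constant transition probabilities --------------------------------
    relinquishment = 0.012,
    loss = 0.0049,           # shelter-routed; see derive_loss_rate()
    abandonment = 0.05,
    kitten_feral = 0.05,     # free-roaming kittens becoming feral
    feral_surrender = 1e-4,
    recovery_intact = rec$c_intact,
    recovery_sterile = rec$c_sterile,
    # density-dependence curve coefficients ----------------------------
    adoption_slope = -12,
    adoption_intercept = 12,
    offstreet_decay = derive_offstreet_decay(),
    availability_slope = 3.87637,
    availability_intercept = -5,
    surrender_slope = 0.1671,
    surrender_intercept = -0.5858,
    surv_max_freeroaming = 0.82,   # adult survival as density -> 0
    surv_max_feral = 0.65,
    surv_max_feral_juvenile = 0.25, # 6-month intercept for feral kittens
    juvfree_slope = -0.587,  # frequency dependence on proportion intact
    juvfree_intercept = 0.907,
    dd = list(variant = dd_variant,
              juvenile_rule = juvenile_rule,
              density_interpretation = density_interpretation,
              offspring_sterilization = offspring_sterilization,
              # published curve coefficients, used verbatim by variant
              composite_free = c(b = 0.476, c = 0.0482),
              composite_feral = c(b = 3.812, c = -2.676),
              per_hectare = c(b_freeroaming = 0.475669, b_feral = 10.0719))
  ), class = "cat_params")

  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("overrides must be a fully named list")
    unknown <- setdiff(nm, parameter_names())
    if (length(unknown))
      stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
    for (n in nm) params[[n]] <- overrides[[n]]
  }
  validate_parameter_set(params)
  params
}

# Names of scalar lower-level parameters: both the override surface of
# build_parameter_set() and the theta vector of the elasticity analysis.

#' Names of the lower-level model parameters
#'
#' These scalar rates and curve coefficients form the parameter vector of
#' the perturbation analysis and are the valid names for `overrides` in
#' [build_parameter_set()].
#'
#' @return Character vector of parameter names.
#' @export
parameter_names <- function() {
  c("s0_owned", "s1_owned", "s0_shelter_base", "s1_shelter_base",
    "euthanasia",
    "litter_size_owned", "litter_size_freeroaming", "litter_size_feral",
    "juvenile_breeding_fraction",
    "n0_owned", "n1_owned", "n0_shelter", "n1_shelter",
    "n0_freeroaming", "n1_freeroaming", "n0_feral", "n1_feral",
    "relinquishment", "loss", "abandonment", "kitten_feral",
    "feral_surrender", "recovery_intact", "recovery_sterile",
    "adoption_slope", "adoption_intercept",
    "offstreet_decay", "availability_slope", "availability_intercept",
    "surrender_slope", "surrender_intercept",
    "surv_max_freeroaming", "surv_max_feral", "surv_max_feral_juvenile",
    "juvfree_slope", "juvfree_intercept")
}

validate_parameter_set <- function(params) {
  probs <- c("s0_owned", "s1_owned", "s0_shelter_base", "s1_shelter_base",
             "euthanasia", "juvenile_breeding_fraction",
             "n0_owned", "n1_owned", "n0_shelter", "n1_shelter",
             "n0_freeroaming", "n1_freeroaming", "n0_feral", "n1_feral",
             "relinquishment", "loss", "abandonment", "kitten_feral",
             "feral_surrender", "recovery_intact", "recovery_sterile",
             "surv_max_freeroaming", "surv_max_feral",
             "surv_max_feral_juvenile")
  for (p in probs) {
    v <- params[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("parameter '", p, "' must be a probability in [0, 1], got ", v)
  }
  for (p in c("litter_size_owned", "litter_size_freeroaming",
              "litter_size_feral")) {
    if (params[[p]] < 0) stop("litter size '", p, "' must be nonnegative")
  }
  out <- params$relinquishment + params$loss + params$abandonment
  if (out > 1)
    stop("owned-cat outflow (relinquishment + loss + abandonment) exceeds 1")
  invisible(params)
}

# Survival, fecundity and sterilization rates for one state, stage-indexed
# (juvenile, adult). Density-independent pieces only; unowned survival is
# evaluated per population snapshot by the vital-rate functions.
static_rates <- function(params, state) {
  k <- params$litters
  jf <- params$juvenile_breeding_fraction
  switch(state,
    owned = list(
      s0 = params$s0_owned, s1 = params$s1_owned,
      f1 = params$litter_size_owned * k / 2,
      f0 = jf * params$litter_size_owned * k / 2,
      n0 = params$n0_owned, n1 = params$n1_owned),
    shelter = list(
      s0 = params$s0_shelter_base * (1 - params$euthanasia),
      s1 = params$s1_shelter_base * (1 - params$euthanasia),
      f0 = 0, f1 = 0,
      n0 = params$n0_shelter, n1 = params$n1_shelter),
    freeroaming = list(
      s0 = NA_real_, s1 = NA_real_, # density dependent
      f1 = params$litter_size_freeroaming * k / 2,
      f0 = jf * params$litter_size_freeroaming * k / 2,
      n0 = params$n0_freeroaming, n1 = params$n1_freeroaming),
    feral = list(
      s0 = NA_real_, s1 = NA_real_, # density dependent
      f1 = params$litter_size_feral * k / 2,
      f0 = jf * params$litter_size_feral * k / 2,
      n0 = params$n0_feral, n1 = params$n1_feral),
    stop("unknown state: ", state)
  )
}

#' @export
print.cat_params <- function(x, ...) {
  cat("<cat_params>\n")
  cat(sprintf("  city: latitude %.2f, %s dwellings, %s ha\n",
              x$city$latitude, format(x$city$dwellings, big.mark = ","),
              format(x$city$area_ha, big.mark = ",")))
  cat(sprintf("  breeding season: %.1f days (%.3f litters/female/yr)\n",
              x$season_days, x$litters))
  cat(sprintf("  K (females): owned %.0f, shelter %.0f/yr, free-roaming %.0f, feral %.0f\n",
              x$K$owned, x$K$shelter, x$K$freeroaming, x$K$feral))
  cat(sprintf("  density dependence: %s (juvenile rule %s)\n",
              x$dd$variant, x$dd$juvenile_rule))
  invisible(x)
}
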
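# Shared fixtures: cities and parameter sets used across test files.

guelph_city <- function() {
  city_inputs(latitude = 43.55, dwellings = 52620, area_ha = 7885,
              freeroaming_density = 0.787, feral_density = 0.246)
}

guelph_params <- function(...) build_parameter_set(guelph_city(), ...)

# A small town: fast equilibrium solves for property-style tests.
toy_city <- function() {
  city_inputs(latitude = 45, dwellings = 5000, area_ha = 800,
              shelter_capacity = 20)
}

toy_params <- function(...) build_parameter_set(toy_city(), ...)

# Random valid demographic rates for property tests.
random_rates <- function() {
  list(s0 = runif(1), s1 = runif(1), f0 = runif(1, 0, 4), f1 = runif(1, 0, 4),
       n0 = runif(1), n1 = runif(1))
}

# Random nonnegative population vector.
random_population <- function(scale = 1000) {
  population_vector(owned = runif(4, 0, scale), shelter = runif(4, 0, scale),
                    freeroaming = runif(4, 0, scale),
                    feral = runif(4, 0, scale))
}
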
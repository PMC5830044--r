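# Density- and frequency-dependent vital rates.

test_that("calibrated adult survival hits 0.5 at carrying capacity exactly", {
  p <- guelph_params(dd_variant = "calibrated")
  K <- p$K$freeroaming
  expect_equal(adult_unowned_survival(K, K, p, "freeroaming"), 0.5,
               tolerance = 1e-15)
  expect_identical(adult_unowned_survival(0, K, p, "freeroaming"), 0.82)
  Kf <- p$K$feral
  expect_equal(adult_unowned_survival(Kf, Kf, p, "feral"), 0.5,
               tolerance = 1e-15)
  expect_identical(adult_unowned_survival(0, Kf, p, "feral"), 0.65)
})

test_that("published composite survival forms evaluate verbatim", {
  p <- guelph_params(dd_variant = "composite")
  K <- p$K$freeroaming
  # free-roaming composite at carrying capacity is close to the 0.5 target
  expect_equal(adult_unowned_survival(K, K, p, "freeroaming"),
               0.82 * exp(-0.476 * exp(0.0482)), tolerance = 1e-12)
  expect_equal(adult_unowned_survival(K, K, p, "freeroaming"), 0.4976,
               tolerance = 1e-4)
  Kf <- p$K$feral
  expect_equal(adult_unowned_survival(Kf, Kf, p, "feral"),
               0.65 * exp(-3.812 * exp(-2.676)), tolerance = 1e-12)
  # feral juvenile composite at carrying capacity
  p_full <- guelph_params(dd_variant = "composite", juvenile_rule = "full_adult")
  six_month <- 0.25 * exp(-3.812 * exp(-2.676))
  expect_equal(six_month, 0.1923, tolerance = 1e-3)
})

test_that("per-density survival forms use abundance over area", {
  p <- guelph_params(dd_variant = "per_hectare")
  area <- p$city$area_ha
  N <- 2000
  expect_equal(adult_unowned_survival(N, p$K$freeroaming, p, "freeroaming"),
               0.82 * exp(-0.475669 * N / area), tolerance = 1e-12)
  expect_equal(adult_unowned_survival(N, p$K$feral, p, "feral"),
               0.65 * exp(-10.0719 * N / area), tolerance = 1e-12)
  p_tot <- guelph_params(dd_variant = "per_hectare",
                         density_interpretation = "total")
  expect_equal(adult_unowned_survival(N, p$K$freeroaming, p_tot, "freeroaming"),
               0.82 * exp(-0.475669 * 2 * N / area), tolerance = 1e-12)
})

test_that("juvenile free-roaming survival is frequency dependent", {
  p <- guelph_params()
  # six-month component at the intercept and at full intactness
  expect_equal(juvenile_freeroaming_survival(0, 1, p), 0.907,
               tolerance = 1e-12)
  expect_equal(juvenile_freeroaming_survival(1, 1, p), 0.32,
               tolerance = 1e-12)
  # composition with the adult rate: sqrt under the default rule
  expect_equal(juvenile_freeroaming_survival(0.5, 0.64, p),
               (0.907 - 0.587 * 0.5) * 0.8, tolerance = 1e-12)
  expect_equal(juvenile_freeroaming_survival(0.5, 0.64, p), 0.4908,
               tolerance = 1e-4)
  p_full <- guelph_params(juvenile_rule = "full_adult")
  expect_equal(juvenile_freeroaming_survival(0.5, 0.64, p_full),
               (0.907 - 0.587 * 0.5) * 0.64, tolerance = 1e-12)
})

test_that("juvenile feral survival rescales the adult curve to 0.25", {
  p <- guelph_params(dd_variant = "calibrated", juvenile_rule = "full_adult")
  K <- p$K$feral
  # at K the adult curve is 0.5, the juvenile intercept rescaling gives
  # 0.25 * (0.5 / 0.65) for the first six months, then the adult factor
  expect_equal(juvenile_feral_survival(K, K, p), 0.25 * (0.5 / 0.65) * 0.5,
               tolerance = 1e-12)
  expect_equal(juvenile_feral_survival(K, K, p), 0.0962, tolerance = 1e-3)
  p_sqrt <- guelph_params(dd_variant = "calibrated")
  expect_equal(juvenile_feral_survival(0, K, p_sqrt),
               0.25 * sqrt(0.65), tolerance = 1e-12)
})

test_that("shelter adoption follows the two-term logistic in N/K", {
  p <- guelph_params()
  K <- p$K$owned
  expect_equal(shelter_adoption_rate(K, K, p), 0.5, tolerance = 1e-12)
  expect_equal(shelter_adoption_rate(0, K, p), plogis(12), tolerance = 1e-12)
  expect_equal(shelter_adoption_rate(0, K, p), 0.999994, tolerance = 1e-6)
  expect_equal(shelter_adoption_rate(2 * K, K, p), plogis(-12),
               tolerance = 1e-12)
  expect_equal(shelter_adoption_rate(2 * K, K, p), 6.1e-6, tolerance = 1e-2)
  # strictly decreasing in the owned population
  Ns <- seq(0, 3 * K, length.out = 50)
  d <- vapply(Ns, shelter_adoption_rate, numeric(1), K_owned = K, params = p)
  expect_true(all(diff(d) < 0))
  expect_error(shelter_adoption_rate(100, 0, p), "positive")
})

test_that("off-street adoption is the product of seeking and availability", {
  p <- guelph_params()
  Ko <- p$K$owned; Kf <- p$K$freeroaming
  expect_equal(offstreet_adoption_rate(Ko, Ko, Kf, Kf, p),
               0.3 * plogis(3.87637 - 5), tolerance = 1e-5)
  expect_equal(offstreet_adoption_rate(Ko, Ko, Kf, Kf, p), 0.0736,
               tolerance = 1e-3)
  expect_equal(offstreet_adoption_rate(Ko, Ko, 0, Kf, p),
               0.3 * plogis(-5), tolerance = 1e-5)
  expect_equal(offstreet_adoption_rate(Ko, Ko, 0, Kf, p), 0.00201,
               tolerance = 1e-2)
  # vanishes as the owned population grows without bound
  expect_lt(offstreet_adoption_rate(50 * Ko, Ko, Kf, Kf, p), 1e-20)
  expect_error(offstreet_adoption_rate(1, 0, 1, 1, p), "positive")
})

test_that("surrender is the product of two increasing logistics", {
  p <- guelph_params()
  Kf <- p$K$freeroaming
  expect_equal(surrender_rate(Kf, Kf, p),
               plogis(0.1671 - 0.5858) * plogis(3.87637 - 5),
               tolerance = 1e-12)
  expect_equal(surrender_rate(Kf, Kf, p), 0.0974, tolerance = 1e-3)
  expect_equal(surrender_rate(0, Kf, p), plogis(-0.5858) * plogis(-5),
               tolerance = 1e-12)
  expect_equal(surrender_rate(0, Kf, p), 0.00239, tolerance = 1e-2)
  # monotone increasing in free-roaming abundance
  Ns <- seq(0, 4 * Kf, length.out = 60)
  s <- vapply(Ns, surrender_rate, numeric(1), K_free = Kf, params = p)
  expect_true(all(diff(s) > 0))
  expect_gt(surrender_rate(2 * Kf, Kf, p), surrender_rate(Kf, Kf, p))
})

test_that("all rates stay in [0, 1] and decay monotonically where claimed", {
  set.seed(42)
  for (variant in c("calibrated", "composite", "per_hectare")) {
    p <- guelph_params(dd_variant = variant)
    Ns <- c(0, 10^runif(40, 0, 5))
    for (state in c("freeroaming", "feral")) {
      K <- p$K[[state]]
      s <- vapply(Ns, adult_unowned_survival, numeric(1), K = K, params = p,
                  state = state)
      expect_true(all(s >= 0 & s <= 1))
    }
    # the decay families are non-increasing in N (the printed feral
    # composite form increases with N and is exempt by construction)
    Ngrid <- seq(0, 5 * p$K$freeroaming, length.out = 100)
    sf <- vapply(Ngrid, adult_unowned_survival, numeric(1),
                 K = p$K$freeroaming, params = p, state = "freeroaming")
    if (variant != "composite") expect_true(all(diff(sf) <= 0))
  }
  # frequency-dependent juvenile survival clamps at the boundaries
  p <- guelph_params(overrides = list(juvfree_intercept = 0.2))
  expect_identical(juvenile_freeroaming_survival(1, 1, p), 0)
})
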
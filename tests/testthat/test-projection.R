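# Vec-permutation assembly, projection, and the equilibrium solver.

test_that("vec-permutation matrix rearranges stage-major to state-major", {
  expect_identical(vec_permutation_matrix(1, 1), matrix(1, 1, 1))
  # brute-force 2x2 case: (n11, n12, n21, n22) -> (n11, n21, n12, n22)
  K22 <- vec_permutation_matrix(2, 2)
  expect_equal(as.numeric(K22 %*% c(11, 12, 21, 22)), c(11, 21, 12, 22))
  # orthogonal permutation with exactly one 1 per row and column
  for (dims in list(c(4, 4), c(2, 3), c(3, 5))) {
    K <- vec_permutation_matrix(dims[1], dims[2])
    expect_equal(K %*% t(K), diag(prod(dims)))
    expect_true(all(K %in% c(0, 1)))
    expect_true(all(rowSums(K) == 1) && all(colSums(K) == 1))
  }
})

test_that("demography block matches direct symbol substitution", {
  B <- build_demography_block(s0 = 0.5, s1 = 0.5, f0 = 0, f1 = 2,
                              n0 = 0, n1 = 0)
  expected <- rbind(c(0, 1, 0, 0),
                    c(0.5, 0.5, 0, 0),
                    c(0, 0, 0, 0),
                    c(0, 0, 0.5, 0.5))
  expect_equal(unname(B), expected)
  # full sterilization: no intact flow survives
  B1 <- build_demography_block(0.6, 0.7, 1, 2, 1, 1)
  expect_true(all(B1[1:2, ] == 0))
  expect_true(all(B1[3:4, 1:2] > 0))
})

test_that("demography column sums match their closed forms", {
  set.seed(101)
  for (os in c("kitten_rate", "parent_stage")) {
    for (i in 1:200) {
      r <- random_rates()
      B <- build_demography_block(r$s0, r$s1, r$f0, r$f1, r$n0, r$n1,
                                  offspring_sterilization = os)
      expect_equal(unname(colSums(B)),
                   c(r$s0 * (1 + r$f0), r$s1 * (1 + r$f1), r$s0, r$s1),
                   tolerance = 1e-12)
      expect_true(all(B >= 0))
    }
  }
})

test_that("offspring sterilization rule splits kittens as documented", {
  # kitten-rate: all newborns face n0; parent-stage: mother's rate
  Bk <- build_demography_block(0.7, 0.8, 1, 2, 0.7, 0.1, "kitten_rate")
  Bp <- build_demography_block(0.7, 0.8, 1, 2, 0.7, 0.1, "parent_stage")
  expect_equal(Bk[1, 2], 0.8 * 2 * 0.3)
  expect_equal(Bk[3, 2], 0.8 * 2 * 0.7)
  expect_equal(Bp[1, 2], 0.8 * 2 * 0.9)
  expect_equal(Bp[3, 2], 0.8 * 2 * 0.1)
  expect_equal(Bk[, 1], Bp[, 1]) # juvenile-born kittens identical
})

test_that("transition blocks are column-stochastic with documented zeros", {
  p <- guelph_params()
  snap <- population_snapshot(default_initial_population())
  for (stage in 1:4) {
    M <- build_transition_block(stage, p, snap)
    expect_equal(unname(colSums(M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    # kittens becoming feral applies to juvenile stages only
    if (stage %in% c(2, 4)) expect_identical(M["feral", "freeroaming"], 0)
    else expect_gt(M["feral", "freeroaming"], 0)
    # nothing leaves feral except surrender to shelters
    expect_identical(M["owned", "feral"], 0)
    expect_identical(M["freeroaming", "feral"], 0)
  }
  # recovery differs by reproductive stage (evaluated away from the
  # adoption saturation regime, with the owned population at capacity)
  snap_eq <- population_snapshot(population_vector(
    owned = rep(p$K$owned / 4, 4), shelter = rep(100, 4),
    freeroaming = rep(p$K$freeroaming / 4, 4),
    feral = rep(p$K$feral / 4, 4)))
  M1 <- build_transition_block(1, p, snap_eq)
  M3 <- build_transition_block(3, p, snap_eq)
  d1 <- M1["owned", "shelter"] # d + c_intact
  d3 <- M3["owned", "shelter"] # d + c_sterile
  expect_equal(d3 - d1, p$recovery_sterile - p$recovery_intact,
               tolerance = 1e-12)
})

test_that("near-zero transitions yield a near-identity block", {
  p <- guelph_params(overrides = list(
    relinquishment = 0, loss = 0, abandonment = 0, kitten_feral = 0,
    feral_surrender = 0, recovery_intact = 0, recovery_sterile = 0,
    adoption_intercept = -50, availability_intercept = -50))
  snap <- population_snapshot(default_initial_population())
  for (stage in 1:4) {
    M <- build_transition_block(stage, p, snap)
    expect_equal(unname(M), diag(4), tolerance = 1e-15)
  }
})

test_that("column sums survive randomized parameters and states", {
  set.seed(202)
  for (i in 1:200) {
    ov <- list(relinquishment = runif(1, 0, 0.3),
               loss = runif(1, 0, 0.3),
               abandonment = runif(1, 0, 0.3),
               kitten_feral = runif(1),
               feral_surrender = runif(1),
               recovery_intact = runif(1, 0, 0.5),
               recovery_sterile = runif(1, 0, 0.5))
    p <- try(guelph_params(overrides = ov), silent = TRUE)
    if (inherits(p, "try-error")) next # invalid outflow combinations
    snap <- population_snapshot(random_population(10^runif(1, 1, 5)))
    for (stage in 1:4) {
      M <- build_transition_block(stage, p, snap)
      expect_equal(unname(colSums(M)), rep(1, 4), tolerance = 1e-9)
      expect_true(all(M >= 0))
    }
  }
})

test_that("projection matrix assembles demography before movement", {
  p <- guelph_params()
  snap <- population_snapshot(default_initial_population())
  A <- assemble_projection(p, snap)
  expect_true(all(A >= 0))
  expect_identical(dim(A), c(16L, 16L))
  # with near-identity movement the states decouple: the owned block of A
  # reproduces the owned demography block alone
  p_id <- guelph_params(overrides = list(
    relinquishment = 0, loss = 0, abandonment = 0, kitten_feral = 0,
    feral_surrender = 0, recovery_intact = 0, recovery_sterile = 0,
    adoption_intercept = -50, availability_intercept = -50))
  A_id <- assemble_projection(p_id, snap)
  B_owned <- urbancats:::state_demography_block("owned", p_id, snap)
  idx <- pv_index(1:4, 1)
  expect_equal(A_id[idx, idx], unname(B_owned), tolerance = 1e-12)
  # off-diagonal state coupling vanishes
  expect_equal(sum(A_id[idx, -idx]), 0, tolerance = 1e-12)
})

test_that("projecting matches brute-force row-by-row dot products", {
  p <- guelph_params()
  n <- as.numeric(default_initial_population())
  A <- assemble_projection(p, population_snapshot(n))
  manual <- numeric(16)
  for (i in 1:16) {
    acc <- 0
    for (j in 1:16) acc <- acc + A[i, j] * n[j]
    manual[i] <- acc
  }
  expect_equal(project_population(n, p), manual, tolerance = 1e-12)
})

test_that("extinction is absorbing and density dependence breaks scaling", {
  p <- guelph_params()
  expect_equal(project_population(rep(0, 16), p), rep(0, 16))
  n <- as.numeric(default_initial_population())
  expect_false(isTRUE(all.equal(project_population(2 * n, p),
                                2 * project_population(n, p))))
})

test_that("equilibrium is a fixed point independent of the start vector", {
  p <- guelph_params()
  eq <- solve_equilibrium(p)
  expect_true(eq$converged)
  expect_lte(eq$iterations, 1200)
  # fixed-point residual below tolerance
  n_star <- as.numeric(eq$n)
  resid <- max(abs(project_population(n_star, p) - n_star)) / max(n_star)
  expect_lt(resid, eq$tol * 10)
  # a different positive start reaches the same equilibrium
  n_alt <- population_vector(owned = rep(5000, 4), shelter = rep(50, 4),
                             freeroaming = rep(10, 4), feral = rep(500, 4))
  eq2 <- solve_equilibrium(p, n0 = n_alt)
  expect_true(eq2$converged)
  expect_equal(as.numeric(eq2$n), n_star, tolerance = 1e-6)
  # doubled totals are twice the female totals and the standing total
  # excludes the shelter flow-through
  expect_equal(unname(eq$totals[1:4]), unname(2 * eq$female_totals))
  expect_equal(eq$totals[["total"]],
               eq$totals[["owned"]] + eq$totals[["freeroaming"]] +
                 eq$totals[["feral"]])
})

test_that("zero survival collapses to extinction within two iterations", {
  p <- guelph_params(overrides = list(
    s0_owned = 0, s1_owned = 0, s0_shelter_base = 0, s1_shelter_base = 0,
    surv_max_freeroaming = 0, surv_max_feral = 0,
    surv_max_feral_juvenile = 0, juvfree_intercept = 0))
  eq <- solve_equilibrium(p)
  expect_true(eq$converged)
  expect_lte(eq$iterations, 2)
  expect_equal(as.numeric(eq$n), rep(0, 16))
})

test_that("non-convergence is reported with a diagnostic, not hidden", {
  # a compact near-equatorial city under the composite survival forms
  city <- city_inputs(21.3, 52620, 2590)
  p <- build_parameter_set(city, dd_variant = "composite")
  eq <- solve_equilibrium(p, max_iter = 400)
  expect_false(eq$converged)
  expect_equal(eq$iterations, 400)
  expect_true(eq$diagnostic != "converged")
  expect_output(print(eq), "NOT converged")
})

test_that("trajectories are recorded when requested", {
  p <- toy_params()
  eq <- solve_equilibrium(p, keep_trajectory = TRUE)
  expect_identical(nrow(eq$trajectory), eq$iterations + 1L)
  expect_equal(eq$trajectory[1, ], as.numeric(default_initial_population()),
               ignore_attr = TRUE)
  expect_equal(eq$trajectory[nrow(eq$trajectory), ], as.numeric(eq$n),
               ignore_attr = TRUE)
})
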
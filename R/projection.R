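# Vec-permutation assembly of the 16x16 annual projection matrix,
# projection, and the density-dependent equilibrium solver.

# Stage/state labels. Stage-major ordering: entry (stage i, state j) sits at
# position (i - 1) * 4 + j.
CAT_STAGES <- c("intact_juvenile", "intact_adult",
                "sterile_juvenile", "sterile_adult")
CAT_STATES <- c("owned", "shelter", "freeroaming", "feral")

#' Index into the stage-major population vector
#'
#' @param stage Stage index 1-4 (intact juvenile, intact adult, sterile
#'   juvenile, sterile adult).
#' @param state State index 1-4 (owned, shelter, free-roaming, feral).
#' @return Position(s) in the 16-entry stage-major vector.
#' @export
pv_index <- function(stage, state) {
  stopifnot(all(stage %in% 1:4), all(state %in% 1:4))
  4L * (stage - 1L) + state
}

#' Construct a population vector
#'
#' Builds the 16-entry female population vector in stage-major order (all
#' states for stage 1, then stage 2, ...). Input is a 4x4 matrix or
#' per-state vectors of the 4 stage abundances.
#'
#' @param owned,shelter,freeroaming,feral Length-4 nonnegative vectors of
#'   female counts in stage order (intact juvenile, intact adult, sterile
#'   juvenile, sterile adult).
#' @return A named numeric vector of length 16, class `population_vector`.
#' @examples
#' # the default initial condition of the model
#' n0 <- default_initial_population()
#' matrix(n0, 4, 4, byrow = TRUE,
#'        dimnames = list(c("ij", "ia", "sj", "sa"),
#'                        c("owned", "shelter", "free", "feral")))
#' @export
population_vector <- function(owned, shelter, freeroaming, feral) {
  m <- cbind(owned, shelter, freeroaming, feral)
  stopifnot(nrow(m) == 4L, all(is.finite(m)), all(m >= 0))
  n <- as.numeric(t(m))
  names(n) <- paste(rep(CAT_STAGES, each = 4L), rep(CAT_STATES, 4L),
                    sep = ".")
  class(n) <- "population_vector"
  n
}

as_population_vector <- function(n) {
  if (inherits(n, "population_vector")) return(unclass(n))
  n <- as.numeric(n)
  if (length(n) != 16L) stop("population vector must have 16 entries")
  if (any(!is.finite(n)) || any(n < 0))
    stop("population vector entries must be finite and nonnegative")
  n
}

#' Default initial population
#'
#' The starting vector used for all equilibrium runs: 100 female cats in
#' each owned stage, none in shelters, 300 in each free-roaming stage, and
#' 40 in each feral stage.
#'
#' @return A `population_vector`.
#' @export
default_initial_population <- function() {
  population_vector(owned = rep(100, 4), shelter = rep(0, 4),
                    freeroaming = rep(300, 4), feral = rep(40, 4))
}

#' Vec-permutation (commutation) matrix
#'
#' Returns the (s r) x (s r) 0/1 permutation matrix that maps the
#' stage-major population vector (states nested within stages) to the
#' state-major arrangement (stages nested within states), so demography can
#' be applied block-diagonally by state and movement block-diagonally by
#' stage. It is orthogonal: `K %*% t(K)` is the identity.
#'
#' @param s Number of stages.
#' @param r Number of states.
#' @return An (s r) x (s r) permutation matrix.
#' @export
vec_permutation_matrix <- function(s, r) {
  stopifnot(s >= 1, r >= 1)
  K <- matrix(0, s * r, s * r)
  for (i in seq_len(s)) {
    for (j in seq_len(r)) {
      K[(j - 1L) * s + i, (i - 1L) * r + j] <- 1
    }
  }
  K
}

#' Demography block for one state
#'
#' The 4x4 within-state projection matrix over stages (intact juvenile,
#' intact adult, sterile juvenile, sterile adult):
#' \preformatted{
#'   [ s0 f0 (1-n0)   s1 f1 (1-n1)   0    0  ]
#'   [ s0 (1-n0)      s1 (1-n1)      0    0  ]
#'   [ s0 f0 n0       s1 f1 n1       0    0  ]
#'   [ s0 n0          s1 n1          s0   s1 ]
#' }
#' where s is survival, f fecundity (female kittens per female per year) and
#' n the sterilization probability, subscripted 0 for juveniles and 1 for
#' adults. Column sums are s0(1+f0), s1(1+f1), s0, s1.
#'
#' The intact/sterile split of the offspring rows (1 and 3) uses the
#' juvenile sterilization rate for kittens of both juvenile and adult
#' mothers by default (`offspring_sterilization = "kitten_rate"`): kittens
#' are sterilized in their first year at the kitten rate regardless of who
#' bore them. The alternative `"parent_stage"` splits offspring by the
#' mother's stage-specific rate (n0 in column 1, n1 in column 2). Both
#' choices leave the column sums unchanged; only the kitten-rate form yields
#' a subcritical owned-cat subsystem at temperate latitudes (see the methods
#' vignette).
#'
#' @param s0,s1 Juvenile and adult annual survival.
#' @param f0,f1 Juvenile and adult fecundity.
#' @param n0,n1 Juvenile and adult sterilization probability.
#' @param offspring_sterilization `"kitten_rate"` (default) or
#'   `"parent_stage"`; see Details.
#' @return A 4x4 nonnegative matrix.
#' @export
build_demography_block <- function(s0, s1, f0, f1, n0, n1,
                                   offspring_sterilization = c("kitten_rate",
                                                               "parent_stage")) {
  offspring_sterilization <- match.arg(offspring_sterilization)
  stopifnot(s0 >= 0, s0 <= 1, s1 >= 0, s1 <= 1, f0 >= 0, f1 >= 0,
            n0 >= 0, n0 <= 1, n1 >= 0, n1 <= 1)
  # sterilization rate applied to offspring of juvenile / adult mothers
  nb <- if (offspring_sterilization == "kitten_rate") c(n0, n0) else c(n0, n1)
  B <- matrix(c(
    s0 * f0 * (1 - nb[1]), s1 * f1 * (1 - nb[2]), 0,  0,
    s0 * (1 - n0),         s1 * (1 - n1),         0,  0,
    s0 * f0 * nb[1],       s1 * f1 * nb[2],       0,  0,
    s0 * n0,               s1 * n1,               s0, s1
  ), nrow = 4, byrow = TRUE)
  if (any(B < 0)) stop("negative demography entries: rates mis-specified")
  dimnames(B) <- list(CAT_STAGES, CAT_STAGES)
  B
}

#' Transition block for one stage
#'
#' The 4x4 column-stochastic matrix of annual movement among states (owned,
#' shelter, free-roaming, feral). Columns are the source state. The
#' return-to-owner rate uses the intact value for intact stages and the
#' sterile value for sterile stages; kittens of free-roaming cats become
#' feral (`kitten_feral`) only in the juvenile stages.
#'
#' Away from equilibrium the density-dependent outflows can transiently
#' saturate (e.g. adoption approaches 1 when the owned population is far
#' below carrying capacity, so adoption + return-to-owner would exceed 1).
#' To keep every column a probability distribution, adoption is capped at
#' one minus the return-to-owner rate, and the free-roaming outflows are
#' rescaled proportionally if their sum would exceed 1. Constant rates that
#' sum past 1 (an invalid configuration) remain an error.
#'
#' @param stage Stage index 1-4.
#' @param params A `cat_params` object.
#' @param snapshot A [population_snapshot()] at which the density-dependent
#'   adoption and surrender rates are evaluated.
#' @return A 4x4 column-stochastic matrix.
#' @export
build_transition_block <- function(stage, params, snapshot) {
  stopifnot(stage %in% 1:4)
  r <- params$relinquishment
  l <- params$loss
  ab <- params$abandonment
  cc <- if (stage %in% c(1L, 2L)) params$recovery_intact
        else params$recovery_sterile
  ff <- if (stage %in% c(1L, 3L)) params$kitten_feral else 0
  fs <- params$feral_surrender
  d <- shelter_adoption_rate(snapshot$owned, params$K$owned, params)
  d <- min(d, 1 - cc) # return-to-owner takes precedence when d saturates
  fa <- offstreet_adoption_rate(snapshot$owned, params$K$owned,
                                snapshot$freeroaming, params$K$freeroaming,
                                params)
  su <- surrender_rate(snapshot$freeroaming, params$K$freeroaming, params)
  out_free <- fa + su + ff
  if (out_free > 1) { # transient saturation guard, keeps column stochastic
    fa <- fa / out_free
    su <- su / out_free
    ff <- ff / out_free
  }
  M <- matrix(c(
    1 - (r + l + ab), d + cc,       fa,                  0,
    r,                1 - (d + cc), su,                  fs,
    l + ab,           0,            1 - (fa + su + ff),  0,
    0,                0,            ff,                  1 - fs
  ), nrow = 4, byrow = TRUE)
  if (any(diag(M) < -1e-9))
    stop("outflow probabilities sum past 1 in transition block (stage ",
         stage, ")")
  diag(M) <- pmax(diag(M), 0) # absorb roundoff from the saturation guard
  dimnames(M) <- list(CAT_STATES, CAT_STATES)
  M
}

# Demography block for state i, with unowned survival evaluated at the
# snapshot.
state_demography_block <- function(state, params, snapshot) {
  rt <- static_rates(params, state)
  if (state == "freeroaming") {
    rt$s1 <- adult_unowned_survival(snapshot$freeroaming,
                                    params$K$freeroaming, params,
                                    "freeroaming")
    rt$s0 <- juvenile_freeroaming_survival(snapshot$prop_intact, rt$s1,
                                           params)
  } else if (state == "feral") {
    rt$s1 <- adult_unowned_survival(snapshot$feral, params$K$feral, params,
                                    "feral")
    rt$s0 <- juvenile_feral_survival(snapshot$feral, params$K$feral, params)
  }
  os <- params$dd$offspring_sterilization
  if (is.null(os)) os <- "kitten_rate"
  build_demography_block(rt$s0, rt$s1, rt$f0, rt$f1, rt$n0, rt$n1,
                         offspring_sterilization = os)
}

block_diagonal <- function(blocks) {
  k <- length(blocks)
  p <- nrow(blocks[[1L]])
  out <- matrix(0, k * p, k * p)
  for (b in seq_len(k)) {
    idx <- (b - 1L) * p + seq_len(p)
    out[idx, idx] <- blocks[[b]]
  }
  out
}

#' Assemble the annual projection matrix
#'
#' Builds the 16x16 matrix \eqn{A = M K^T B K}: the vec-permutation matrix
#' `K` rearranges the stage-major population vector so the block-diagonal
#' demography matrix `B` (one block per state) applies, the arrangement is
#' reversed, and the block-diagonal movement matrix `M` (one transition
#' block per stage) moves individuals among states. Demography therefore
#' precedes movement within each annual step. All density-dependent rates
#' are evaluated at `snapshot`.
#'
#' @param params A `cat_params` object.
#' @param snapshot A [population_snapshot()].
#' @return A 16x16 nonnegative matrix.
#' @export
assemble_projection <- function(params, snapshot) {
  K <- vec_permutation_matrix(4L, 4L)
  B <- block_diagonal(lapply(CAT_STATES, state_demography_block,
                             params = params, snapshot = snapshot))
  M <- block_diagonal(lapply(1:4, build_transition_block, params = params,
                             snapshot = snapshot))
  M %*% t(K) %*% B %*% K
}

#' Project the population one year forward
#'
#' Evaluates all density-dependent rates at the current vector `n`,
#' assembles the projection matrix A(n), and returns A(n) n.
#'
#' @param n A 16-entry stage-major population vector.
#' @param params A `cat_params` object.
#' @return The population vector one year later.
#' @export
project_population <- function(n, params) {
  n <- as_population_vector(n)
  A <- assemble_projection(params, population_snapshot(n))
  out <- as.numeric(A %*% n)
  if (any(!is.finite(out)))
    stop("projection produced non-finite abundances (numerical blow-up)")
  out
}

#' Solve for the density-dependent equilibrium
#'
#' Iterates the annual projection from a starting vector until the maximum
#' relative step change falls below `tol` or `max_iter` years elapse. The
#' result records whether convergence was reached; a run that hits the
#' iteration cap is classified from the tail of its trajectory as
#' oscillatory, divergent, or slowly converging, and is never reported as
#' converged.
#'
#' @param params A `cat_params` object.
#' @param n0 Starting population vector (default
#'   [default_initial_population()]).
#' @param max_iter Maximum number of annual iterations (default 1200).
#' @param tol Convergence tolerance on the maximum relative step change
#'   (default 1e-9).
#' @param keep_trajectory If `TRUE`, store the full iteration-by-iteration
#'   trajectory (a matrix with one row per year).
#' @return An object of class `equilibrium_result` with elements `n` (final
#'   female vector), `iterations`, `converged`, `diagnostic`,
#'   `female_totals` and `totals` (doubled, both-sex abundances per state
#'   plus `total` = owned + free-roaming + feral and `total_with_shelter`),
#'   and optionally `trajectory`.
#' @examples
#' p <- build_parameter_set(city_inputs(43.55, 52620, 7885))
#' eq <- solve_equilibrium(p)
#' eq$totals["owned"]
#' @export
solve_equilibrium <- function(params, n0 = default_initial_population(),
                              max_iter = 1200, tol = 1e-9,
                              keep_trajectory = FALSE) {
  stopifnot(max_iter >= 1, tol > 0)
  n <- as_population_vector(n0)
  traj <- if (keep_trajectory) matrix(NA_real_, max_iter + 1L, 16L) else NULL
  if (keep_trajectory) traj[1L, ] <- n
  converged <- FALSE
  iterations <- 0L
  tail_steps <- numeric(0)
  for (it in seq_len(max_iter)) {
    n_next <- project_population(n, params)
    denom <- pmax(abs(n), 1e-12)
    step <- max(abs(n_next - n) / denom)
    if (keep_trajectory) traj[it + 1L, ] <- n_next
    if (it > max_iter - 50L) tail_steps <- c(tail_steps, step)
    n <- n_next
    iterations <- it
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  diagnostic <- if (converged) {
    "converged"
  } else {
    classify_nonconvergence(tail_steps)
  }
  female_totals <- state_totals(n)
  totals <- 2 * female_totals
  totals <- c(totals,
              total = unname(totals["owned"] + totals["freeroaming"] +
                               totals["feral"]),
              total_with_shelter = unname(sum(totals)))
  structure(list(
    n = n,
    iterations = iterations,
    converged = converged,
    diagnostic = diagnostic,
    female_totals = female_totals,
    totals = totals,
    tol = tol,
    trajectory = if (keep_trajectory) traj[seq_len(iterations + 1L), ,
                                           drop = FALSE] else NULL
  ), class = "equilibrium_result")
}

# Classify a non-converged tail of relative step sizes.
classify_nonconvergence <- function(steps) {
  if (length(steps) < 3L) return("non-converged")
  diffs <- diff(steps)
  if (all(diffs > 0)) return("divergent")
  if (all(diffs < 0)) return("slowly converging")
  sign_changes <- sum(diff(sign(diffs)) != 0)
  if (sign_changes >= length(diffs) / 2) "oscillatory" else "non-converged"
}

state_totals <- function(n) {
  n <- as_population_vector(n)
  vapply(1:4, function(j) sum(n[pv_index(1:4, j)]), numeric(1)) |>
    stats::setNames(CAT_STATES)
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("<equilibrium_result>\n")
  status <- if (x$converged) sprintf("converged in %d iterations", x$iterations)
            else sprintf("NOT converged after %d iterations (%s)",
                         x$iterations, x$diagnostic)
  cat("  ", status, "\n", sep = "")
  cat("  both-sex abundances:\n")
  for (s in names(x$totals)) {
    cat(sprintf("    %-20s %10.1f\n", s, x$totals[[s]]))
  }
  invisible(x)
}
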
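# Perturbation (elasticity) analysis of equilibrium abundance with respect
# to every lower-level parameter, by full re-solve finite differences and by
# implicit differentiation of the fixed point.

#' Group abundance from a population vector
#'
#' Sums the female entries of a group of states: `owned`, `shelter`,
#' `unowned` (free-roaming + feral), or `total` (owned + free-roaming +
#' feral; the shelter state is a flow-through and is excluded from the
#' standing total). A logical mask of length 16 selects arbitrary entries.
#'
#' @param n A 16-entry stage-major population vector.
#' @param group Group name or a logical mask of length 16.
#' @return Summed female count.
#' @export
group_abundance <- function(n, group) {
  n <- as_population_vector(n)
  if (is.logical(group)) {
    stopifnot(length(group) == 16L)
    return(sum(n[group]))
  }
  idx <- switch(group,
    owned = pv_index(1:4, 1L),
    shelter = pv_index(1:4, 2L),
    freeroaming = pv_index(1:4, 3L),
    feral = pv_index(1:4, 4L),
    unowned = c(pv_index(1:4, 3L), pv_index(1:4, 4L)),
    total = c(pv_index(1:4, 1L), pv_index(1:4, 3L), pv_index(1:4, 4L)),
    stop("unknown group: ", group)
  )
  sum(n[idx])
}

ELASTICITY_GROUPS <- c("owned", "shelter", "unowned", "total")

# Return params with the named scalar parameter set to value, re-validated.
set_parameter <- function(params, name, value) {
  if (!name %in% parameter_names())
    stop("unknown parameter: ", name)
  params[[name]] <- value
  validate_parameter_set(params)
}

get_parameter <- function(params, name) {
  if (!name %in% parameter_names())
    stop("unknown parameter: ", name)
  params[[name]]
}

#' Elasticities by re-solve finite differences
#'
#' For each parameter \eqn{\theta}, re-solves the model to equilibrium at
#' \eqn{\theta(1 \pm \delta)} and forms the central-difference elasticity of
#' each group abundance,
#' \eqn{[N_g(\theta(1+\delta)) - N_g(\theta(1-\delta))] / (2 \delta N_g)}.
#' Perturbed solves are warm-started from the baseline equilibrium. A
#' parameter whose baseline value is 0 cannot be perturbed proportionally;
#' its row reports the absolute sensitivity (per unit of \eqn{\theta},
#' scaled by \eqn{1/N_g}) and is flagged in the `scaling` column.
#'
#' @param params A `cat_params` object.
#' @param theta_names Parameters to perturb (default all of
#'   [parameter_names()]).
#' @param delta Relative perturbation size (default 1e-3).
#' @param baseline Optional precomputed baseline `equilibrium_result`.
#' @param max_iter,tol Solver settings for the perturbed runs.
#' @return A data frame with columns `parameter`, `group`, `elasticity`,
#'   `scaling` (`"relative"` or `"absolute"`), `method`, `delta`. Entries
#'   where a perturbed run failed to converge are `NA`.
#' @export
elasticity_fd <- function(params, theta_names = parameter_names(),
                          delta = 1e-3, baseline = NULL,
                          max_iter = 5000, tol = 1e-11) {
  stopifnot(delta > 0, delta <= 0.05)
  if (is.null(baseline))
    baseline <- solve_equilibrium(params, max_iter = max_iter, tol = tol)
  if (!baseline$converged)
    stop("baseline equilibrium did not converge: ", baseline$diagnostic)
  n_star <- baseline$n
  base_N <- vapply(ELASTICITY_GROUPS, group_abundance, numeric(1), n = n_star)

  solve_at <- function(nm, value) {
    p2 <- try(set_parameter(params, nm, value), silent = TRUE)
    if (inherits(p2, "try-error")) return(NULL) # value outside valid range
    eq <- try(solve_equilibrium(p2, n0 = n_star, max_iter = max_iter,
                                tol = tol), silent = TRUE)
    if (inherits(eq, "try-error") || !eq$converged) return(NULL)
    eq$n
  }

  rows <- list()
  for (nm in theta_names) {
    theta <- get_parameter(params, nm)
    relative <- theta != 0
    h <- if (relative) abs(theta) * delta else delta
    up <- solve_at(nm, theta + h)
    dn <- solve_at(nm, theta - h)
    for (g in ELASTICITY_GROUPS) {
      # central difference; one-sided at a parameter bound
      dN <- if (!is.null(up) && !is.null(dn)) {
        (group_abundance(up, g) - group_abundance(dn, g)) / (2 * h)
      } else if (!is.null(up)) {
        (group_abundance(up, g) - base_N[[g]]) / h
      } else if (!is.null(dn)) {
        (base_N[[g]] - group_abundance(dn, g)) / h
      } else {
        NA_real_
      }
      val <- if (base_N[[g]] == 0) 0
             else dN * (if (relative) theta else 1) / base_N[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, group = g, elasticity = val,
        scaling = if (relative) "relative" else "absolute",
        method = "finite-difference", delta = delta,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One projection step as a function of (n, params): g(n, theta) = A(n) n.
step_map <- function(n, params) project_population(n, params)

#' Elasticities by implicit differentiation of the fixed point
#'
#' At the equilibrium \eqn{n^* = g(n^*, \theta)} with \eqn{g(n, \theta) =
#' A(n, \theta) n}, the chain rule gives
#' \deqn{(I - J) \frac{dn^*}{d\theta} = \frac{\partial g}{\partial \theta}}
#' where \eqn{J = dg/dn} is the Jacobian of one projection step (including
#' the dependence of the density-dependent rates on n). Both derivative
#' blocks are formed by central numerical differentiation of the assembled
#' step map; the linear system is solved once per parameter and the result
#' scaled to elasticities. Valid when the equilibrium is locally attracting
#' (spectral radius of J below 1).
#'
#' @param params A `cat_params` object.
#' @param theta_names Parameters to differentiate (default all).
#' @param baseline Optional precomputed baseline `equilibrium_result`.
#' @param h_rel Relative step for the numerical derivatives (default 1e-6).
#' @param max_iter,tol Solver settings for the baseline run if not supplied.
#' @return A data frame in the same layout as [elasticity_fd()] with
#'   `method = "implicit"`.
#' @export
elasticity_implicit <- function(params, theta_names = parameter_names(),
                                baseline = NULL, h_rel = 1e-6,
                                max_iter = 5000, tol = 1e-11) {
  if (is.null(baseline))
    baseline <- solve_equilibrium(params, max_iter = max_iter, tol = tol)
  if (!baseline$converged)
    stop("baseline equilibrium did not converge: ", baseline$diagnostic)
  n_star <- as_population_vector(baseline$n)

  # Jacobian of the step map in n (16 x 16), central differences.
  J <- matrix(0, 16L, 16L)
  for (k in seq_len(16L)) {
    h <- h_rel * max(abs(n_star[k]), max(n_star) * 1e-3, 1)
    up <- n_star; up[k] <- up[k] + h
    dn <- n_star; dn[k] <- max(dn[k] - h, 0)
    hh <- up[k] - dn[k]
    J[, k] <- (step_map(up, params) - step_map(dn, params)) / hh
  }
  IJ <- diag(16L) - J
  cn <- tryCatch(solve(IJ), error = function(e) {
    ev <- max(Mod(eigen(J, only.values = TRUE)$values))
    stop("(I - J) is numerically singular (spectral radius of J = ",
         signif(ev, 4), "); the fixed point is not locally contracting -- ",
         "use elasticity_fd() instead")
  })

  base_N <- vapply(ELASTICITY_GROUPS, group_abundance, numeric(1),
                   n = n_star)
  masks <- lapply(ELASTICITY_GROUPS, function(g) {
    m <- logical(16L)
    idx <- switch(g,
      owned = pv_index(1:4, 1L), shelter = pv_index(1:4, 2L),
      unowned = c(pv_index(1:4, 3L), pv_index(1:4, 4L)),
      total = c(pv_index(1:4, 1L), pv_index(1:4, 3L), pv_index(1:4, 4L)))
    m[idx] <- TRUE
    m
  })
  names(masks) <- ELASTICITY_GROUPS

  rows <- list()
  for (nm in theta_names) {
    theta <- get_parameter(params, nm)
    relative <- theta != 0
    h <- if (relative) abs(theta) * 1e-4 else 1e-5
    step_at <- function(value) {
      p2 <- try(set_parameter(params, nm, value), silent = TRUE)
      if (inherits(p2, "try-error")) return(NULL)
      step_map(n_star, p2)
    }
    gp <- step_at(theta + h)
    gm <- step_at(theta - h)
    g0 <- step_map(n_star, params)
    dg_dtheta <- if (!is.null(gp) && !is.null(gm)) (gp - gm) / (2 * h)
                 else if (!is.null(gp)) (gp - g0) / h
                 else (g0 - gm) / h
    dn_dtheta <- cn %*% dg_dtheta
    for (g in ELASTICITY_GROUPS) {
      dN <- sum(dn_dtheta[masks[[g]]])
      val <- if (base_N[[g]] == 0) 0
             else dN * (if (relative) theta else 1) / base_N[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, group = g, elasticity = val,
        scaling = if (relative) "relative" else "absolute",
        method = "implicit", delta = h_rel,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Elasticity table for a city
#'
#' Convenience wrapper running the requested elasticity method over all
#' lower-level parameters at the city's equilibrium.
#'
#' @param params A `cat_params` object.
#' @param method `"finite-difference"` (default) or `"implicit"`.
#' @param ... Passed to [elasticity_fd()] or [elasticity_implicit()].
#' @return A tidy data frame of elasticities.
#' @export
elasticity_table <- function(params,
                             method = c("finite-difference", "implicit"),
                             ...) {
  method <- match.arg(method)
  if (method == "finite-difference") elasticity_fd(params, ...)
  else elasticity_implicit(params, ...)
}
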
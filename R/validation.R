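# Model-fit statistics: tests of a 1:1 predicted-observed relationship and
# exact binomial confidence intervals for sterile proportions.

#' Test a 1:1 relationship between predictions and observations
#'
#' Ordinary least squares of observed on predicted values, with a t test of
#' the intercept against 0 and of the slope against 1 (not 0): a model whose
#' predictions match observations should have intercept 0 and slope 1.
#'
#' @param predicted Model-predicted values.
#' @param observed Observed values (same length, at least 3 pairs).
#' @return A list with `intercept`, `slope`, `se_intercept`, `se_slope`,
#'   `t_intercept`, `p_intercept`, `t_slope_vs_1`, `p_slope`, `df`, and
#'   `degenerate` (`TRUE` when the fit is exact and the standard errors are
#'   0, in which case the t statistics are 0 for a perfect 1:1 fit and
#'   infinite otherwise).
#' @examples
#' fit <- one_to_one_regression(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))
#' fit$p_slope  # is the slope distinguishable from 1?
#' @export
one_to_one_regression <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (length(predicted) < 3)
    stop("at least 3 predicted/observed pairs are required")
  if (stats::var(predicted) == 0)
    stop("predicted values have zero variance; slope is undefined")
  fit <- stats::lm(observed ~ predicted)
  cf <- stats::coef(fit)
  # summary.lm warns on exact fits; the degenerate branch below handles them
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[, "Std. Error"]
  df <- fit$df.residual
  scale <- max(abs(observed), 1)
  degenerate <- all(abs(stats::residuals(fit)) < 1e-10 * scale)
  if (degenerate) {
    # an exact fit has no residual error: the t statistics are 0 when the
    # coefficient already equals its null value and infinite otherwise
    t_int <- if (abs(cf[1]) < 1e-10 * scale) 0 else Inf * sign(cf[1])
    t_slp <- if (abs(cf[2] - 1) < 1e-10) 0 else Inf * sign(cf[2] - 1)
  } else {
    t_int <- cf[1] / se[1]
    t_slp <- (cf[2] - 1) / se[2]
  }
  p_from_t <- function(t) {
    if (!is.finite(t)) return(0)
    2 * stats::pt(-abs(t), df)
  }
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       t_intercept = unname(t_int), p_intercept = p_from_t(t_int),
       t_slope_vs_1 = unname(t_slp), p_slope = p_from_t(t_slp),
       df = df, degenerate = degenerate)
}

#' Binomial confidence interval for a proportion
#'
#' Exact Clopper-Pearson interval by default (beta quantiles), with the
#' Wilson score interval available. Used to put 95% intervals on observed
#' sterile proportions of unowned cats.
#'
#' @param successes Number of successes (e.g. sterilized cats).
#' @param trials Number of trials (cats examined).
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default, exact) or `"wilson"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' binomial_ci(5, 10)  # (0.187, 0.813)
#' @export
binomial_ci <- function(successes, trials, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            level > 0, level < 1)
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    lower <- if (successes == 0) 0
             else stats::qbeta(alpha / 2, successes, trials - successes + 1)
    upper <- if (successes == trials) 1
             else stats::qbeta(1 - alpha / 2, successes + 1,
                               trials - successes)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- successes / trials
    denom <- 1 + z^2 / trials
    center <- (p + z^2 / (2 * trials)) / denom
    half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
    lower <- max(0, center - half)
    upper <- min(1, center + half)
  }
  c(lower = lower, upper = upper)
}

#' Validate comparison pairs from a data frame
#'
#' Runs the 1:1 regression on a table of predicted/observed abundance pairs
#' and, where count columns are present, computes a binomial confidence
#' interval per row.
#'
#' @param pairs Data frame with columns `predicted` and `observed`, and
#'   optionally `successes` and `trials` for per-row proportions (a `city`
#'   label column is carried through if present).
#' @param level Confidence level for the per-row intervals.
#' @return A list with `regression` (see [one_to_one_regression()]) and
#'   `ci` (a data frame, or `NULL` when no count columns are supplied).
#' @export
validate_pairs <- function(pairs, level = 0.95) {
  stopifnot(is.data.frame(pairs),
            all(c("predicted", "observed") %in% names(pairs)))
  reg <- one_to_one_regression(pairs$predicted, pairs$observed)
  ci <- NULL
  if (all(c("successes", "trials") %in% names(pairs))) {
    bounds <- t(mapply(binomial_ci, pairs$successes, pairs$trials,
                       MoreArgs = list(level = level)))
    ci <- data.frame(
      city = if ("city" %in% names(pairs)) pairs$city
             else seq_len(nrow(pairs)),
      proportion = pairs$successes / pairs$trials,
      lower = bounds[, "lower"], upper = bounds[, "upper"],
      stringsAsFactors = FALSE)
  }
  list(regression = reg, ci = ci)
}
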
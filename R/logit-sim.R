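#' Specification of a logistic-regression power/bias simulation
#'
#' Bundles and validates everything the Monte-Carlo engine needs: the true
#' odds ratio per ln(exposure) unit, the marginal (baseline) incidence of the
#' binary outcome, the cohort size, the measurement schedule, the exposure
#' variance components, the test level, the replicate count and the RNG seed.
#'
#' @param or_true True odds ratio per 1 ln(exposure) unit, positive.
#' @param p0 Baseline (marginal) incidence of the outcome, in (0, 1).
#' @param n Number of subjects, at least 10.
#' @param m Repeats per person, whole number at least 1.
#' @param vc A [variance_components()] object.
#' @param alpha Two-sided Wald test level, in (0, 1).
#' @param n_reps Number of simulation replicates, at least 1. The default
#'   2000 pins power to roughly one percentage point.
#' @param seed Integer root seed; replicates draw from independent
#'   L'Ecuyer-CMRG substreams spawned from it, so results are bit-identical
#'   for a given spec + seed.
#' @return An object of class `logit_sim_spec`.
#' @examples
#' logit_sim_spec(or_true = 1.14, p0 = 0.10, n = 1379, m = 2,
#'                vc = variance_components(0.21, 0.72), seed = 1)
#' @export
logit_sim_spec <- function(or_true, p0, n, m, vc, alpha = 0.05,
                           n_reps = 2000, seed = 1) {
  vc <- as_vc(vc)
  stopifnot(is.numeric(or_true), length(or_true) == 1L, is.finite(or_true),
            is.numeric(p0), length(p0) == 1L, is.finite(p0),
            is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(n_reps), length(n_reps) == 1L, is.finite(n_reps),
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (or_true <= 0) stop("or_true must be positive", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  if (n < 10 || n != floor(n)) {
    stop("n must be a whole number of subjects, at least 10", call. = FALSE)
  }
  check_m(m, integer_only = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_reps < 1 || n_reps != floor(n_reps)) {
    stop("n_reps must be a whole number, at least 1", call. = FALSE)
  }
  structure(
    list(or_true = or_true, p0 = p0, n = as.integer(n), m = as.integer(m),
         vc = vc, alpha = alpha, n_reps = as.integer(n_reps),
         seed = as.integer(seed)),
    class = "logit_sim_spec"
  )
}

#' Calibrate the logistic intercept to a marginal incidence
#'
#' Finds the intercept `b0` such that the *marginal* (population-averaged)
#' incidence of the outcome equals `p0` when the true exposure is
#' Normal(0, `sigma2_between`) and the conditional model is
#' `logit P(Y=1|X) = b0 + log_or * X`. The expectation
#' `E[plogis(b0 + log_or X)]` is computed by 64-node Gauss-Hermite
#' quadrature and solved for `b0` by bracketed root finding; the solution is
#' unique because the expectation is strictly increasing in `b0`.
#'
#' With a random intercept this marginal calibration differs (slightly, at
#' these parameter values) from the naive `b0 = qlogis(p0)`, which would fix
#' the incidence of a subject at the exposure mean rather than of the cohort.
#'
#' @param log_or True log odds ratio per ln(exposure) unit.
#' @param p0 Target marginal incidence, in (0, 1).
#' @param sigma2_between Between-person variance of true exposure.
#' @return The calibrated intercept, a single real.
#' @examples
#' calibrate_intercept(log(1.14), 0.10, 0.21)
#' @export
calibrate_intercept <- function(log_or, p0, sigma2_between) {
  stopifnot(is.numeric(log_or), length(log_or) == 1L, is.finite(log_or),
            is.numeric(p0), length(p0) == 1L,
            is.numeric(sigma2_between), length(sigma2_between) == 1L,
            is.finite(sigma2_between), sigma2_between >= 0)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  if (log_or == 0 || sigma2_between == 0) return(stats::qlogis(p0))
  gh <- pracma::gaussHermite(64)
  scale <- sqrt(2 * sigma2_between)
  marginal <- function(b0) {
    sum(gh$w * stats::plogis(b0 + log_or * scale * gh$x)) / sqrt(pi)
  }
  lower <- stats::qlogis(p0) - 20
  upper <- stats::qlogis(p0) + 20
  if ((marginal(lower) - p0) * (marginal(upper) - p0) > 0) {
    stop("intercept root not bracketed within qlogis(p0) +/- 20",
         call. = FALSE)
  }
  root <- stats::uniroot(function(b0) marginal(b0) - p0, c(lower, upper),
                         tol = .Machine$double.eps^0.75)$root
  if (abs(marginal(root) - p0) > 1e-10) {
    stop("intercept calibration did not converge to tolerance", call. = FALSE)
  }
  root
}

#' Simulate one replicate of the logistic-regression study
#'
#' Draws one synthetic cohort under the classical measurement error model
#' and fits the analysis model a practitioner would fit. True exposures are
#' `x_i ~ Normal(0, sigma2_B)`; the analysed exposure is the person-mean of
#' `m` measurements, `w_i = x_i + e_i` with `e_i ~ Normal(0, sigma2_W / m)`;
#' outcomes are Bernoulli with `logit P(Y=1|x) = b0 + log(or_true) * x`.
#' A maximum-likelihood logistic regression of `y` on `w` yields the
#' estimated odds ratio and the two-sided Wald p-value for the slope.
#'
#' @param spec A [logit_sim_spec()].
#' @param stream Optional `.Random.seed` state (an L'Ecuyer-CMRG substream)
#'   to install before drawing; `NULL` uses the current RNG state.
#' @param b0 Optional precomputed intercept; calibrated from the spec when
#'   missing.
#' @return A list with `or_hat`, `p_value` and `converged`. Degenerate
#'   cohorts (all-0 or all-1 outcomes), non-converged fits and separated
#'   fits are flagged `converged = FALSE` rather than raising an error.
#' @export
simulate_replicate <- function(spec, stream = NULL, b0 = NULL) {
  stopifnot(inherits(spec, "logit_sim_spec"))
  if (!is.null(stream)) {
    assign(".Random.seed", stream, envir = globalenv())
  }
  if (is.null(b0)) {
    b0 <- calibrate_intercept(log(spec$or_true), spec$p0,
                              spec$vc$sigma2_between)
  }
  n <- spec$n
  x <- stats::rnorm(n, 0, sqrt(spec$vc$sigma2_between))
  w <- x + stats::rnorm(n, 0, sqrt(spec$vc$sigma2_within / spec$m))
  y <- stats::rbinom(n, 1L, stats::plogis(b0 + log(spec$or_true) * x))
  if (all(y == 0L) || all(y == 1L)) {
    return(list(or_hat = NA_real_, p_value = NA_real_, converged = FALSE))
  }
  fit <- stats::glm.fit(cbind(1, w), y, family = stats::binomial())
  slope <- fit$coefficients[2L]
  # Wald SE as summary.glm computes it, from the final IWLS decomposition
  p1 <- seq_len(fit$rank)
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(covmat[2L, 2L])
  ok <- isTRUE(fit$converged) && !fit$boundary &&
    is.finite(slope) && is.finite(se) && se < 100
  if (!ok) {
    return(list(or_hat = NA_real_, p_value = NA_real_, converged = FALSE))
  }
  list(or_hat = unname(exp(slope)),
       p_value = unname(2 * stats::pnorm(-abs(slope / se))),
       converged = TRUE)
}

#' Monte-Carlo power and odds-ratio bias of a logistic-regression design
#'
#' Runs [simulate_replicate()] `n_reps` times on independent RNG substreams
#' spawned from the root seed and summarises: power is the share of
#' converged replicates with Wald p below `alpha`; per-replicate percent
#' bias is `100 (or_hat - or_true) / or_true`, summarised by its median and
#' empirical 2.5th/97.5th percentiles (linear interpolation between order
#' statistics). Non-converged replicates are excluded from both summaries
#' and counted in `n_excluded`.
#'
#' @param spec A [logit_sim_spec()].
#' @return An object of class `power_bias_result`: a list with `power`,
#'   `bias_median_pct`, `bias_interval_pct` (length-2), `n_reps_used`,
#'   `n_excluded`, `or_hats`, `p_values` and the `spec`. A warning is
#'   recorded in `$warning` when more than 10% of replicates fail to
#'   converge; an error is raised if none converge.
#' @examples
#' \donttest{
#' spec <- logit_sim_spec(1.14, 0.10, 1379, 2, variance_components(0.21, 0.72),
#'                        n_reps = 500, seed = 42)
#' run_power_bias(spec)
#' }
#' @export
run_power_bias <- function(spec) {
  stopifnot(inherits(spec, "logit_sim_spec"))
  b0 <- calibrate_intercept(log(spec$or_true), spec$p0,
                            spec$vc$sigma2_between)

  # independent per-replicate substreams from one root seed; restore the
  # caller's RNG state on exit
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())

  or_hat <- p_val <- rep(NA_real_, spec$n_reps)
  conv <- logical(spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    stream <- parallel::nextRNGStream(stream)
    rep_r <- simulate_replicate(spec, stream = stream, b0 = b0)
    or_hat[r] <- rep_r$or_hat
    p_val[r] <- rep_r$p_value
    conv[r] <- rep_r$converged
  }

  n_used <- sum(conv)
  n_excl <- spec$n_reps - n_used
  if (n_used == 0L) {
    stop("no simulation replicate converged; check the design parameters",
         call. = FALSE)
  }
  warn <- NULL
  if (n_excl > 0.10 * spec$n_reps) {
    warn <- sprintf("%d of %d replicates excluded (non-convergence)",
                    n_excl, spec$n_reps)
    warning(warn, call. = FALSE)
  }
  bias_pct <- 100 * (or_hat[conv] - spec$or_true) / spec$or_true
  structure(
    list(
      power = mean(p_val[conv] < spec$alpha),
      bias_median_pct = stats::median(bias_pct),
      bias_interval_pct = unname(stats::quantile(bias_pct,
                                                 c(0.025, 0.975))),
      n_reps_used = n_used,
      n_excluded = n_excl,
      intercept = b0,
      or_hats = or_hat,
      p_values = p_val,
      warning = warn,
      spec = spec
    ),
    class = "power_bias_result"
  )
}

#' @export
print.power_bias_result <- function(x, ...) {
  s <- x$spec
  cat("Logistic-regression power/bias simulation\n")
  cat(sprintf("  true OR %.4g per ln-unit, p0 %.3g, n %d, m %d, alpha %.3g\n",
              s$or_true, s$p0, s$n, s$m, s$alpha))
  cat(sprintf("  replicates: %d used, %d excluded (seed %d)\n",
              x$n_reps_used, x$n_excluded, s$seed))
  cat(sprintf("  power: %.3f\n", x$power))
  cat(sprintf("  median percent bias in OR: %.1f%% (95%% interval %.1f to %.1f%%)\n",
              x$bias_median_pct, x$bias_interval_pct[1L],
              x$bias_interval_pct[2L]))
  invisible(x)
}

#' Convert an odds ratio per exposure range to an OR per ln-unit
#'
#' Published ORs are often quoted per interquartile range of exposure. If
#' that range spans `range_width_ln` units of ln(exposure), the equivalent
#' OR per single ln-unit is `exp(log(or_per_range) / range_width_ln)`.
#'
#' @param or_per_range Odds ratio per full exposure range, positive.
#' @param range_width_ln Width of the range in ln(exposure) units, positive.
#' @return Odds ratio per 1 ln(exposure) unit.
#' @examples
#' or_per_ln_unit(1.4, 2.5) # 1.1437
#' @export
or_per_ln_unit <- function(or_per_range, range_width_ln) {
  stopifnot(is.numeric(or_per_range), length(or_per_range) == 1L,
            is.numeric(range_width_ln), length(range_width_ln) == 1L,
            is.finite(or_per_range), is.finite(range_width_ln))
  if (or_per_range <= 0 || range_width_ln <= 0) {
    stop("or_per_range and range_width_ln must be positive", call. = FALSE)
  }
  exp(log(or_per_range) / range_width_ln)
}
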
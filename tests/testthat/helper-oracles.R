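# Independent oracles used to validate the closed-form calculators.

# Brute-force Monte-Carlo estimate of the attenuation factor: simulate
# n_persons subjects, regress a linear outcome on the person-mean of m noisy
# measurements, and return the fitted slope relative to the true one along
# with its Monte-Carlo standard error (also on the relative scale).
mc_attenuation <- function(vc, m, beta = 1, n_persons = 1e5) {
  x <- rnorm(n_persons, 0, sqrt(vc$sigma2_between))
  w <- x + rnorm(n_persons, 0, sqrt(vc$sigma2_within / m))
  y <- beta * x + rnorm(n_persons)
  fit <- summary(lm(y ~ w))$coefficients
  list(lambda_hat = fit["w", "Estimate"] / beta,
       se = fit["w", "Std. Error"] / abs(beta))
}

# Bisection inverse of the (unrounded) error-inflated sample size: the slope
# at which n_x / rho^2 equals the target n. Independent of the closed form
# in mde_for_n().
bisect_mde <- function(sigma2_outcome, vc, n_target, m, test) {
  unrounded_n <- function(beta) {
    n_no_error(sigma2_outcome, beta, vc, test) /
      validity_coefficient(vc, m, squared = TRUE)
  }
  upper <- sqrt(sigma2_outcome / vc$sigma2_between) * (1 - 1e-9)
  uniroot(function(b) unrounded_n(b) - n_target,
          lower = 1e-8, upper = upper, tol = 1e-12)$root
}

# One simulated linear-regression study under the classical error model;
# returns the two-sided normal-theory p-value for the slope of outcome on
# the person-mean of m measurements.
simulate_linear_pvalue <- function(sigma2_outcome, beta, vc, n, m) {
  resid_sd <- sqrt(sigma2_outcome - beta^2 * vc$sigma2_between)
  x <- rnorm(n, 0, sqrt(vc$sigma2_between))
  w <- x + rnorm(n, 0, sqrt(vc$sigma2_within / m))
  y <- beta * x + rnorm(n, 0, resid_sd)
  co <- summary(lm(y ~ w))$coefficients
  2 * pnorm(-abs(co["w", "Estimate"] / co["w", "Std. Error"]))
}

sol_vc <- function() variance_components(0.21, 0.72)
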
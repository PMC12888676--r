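#' Type I error and power specification for a two-sided test
#'
#' @param alpha Two-sided Type I error rate, in (0, 1).
#' @param power Target power, in (0, 1), greater than `alpha`.
#' @return An object of class `test_spec`.
#' @details Convenience presets reflect common design practice:
#'   `test_spec_confirmatory()` uses alpha 0.01 with power 0.90 (evaluation
#'   of a previously suspected association), `test_spec_exploratory()` uses
#'   alpha 0.05 with power 0.80.
#' @examples
#' test_spec(alpha = 0.01, power = 0.90)
#' @export
test_spec <- function(alpha = 0.05, power = 0.80) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(power), length(power) == 1L,
            is.finite(alpha), is.finite(power))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  if (power <= alpha) stop("power must exceed alpha", call. = FALSE)
  structure(list(alpha = alpha, power = power), class = "test_spec")
}

#' @rdname test_spec
#' @export
test_spec_confirmatory <- function() test_spec(alpha = 0.01, power = 0.90)

#' @rdname test_spec
#' @export
test_spec_exploratory <- function() test_spec(alpha = 0.05, power = 0.80)

# sum of the two standard-normal quantiles driving all the sample-size
# arithmetic: z_{1-alpha/2} + z_{power}
z_total <- function(test) {
  stats::qnorm(1 - test$alpha / 2) + stats::qnorm(test$power)
}

check_linear_inputs <- function(sigma2_outcome, beta, vc) {
  stopifnot(is.numeric(sigma2_outcome), length(sigma2_outcome) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.finite(sigma2_outcome), is.finite(beta))
  if (sigma2_outcome <= 0) {
    stop("sigma2_outcome must be positive", call. = FALSE)
  }
  if (vc$sigma2_between <= 0) {
    stop("sigma2_between must be positive for design calculations",
         call. = FALSE)
  }
  if (beta^2 * vc$sigma2_between >= sigma2_outcome) {
    stop("beta^2 * sigma2_between must be smaller than sigma2_outcome ",
         "(residual outcome variance must be positive)", call. = FALSE)
  }
  invisible(NULL)
}

#' Subjects needed for a linear-regression slope with error-free exposure
#'
#' Number of subjects required to detect a true slope `beta` of a continuous
#' outcome on true (error-free) exposure at the given two-sided level and
#' power:
#' `n_x = (z_{1-alpha/2} + z_{power})^2 (sigma2_y - beta^2 sigma2_B) /
#' (beta^2 sigma2_B)`.
#' The numerator is the residual outcome variance once the exposure effect
#' is accounted for. Returned unrounded; it is the building block for
#' [n_with_error()].
#'
#' @param sigma2_outcome Marginal variance of the continuous outcome.
#' @param beta True (detectable) slope, outcome units per ln(exposure) unit.
#' @param vc A [variance_components()] object; only `sigma2_between` enters.
#' @param test A [test_spec()].
#' @return Required number of subjects, positive real.
#' @examples
#' n_no_error(1, 0.25, variance_components(0.21, 0.72),
#'            test_spec_confirmatory()) # 1118.8
#' @export
n_no_error <- function(sigma2_outcome, beta, vc, test = test_spec()) {
  vc <- as_vc(vc)
  check_linear_inputs(sigma2_outcome, beta, vc)
  z <- z_total(test)
  effect_var <- beta^2 * vc$sigma2_between
  z^2 * (sigma2_outcome - effect_var) / effect_var
}

#' Subjects needed when exposure is a person-mean of m noisy measurements
#'
#' Inflates the error-free sample size by the inverse squared validity
#' coefficient, `n_z = n_x / rho^2(m)`, and rounds to the nearest whole
#' subject (half away from zero). More repeats per person raise `rho^2` and
#' so shrink the required cohort.
#'
#' @inheritParams n_no_error
#' @param m Repeats per person, whole number at least 1.
#' @return Required number of subjects, positive integer.
#' @examples
#' vc <- variance_components(0.21, 0.72)
#' n_with_error(1, 0.25, vc, m = 1, test_spec_confirmatory()) # 4955
#' n_with_error(1, 0.25, vc, m = 2, test_spec_confirmatory()) # 3037
#' @export
n_with_error <- function(sigma2_outcome, beta, vc, m, test = test_spec()) {
  vc <- as_vc(vc)
  check_m(m, integer_only = TRUE)
  nx <- n_no_error(sigma2_outcome, beta, vc, test)
  rho2 <- validity_coefficient(vc, m, squared = TRUE)
  round_half_up(nx / rho2)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Minimum detectable slope for a fixed cohort and repeat schedule
#'
#' For a study of `n` subjects with `m` measurements per subject, the
#' smallest true slope detectable at the given level and power is
#' `beta_min = z_tot * sqrt(sigma2_y / (sigma2_B (n rho^2(m) + z_tot^2)))`
#' with `z_tot = z_{1-alpha/2} + z_{power}`: the exact algebraic inverse of
#' [n_with_error()] before rounding. Measurement error makes the detectable
#' effect larger than in an error-free study of the same size.
#'
#' @inheritParams n_with_error
#' @param n Number of subjects, whole number at least 2.
#' @return Minimum detectable slope, positive real, on the scale of outcome
#'   units per ln(exposure) unit.
#' @examples
#' mde_for_n(1, variance_components(0.21, 0.72), n = 1379, m = 1,
#'           test_spec_confirmatory()) # 0.466
#' @export
mde_for_n <- function(sigma2_outcome, vc, n, m, test = test_spec()) {
  vc <- as_vc(vc)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n))
  if (n < 2 || n != floor(n)) {
    stop("n must be a whole number of subjects, at least 2", call. = FALSE)
  }
  check_m(m, integer_only = TRUE)
  if (sigma2_outcome <= 0) {
    stop("sigma2_outcome must be positive", call. = FALSE)
  }
  if (vc$sigma2_between <= 0) {
    stop("sigma2_between must be positive for design calculations",
         call. = FALSE)
  }
  z <- z_total(test)
  rho2 <- validity_coefficient(vc, m, squared = TRUE)
  z * sqrt(sigma2_outcome / (vc$sigma2_between * (n * rho2 + z^2)))
}

#' Sample-size inflation due to within-person variability
#'
#' Ratio `n_z / n_x = 1 / rho^2 = (m icc + 1 - icc) / (m icc)` of the
#' subjects needed with error-prone exposure to the subjects needed with no
#' within-person variability (ICC = 1). Vectorised over both arguments via
#' [inflation_grid()].
#'
#' @param icc Intraclass correlation coefficient, in (0, 1\].
#' @param m Repeats per person, whole number at least 1.
#' @return Inflation ratio, at least 1.
#' @examples
#' sample_size_inflation(0.5, 1) # 2
#' @export
sample_size_inflation <- function(icc, m) {
  stopifnot(is.numeric(icc), length(icc) == 1L, is.finite(icc))
  if (icc <= 0) {
    stop("icc must be positive (icc = 0 implies infinite inflation)",
         call. = FALSE)
  }
  if (icc > 1) stop("icc cannot exceed 1", call. = FALSE)
  check_m(m, integer_only = TRUE)
  (m * icc + 1 - icc) / (m * icc)
}

#' @rdname sample_size_inflation
#' @param icc_values,m_values Vectors tabulated in long format, one row per
#'   combination.
#' @export
inflation_grid <- function(icc_values, m_values) {
  grid <- expand.grid(icc = icc_values, m = m_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$inflation <- mapply(sample_size_inflation, grid$icc, grid$m)
  grid
}

#' Power of a linear-regression design with error-prone exposure
#'
#' Achieved power for testing a true slope `beta` at two-sided level `alpha`
#' in a study of `n` subjects with `m` repeats per person:
#' `Phi(beta sqrt(n rho^2 sigma2_B / (sigma2_y - beta^2 sigma2_B)) -
#' z_{1-alpha/2})`. Inverse presentation of the same relationship as
#' [n_with_error()]: plugging its output back in returns at least the target
#' power.
#'
#' @inheritParams n_with_error
#' @param n Number of subjects, whole number at least 2.
#' @param alpha Two-sided Type I error rate.
#' @return Power in (0, 1).
#' @examples
#' power_for_design(1, 0.25, variance_components(0.21, 0.72),
#'                  n = 4955, m = 1, alpha = 0.01) # ~0.90
#' @export
power_for_design <- function(sigma2_outcome, beta, vc, n, m, alpha = 0.05) {
  vc <- as_vc(vc)
  check_linear_inputs(sigma2_outcome, beta, vc)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n >= 2)
  check_m(m, integer_only = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  rho2 <- validity_coefficient(vc, m, squared = TRUE)
  effect_var <- beta^2 * vc$sigma2_between
  ncp <- abs(beta) * sqrt(n * rho2 * vc$sigma2_between /
                            (sigma2_outcome - effect_var))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}
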
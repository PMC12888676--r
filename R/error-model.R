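#' Intraclass correlation coefficient of a biomarker
#'
#' The ICC is the between-person share of the total variance,
#' `sigma2_B / (sigma2_B + sigma2_W)`: the reliability of a single
#' measurement as a proxy for the person's true mean exposure.
#'
#' @param vc A [variance_components()] object.
#' @return ICC in \[0, 1\].
#' @examples
#' icc(variance_components(0.21, 0.72)) # 0.2258
#' @export
icc <- function(vc) {
  vc <- as_vc(vc)
  vc$sigma2_between / (vc$sigma2_between + vc$sigma2_within)
}

#' Validity coefficient of a person-mean of m measurements
#'
#' The validity coefficient rho is the correlation between a person's true
#' mean exposure and the mean of `m` measurements on that person:
#' `rho^2 = sigma2_B / (sigma2_B + sigma2_W / m)`. At `m = 1`, `rho^2`
#' equals the ICC; as `m` grows, rho approaches 1 because averaging wears
#' down the within-person noise.
#'
#' @inheritParams icc
#' @param m Repeats per person, at least 1. Fractional values are accepted
#'   so the function can be evaluated at the real-valued solution of
#'   [repeats_for_validity()].
#' @param squared If `TRUE`, return `rho^2` rather than rho.
#' @return rho (or rho squared) in (0, 1\].
#' @examples
#' validity_coefficient(variance_components(0.21, 0.72), m = 1) # 0.475
#' @export
validity_coefficient <- function(vc, m, squared = FALSE) {
  vc <- as_vc(vc)
  check_m(m)
  rho2 <- vc$sigma2_between / (vc$sigma2_between + vc$sigma2_within / m)
  if (squared) rho2 else sqrt(rho2)
}

#' Repeats per person needed for a target validity coefficient
#'
#' Inverts the validity-coefficient relation (Fleiss' reliability formula)
#' to find the number of repeated measurements per person needed so that the
#' person-mean correlates with the true mean at level `rho`:
#' `m = rho^2 (1 - ICC) / (ICC (1 - rho^2))`. The practical answer is the
#' ceiling of the real-valued solution (never below 1): collecting fewer
#' repeats than the real solution leaves the validity short of target.
#'
#' @param icc Intraclass correlation coefficient, strictly in (0, 1).
#' @param rho Desired validity coefficient, strictly in (0, 1). The
#'   boundaries are rejected: the formula diverges as `rho` approaches 1.
#' @return A list with `m_real` (exact real-valued solution) and `m_int`
#'   (smallest usable whole number of repeats, `max(1, ceiling(m_real))`).
#' @examples
#' repeats_for_validity(icc = 0.2, rho = 0.7) # m_real 3.84, m_int 4
#' @export
repeats_for_validity <- function(icc, rho) {
  stopifnot(is.numeric(icc), length(icc) == 1L, is.numeric(rho),
            length(rho) == 1L, is.finite(icc), is.finite(rho))
  if (icc <= 0 || icc >= 1) {
    stop("icc must lie strictly between 0 and 1", call. = FALSE)
  }
  if (rho <= 0 || rho >= 1) {
    stop("rho must lie strictly between 0 and 1", call. = FALSE)
  }
  rho2 <- rho^2
  m_real <- rho2 * (1 - icc) / (icc * (1 - rho2))
  list(m_real = m_real, m_int = max(1L, as.integer(ceiling(m_real - 1e-9))))
}

#' Attenuation factor of a linear-regression slope
#'
#' Under classical measurement error, regressing an outcome on the
#' person-mean of `m` noisy measurements shrinks the expected slope towards
#' zero by the factor `lambda = m sigma2_B / (m sigma2_B + sigma2_W)`
#' (regression dilution): the expected observed slope is `beta * lambda`.
#'
#' @inheritParams validity_coefficient
#' @return lambda in (0, 1\]. Equals `rho^2` of the person-mean.
#' @examples
#' attenuation_factor(variance_components(0.21, 0.72), m = 4) # 0.538
#' @export
attenuation_factor <- function(vc, m) {
  vc <- as_vc(vc)
  check_m(m)
  if (vc$sigma2_between == 0) {
    stop("attenuation is undefined when sigma2_between = 0", call. = FALSE)
  }
  m * vc$sigma2_between / (m * vc$sigma2_between + vc$sigma2_within)
}

#' Expected percent attenuation bias in a regression slope
#'
#' `(1 - lambda) * 100`: the percentage by which the expected slope from a
#' naive regression on the person-mean of `m` measurements falls short of
#' the true slope. At `m = 1` this is `(1 - ICC) * 100`.
#'
#' @inheritParams attenuation_factor
#' @return Percent bias in \[0, 100).
#' @examples
#' percent_bias(variance_components(0.21, 0.72), m = 4) # 46.15
#' @export
percent_bias <- function(vc, m) {
  100 * (1 - attenuation_factor(vc, m))
}

#' Repeats per person needed to cap the expected attenuation bias
#'
#' Smallest whole number of repeats `m` such that
#' [percent_bias()] does not exceed `bias_max` percent. Solved in closed
#' form: `m >= sigma2_W (100 - bias_max) / (sigma2_B * bias_max)`, then
#' rounded up.
#'
#' @inheritParams attenuation_factor
#' @param bias_max Maximum tolerable percent bias, strictly in (0, 100).
#' @return Smallest integer number of repeats meeting the bias cap.
#' @examples
#' repeats_for_max_bias(variance_components(0.21, 0.72), bias_max = 10) # 31
#' @export
repeats_for_max_bias <- function(vc, bias_max) {
  vc <- as_vc(vc)
  stopifnot(is.numeric(bias_max), length(bias_max) == 1L, is.finite(bias_max))
  if (bias_max <= 0 || bias_max >= 100) {
    stop("bias_max must lie strictly between 0 and 100 percent", call. = FALSE)
  }
  if (vc$sigma2_between == 0) {
    stop("attenuation is undefined when sigma2_between = 0", call. = FALSE)
  }
  m_real <- vc$sigma2_within * (100 - bias_max) /
    (vc$sigma2_between * bias_max)
  max(1L, as.integer(ceiling(m_real - 1e-9)))
}

#' Grid of expected percent attenuation bias over ICC and repeats
#'
#' Percent bias reparameterised by the ICC alone,
#' `(1 - ICC) / (1 - ICC + m * ICC) * 100`, tabulated over all combinations
#' of `icc_values` and `m_values` in long format. Useful to visualise how
#' quickly repeats buy down bias for a biomarker of a given reliability.
#'
#' @param icc_values Numeric vector of ICCs, each strictly in (0, 1).
#' @param m_values Vector of whole numbers of repeats, each at least 1.
#' @return A data.frame with columns `icc`, `m`, `percent_bias`, one row per
#'   combination (ICC varying fastest).
#' @examples
#' bias_grid(c(0.2, 0.5, 0.7), c(1, 2, 5))
#' @export
bias_grid <- function(icc_values, m_values) {
  stopifnot(is.numeric(icc_values), length(icc_values) >= 1L,
            is.numeric(m_values), length(m_values) >= 1L)
  if (any(!is.finite(icc_values)) || any(icc_values <= 0 | icc_values >= 1)) {
    stop("all ICC values must lie strictly between 0 and 1", call. = FALSE)
  }
  vapply(m_values, check_m, numeric(1), integer_only = TRUE)
  grid <- expand.grid(icc = icc_values, m = m_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$percent_bias <-
    (1 - grid$icc) / (1 - grid$icc + grid$m * grid$icc) * 100
  grid
}
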
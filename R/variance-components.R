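#' Between- and within-person variance components of an exposure biomarker
#'
#' Container for the two variance components of the classical measurement
#' error model on the (typically ln-transformed) biomarker scale: the variance
#' of true person-level mean exposures across the population
#' (`sigma2_between`) and the variance of single measurements around a
#' person's true mean (`sigma2_within`, temporal fluctuation plus assay
#' noise).
#'
#' @param sigma2_between Non-negative between-person variance (ln-scale
#'   units squared).
#' @param sigma2_within Non-negative within-person variance of one
#'   measurement (same units).
#'
#' @return An object of class `variance_components`.
#' @seealso [vc_from_icc()] to construct from an intraclass correlation and a
#'   total variance, [icc()], [validity_coefficient()], [attenuation_factor()].
#' @examples
#' variance_components(0.21, 0.72)
#' @export
variance_components <- function(sigma2_between, sigma2_within) {
  stopifnot(
    is.numeric(sigma2_between), length(sigma2_between) == 1L,
    is.numeric(sigma2_within), length(sigma2_within) == 1L,
    is.finite(sigma2_between), is.finite(sigma2_within)
  )
  if (sigma2_between < 0 || sigma2_within < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (sigma2_between + sigma2_within <= 0) {
    stop("at least one variance component must be positive", call. = FALSE)
  }
  structure(
    list(sigma2_between = sigma2_between, sigma2_within = sigma2_within),
    class = "variance_components"
  )
}

#' Variance components from an ICC and a total variance
#'
#' Pilot studies often report the intraclass correlation coefficient (ICC)
#' and the total variance rather than the components themselves. This
#' converts via `sigma2_between = icc * total` and
#' `sigma2_within = sigma2_between * (1 - icc) / icc`.
#'
#' When `total_is_between = TRUE` the supplied total variance is treated as
#' the between-person variance itself (a "best-case" reading used when a
#' published total cannot be decomposed); the within-person component is then
#' derived from the ICC on top of it.
#'
#' @param icc Intraclass correlation coefficient, in (0, 1).
#' @param total_variance Positive variance (ln-scale units squared).
#' @param total_is_between If `TRUE`, interpret `total_variance` as the
#'   between-person variance instead of the sum of both components.
#'
#' @return An object of class `variance_components`.
#' @examples
#' vc_from_icc(0.23, 0.93)
#' vc_from_icc(0.6, 0.019, total_is_between = TRUE)
#' @export
vc_from_icc <- function(icc, total_variance, total_is_between = FALSE) {
  stopifnot(is.numeric(icc), length(icc) == 1L, is.finite(icc))
  stopifnot(is.numeric(total_variance), length(total_variance) == 1L)
  if (icc <= 0 || icc >= 1) {
    stop("icc must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(total_variance) || total_variance <= 0) {
    stop("total_variance must be positive", call. = FALSE)
  }
  if (total_is_between) {
    s2b <- total_variance
  } else {
    s2b <- icc * total_variance
  }
  s2w <- s2b * (1 - icc) / icc
  variance_components(s2b, s2w)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Exposure variance components (ln scale)\n")
  cat(sprintf("  between-person sigma2_B: %.6g\n", x$sigma2_between))
  cat(sprintf("  within-person  sigma2_W: %.6g\n", x$sigma2_within))
  cat(sprintf("  ICC: %.4f\n", icc(x)))
  invisible(x)
}

# internal: accept a variance_components object or coerce a 2-list
as_vc <- function(vc) {
  if (inherits(vc, "variance_components")) return(vc)
  if (is.list(vc) && all(c("sigma2_between", "sigma2_within") %in% names(vc))) {
    return(variance_components(vc$sigma2_between, vc$sigma2_within))
  }
  stop("expected a 'variance_components' object; see variance_components()",
       call. = FALSE)
}

check_m <- function(m, integer_only = FALSE) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (m < 1) stop("m (repeats per person) must be at least 1", call. = FALSE)
  if (integer_only && m != floor(m)) {
    stop("m must be a whole number of repeats", call. = FALSE)
  }
  m
}
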
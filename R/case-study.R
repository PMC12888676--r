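#' Load the bundled case-study parameter sets
#'
#' Two published birth-cohort analyses are shipped as ready-made parameter
#' sets: a pregnancy cohort relating urinary bisphenols to fetal growth
#' (1,379 subjects, ln-scale exposure variance components 0.21 between /
#' 0.72 within) and a mother-child cohort relating urinary triclosan to
#' neurodevelopment (377 mothers / 184 boys, parameterised by ICC plus a
#' total ln-scale variance). They drive [run_case_report()] and serve as
#' realistic worked examples for every calculator.
#'
#' @param name Optional fixture name; omit to get the named list of all
#'   fixtures. One of `"sol_bisphenols"`, `"guo_triclosan_mothers"`,
#'   `"guo_triclosan_boys"`.
#' @param path Path to a fixtures YAML file; defaults to the copy installed
#'   with the package.
#' @return A `case_study_fixture` object (or a named list of them): label,
#'   `vc` ([variance_components()]), `n_actual`, `m_actual`,
#'   `sigma2_outcome`, `beta_design`, `icc_design`, `effects_reported` and
#'   the `source` notes.
#' @examples
#' case_study("sol_bisphenols")
#' names(case_study_fixtures())
#' @export
case_study_fixtures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "case-studies.yaml",
                        package = "biomonpower", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  fixtures <- lapply(names(raw), function(nm) {
    as_case_study_fixture(raw[[nm]], name = nm)
  })
  names(fixtures) <- names(raw)
  fixtures
}

#' @rdname case_study_fixtures
#' @export
case_study <- function(name, path = NULL) {
  fixtures <- case_study_fixtures(path)
  if (!name %in% names(fixtures)) {
    stop("unknown case study '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  }
  fixtures[[name]]
}

as_case_study_fixture <- function(x, name) {
  required <- c("label", "parameterization", "n_actual", "m_actual",
                "sigma2_outcome", "beta_design", "icc_design")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("fixture '", name, "' is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vc <- switch(
    x$parameterization,
    components = variance_components(x$sigma2_between, x$sigma2_within),
    icc_total = vc_from_icc(x$icc, x$total_variance,
                            total_is_between = isTRUE(x$total_is_between)),
    stop("fixture '", name, "' has unknown parameterization '",
         x$parameterization, "'", call. = FALSE)
  )
  stopifnot(x$n_actual >= 2, x$m_actual >= 1, x$sigma2_outcome > 0)
  structure(
    list(name = name, label = x$label, vc = vc,
         n_actual = as.integer(x$n_actual),
         m_actual = as.integer(x$m_actual),
         sigma2_outcome = x$sigma2_outcome,
         beta_design = x$beta_design,
         icc_design = as.numeric(unlist(x$icc_design)),
         effects_reported = x$effects_reported,
         source = x$source),
    class = "case_study_fixture"
  )
}

#' @export
print.case_study_fixture <- function(x, ...) {
  cat(sprintf("Case study: %s\n", x$label))
  cat(sprintf("  n = %d subjects, m = %d repeats; outcome variance %.4g\n",
              x$n_actual, x$m_actual, x$sigma2_outcome))
  print(x$vc)
  invisible(x)
}

#' Study-design report for a case study
#'
#' Re-evaluates a published study's design with every calculator in the
#' package: the repeats per person needed for validity coefficients 0.7 and
#' 0.9 (at each design ICC of the fixture), the expected percent attenuation
#' bias at the repeats the study actually used, the cohort sizes a
#' sufficiently powered study would need at 1, 2 and 10 repeats, and the
#' minimum detectable slope for the cohort actually enrolled at the same
#' repeat schedules.
#'
#' @param fixture A `case_study_fixture` from [case_study()], or a fixture
#'   name.
#' @param test A [test_spec()]; defaults to the confirmatory preset
#'   (alpha 0.01, power 0.90).
#' @param m_values Repeat schedules tabulated for sample size and MDE.
#' @param rho_values Target validity coefficients tabulated for the
#'   required-repeats section.
#' @return An object of class `case_study_report` with data.frame components
#'   `repeats_required`, `bias_at_actual`, `n_required`, `mde_at_actual`.
#' @examples
#' run_case_report("sol_bisphenols")
#' @export
run_case_report <- function(fixture, test = test_spec_confirmatory(),
                            m_values = c(1L, 2L, 10L),
                            rho_values = c(0.7, 0.9)) {
  if (is.character(fixture)) fixture <- case_study(fixture)
  stopifnot(inherits(fixture, "case_study_fixture"),
            inherits(test, "test_spec"))

  repeats <- expand.grid(icc = fixture$icc_design, rho = rho_values,
                         KEEP.OUT.ATTRS = FALSE)
  repeats <- repeats[order(repeats$icc, repeats$rho), , drop = FALSE]
  sol <- mapply(function(i, r) repeats_for_validity(i, r)$m_int,
                repeats$icc, repeats$rho)
  repeats$m_required <- as.integer(sol)
  rownames(repeats) <- NULL

  bias <- data.frame(
    m = fixture$m_actual,
    percent_bias = percent_bias(fixture$vc, fixture$m_actual)
  )

  n_req <- data.frame(
    m = as.integer(m_values),
    n_required = vapply(m_values, function(m) {
      n_with_error(fixture$sigma2_outcome, fixture$beta_design, fixture$vc,
                   m = m, test = test)
    }, integer(1))
  )

  mde <- data.frame(
    m = as.integer(m_values),
    mde = vapply(m_values, function(m) {
      mde_for_n(fixture$sigma2_outcome, fixture$vc, n = fixture$n_actual,
                m = m, test = test)
    }, numeric(1))
  )
  # detectable slope carries the sign of the design effect
  if (fixture$beta_design < 0) mde$mde <- -mde$mde

  structure(
    list(fixture = fixture, test = test,
         repeats_required = repeats,
         bias_at_actual = bias,
         n_required = n_req,
         mde_at_actual = mde),
    class = "case_study_report"
  )
}

#' @export
print.case_study_report <- function(x, ...) {
  f <- x$fixture
  cat(sprintf("Design report: %s\n", f$label))
  cat(sprintf("  (alpha = %.3g two-sided, power = %.2f)\n\n",
              x$test$alpha, x$test$power))
  cat("Repeats per person required for a target validity coefficient:\n")
  print(x$repeats_required, row.names = FALSE)
  cat(sprintf("\nExpected attenuation bias at the actual design (m = %d): %.1f%%\n",
              f$m_actual, x$bias_at_actual$percent_bias))
  cat(sprintf("\nSubjects required to detect slope %.3g (outcome variance %.3g):\n",
              f$beta_design, f$sigma2_outcome))
  print(x$n_required, row.names = FALSE)
  cat(sprintf("\nMinimum detectable slope with the actual n = %d:\n",
              f$n_actual))
  print(x$mde_at_actual, row.names = FALSE)
  invisible(x)
}

#' Flatten a case-study report to a long-format table
#'
#' @param x A `case_study_report`.
#' @param ... Unused.
#' @return A data.frame with columns `section`, `icc`, `rho`, `m`, `value`,
#'   suitable for TSV export.
#' @export
as.data.frame.case_study_report <- function(x, ...) {
  rr <- data.frame(section = "repeats_required",
                   icc = x$repeats_required$icc,
                   rho = x$repeats_required$rho,
                   m = NA_integer_,
                   value = as.numeric(x$repeats_required$m_required))
  bb <- data.frame(section = "bias_at_actual", icc = NA_real_,
                   rho = NA_real_, m = x$bias_at_actual$m,
                   value = x$bias_at_actual$percent_bias)
  nn <- data.frame(section = "n_required", icc = NA_real_, rho = NA_real_,
                   m = x$n_required$m,
                   value = as.numeric(x$n_required$n_required))
  mm <- data.frame(section = "mde_at_actual", icc = NA_real_, rho = NA_real_,
                   m = x$mde_at_actual$m, value = x$mde_at_actual$mde)
  rbind(rr, bb, nn, mm)
}
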
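#' Plot expected attenuation bias against ICC, by repeats per person
#'
#' Line plot of [bias_grid()]: one curve per number of repeats, with a
#' dashed reference line at the bias level commonly taken as the threshold
#' for adjusting estimates during analysis (10% by default).
#'
#' @param icc_values ICC grid (x axis).
#' @param m_values Repeat schedules, one line each.
#' @param threshold Horizontal reference line, percent; `NULL` to omit.
#' @return A ggplot object. Requires the ggplot2 package.
#' @export
plot_bias_grid <- function(icc_values = seq(0.05, 0.95, by = 0.05),
                           m_values = c(1L, 2L, 3L, 5L, 10L),
                           threshold = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  grid <- bias_grid(icc_values, m_values)
  grid$m <- factor(grid$m)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$icc,
                                          y = .data$percent_bias,
                                          colour = .data$m)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ICC of exposure biomarker",
                  y = "Expected bias in slope (%)",
                  colour = "Repeats (m)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot sample-size inflation against ICC, by repeats per person
#'
#' Line plot of [inflation_grid()]: how many times more subjects are needed
#' to keep the power of a design with no within-person variability
#' (ICC = 1), as a function of the biomarker's ICC and the number of
#' repeated measurements.
#'
#' @inheritParams plot_bias_grid
#' @return A ggplot object. Requires the ggplot2 package.
#' @export
plot_inflation_grid <- function(icc_values = seq(0.05, 0.95, by = 0.05),
                                m_values = c(1L, 2L, 3L, 5L, 10L)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  grid <- inflation_grid(icc_values, m_values)
  grid$m <- factor(grid$m)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$icc, y = .data$inflation,
                                     colour = .data$m)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ICC of exposure biomarker",
                  y = expression(n[z] / n[x]),
                  colour = "Repeats (m)") +
    ggplot2::theme_minimal()
}
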
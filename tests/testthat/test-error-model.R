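test_that("ICC and validity coefficient follow the variance-component arithmetic", {
  vc <- sol_vc()
  expect_equal(icc(vc), 0.21 / 0.93, tolerance = 1e-12)
  expect_equal(icc(variance_components(1, 3)), 0.25)
  expect_equal(icc(variance_components(0.5, 0)), 1)
  expect_equal(icc(variance_components(0, 0.5)), 0)

  # rho^2 at m = 1 is the ICC; rho itself is its square root
  expect_equal(validity_coefficient(vc, 1, squared = TRUE), icc(vc),
               tolerance = 1e-12)
  expect_equal(validity_coefficient(vc, 1), sqrt(0.21 / 0.93),
               tolerance = 1e-12)
  # frozen direct evaluations
  expect_equal(round(validity_coefficient(vc, 1, squared = TRUE), 4), 0.2258)
  expect_equal(round(validity_coefficient(vc, 1), 4), 0.4752)

  # no within-person noise: perfect validity for any m
  expect_equal(validity_coefficient(variance_components(0.3, 0), 5), 1)
  # averaging ever more repeats drives rho to 1
  expect_gt(validity_coefficient(vc, 1e6, squared = TRUE), 1 - 1e-5)
  # strictly increasing in m
  rho2 <- vapply(1:20, function(m) validity_coefficient(vc, m, TRUE),
                 numeric(1))
  expect_true(all(diff(rho2) > 0))
})

test_that("degenerate variance components are rejected", {
  expect_error(variance_components(0, 0), "positive")
  expect_error(variance_components(-0.1, 0.5), "non-negative")
  expect_error(validity_coefficient(sol_vc(), 0.5), "at least 1")
  expect_error(attenuation_factor(variance_components(0, 1), 2), "undefined")
  expect_error(icc("not a vc"), "variance_components")
})

test_that("required repeats for a target validity reproduce the published pairs", {
  # (icc, rho) -> required integer repeats, all eight published pairs
  cases <- data.frame(
    icc = c(0.2, 0.2, 0.3, 0.3, 0.4, 0.4, 0.6, 0.6),
    rho = rep(c(0.7, 0.9), 4),
    m = c(4L, 18L, 3L, 10L, 2L, 7L, 1L, 3L)
  )
  for (i in seq_len(nrow(cases))) {
    expect_identical(repeats_for_validity(cases$icc[i], cases$rho[i])$m_int,
                     cases$m[i])
  }
  expect_equal(repeats_for_validity(0.2, 0.7)$m_real, 3.843137,
               tolerance = 1e-6)
  # at rho^2 = ICC one measurement suffices exactly
  for (x in c(0.1, 0.35, 0.8)) {
    expect_equal(repeats_for_validity(x, sqrt(x))$m_real, 1,
                 tolerance = 1e-12)
  }
  expect_error(repeats_for_validity(0, 0.7), "strictly between")
  expect_error(repeats_for_validity(0.5, 1), "strictly between")
})

test_that("repeats formula and validity coefficient are mutual inverses", {
  # evaluating the validity at the unrounded solution recovers rho^2
  set.seed(4821)
  for (i in 1:50) {
    icc_i <- runif(1, 0.05, 0.95)
    rho_i <- runif(1, sqrt(icc_i), 0.995) # keep m_real >= 1
    m_real <- repeats_for_validity(icc_i, rho_i)$m_real
    vc <- vc_from_icc(icc_i, 1)
    expect_equal(validity_coefficient(vc, m_real, squared = TRUE), rho_i^2,
                 tolerance = 1e-9)
  }
})

test_that("attenuation factor and percent bias are complementary and monotone", {
  vc <- sol_vc()
  expect_equal(attenuation_factor(vc, 4), 0.84 / 1.56, tolerance = 1e-12)
  expect_equal(percent_bias(vc, 4), 100 * (1 - 0.84 / 1.56),
               tolerance = 1e-12)
  expect_equal(attenuation_factor(variance_components(0.4, 0), 3), 1)
  expect_equal(percent_bias(variance_components(0.4, 0), 7), 0)

  set.seed(902)
  for (i in 1:25) {
    vc_i <- variance_components(runif(1, 0.01, 2), runif(1, 0.01, 2))
    m_i <- sample(1:20, 1)
    expect_equal(percent_bias(vc_i, m_i) +
                   100 * attenuation_factor(vc_i, m_i), 100,
                 tolerance = 1e-10)
  }
  # bias falls with repeats, rises with within-person noise
  bias_m <- vapply(1:15, function(m) percent_bias(vc, m), numeric(1))
  expect_true(all(diff(bias_m) < 0))
  bias_w <- vapply(seq(0.1, 2, by = 0.1), function(w) {
    percent_bias(variance_components(0.21, w), 3)
  }, numeric(1))
  expect_true(all(diff(bias_w) > 0))
  expect_equal(percent_bias(vc, 1), (1 - icc(vc)) * 100, tolerance = 1e-12)
})

test_that("attenuation factor matches a brute-force regression oracle", {
  set.seed(70311)
  for (case in list(list(vc = sol_vc(), m = 2),
                    list(vc = variance_components(0.5, 0.25), m = 1),
                    list(vc = variance_components(0.1, 0.4), m = 5))) {
    mc <- mc_attenuation(case$vc, case$m, beta = 0.8, n_persons = 1e5)
    lambda <- attenuation_factor(case$vc, case$m)
    expect_lt(abs(mc$lambda_hat - lambda), 2 * mc$se)
  }
})

test_that("smallest m capping the expected bias agrees with a brute-force scan", {
  scan_m <- function(vc, bias_max) {
    Position(function(m) percent_bias(vc, m) <= bias_max, 1:4000)
  }
  expect_identical(repeats_for_max_bias(sol_vc(), 10), scan_m(sol_vc(), 10))
  expect_identical(repeats_for_max_bias(sol_vc(), 10), 31L)
  expect_identical(repeats_for_max_bias(variance_components(0.0095, 0.01425),
                                        10), 14L)
  expect_identical(repeats_for_max_bias(variance_components(0.3, 0.3), 50),
                   1L)
  set.seed(515)
  for (i in 1:20) {
    vc_i <- variance_components(runif(1, 0.05, 1), runif(1, 0.05, 1))
    b_i <- runif(1, 2, 80)
    expect_identical(repeats_for_max_bias(vc_i, b_i), scan_m(vc_i, b_i))
  }
  expect_error(repeats_for_max_bias(sol_vc(), 0), "strictly between")
  expect_error(repeats_for_max_bias(sol_vc(), 100), "strictly between")
})

test_that("bias grid matches the component formula and its limits", {
  grid <- bias_grid(c(0.2, 0.7), c(1L, 5L))
  expect_equal(nrow(grid), 4L)
  expect_equal(grid$percent_bias[grid$icc == 0.7 & grid$m == 5],
               0.3 / 3.8 * 100, tolerance = 1e-12)
  # m = 1 row reduces to (1 - ICC) * 100
  m1 <- bias_grid(seq(0.1, 0.9, 0.1), 1L)
  expect_equal(m1$percent_bias, (1 - m1$icc) * 100, tolerance = 1e-12)
  # near-perfect reliability: bias vanishes
  expect_lt(bias_grid(1 - 1e-9, 3L)$percent_bias, 1e-6)
  # agrees with percent_bias on components with matching ICC
  g <- bias_grid(0.23, 4L)
  expect_equal(g$percent_bias, percent_bias(vc_from_icc(0.23, 1.7), 4L),
               tolerance = 1e-10)
  expect_error(bias_grid(c(0.2, 1), 1L), "strictly between")
})
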
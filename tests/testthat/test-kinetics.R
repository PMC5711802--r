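test_that("exponential-with-drift fit recovers transient parameters", {
  # model identity, no drift
  tr <- simulate_folding_transient(a = 1, k_obs = 100, b = 0, c0 = 0.2,
                                   sigma = 0)
  fit <- fit_exponential_with_drift(tr)
  expect_sigfig(fit$k_obs, 100, 6)
  expect_sigfig(fit$a, 1, 6)

  # photobleaching-like drift, all 4 parameters
  tr_d <- simulate_folding_transient(a = 1, k_obs = 100, b = -0.01, c0 = 0.2,
                                     sigma = 0)
  fit_d <- fit_exponential_with_drift(tr_d)
  expect_sigfig(fit_d$a, 1, 4)
  expect_sigfig(fit_d$k_obs, 100, 4)
  expect_sigfig(fit_d$b, -0.01, 4)
  expect_sigfig(fit_d$c, 0.2, 4)

  # noisy fast transient: within 3 standard errors
  tr_n <- simulate_folding_transient(a = 1, k_obs = 500, b = -0.005, c0 = 0.2,
                                     sigma = 0.02, seed = 11)
  fit_n <- fit_exponential_with_drift(tr_n)
  expect_lt(abs(fit_n$k_obs - 500), 3 * fit_n$std_errors["k_obs"])

  # rising (unfolding) transients fit with negative amplitude
  tr_r <- simulate_folding_transient(a = -0.8, k_obs = 50, b = 0, c0 = 1,
                                     sigma = 0)
  expect_sigfig(fit_exponential_with_drift(tr_r)$k_obs, 50, 5)
})

test_that("short transients trigger a coverage warning, dead time is honoured", {
  slow <- simulate_folding_transient(a = 1, k_obs = 0.05, b = 0, c0 = 0,
                                     grid = seq(0.01, 10, length.out = 100),
                                     sigma = 0)
  expect_warning(fit_exponential_with_drift(slow), "relaxation times")
  tr <- simulate_folding_transient(a = 1, k_obs = 100, b = 0, c0 = 0.2,
                                   sigma = 0)
  fit <- fit_exponential_with_drift(tr, dead_time = 2e-3)
  expect_sigfig(fit$k_obs, 100, 4)
})

test_that("chevron model equals brute-force branch summation", {
  # oracle: sum the two exponential branches in linear space
  brute <- function(u, kf, ku, mf, mu, RT) {
    log10(kf * exp(-mf * u / RT) + ku * exp(mu * u / RT))
  }
  RT <- 1.987e-3 * 298
  u <- seq(0, 8, by = 0.5)
  cases <- list(c(10123, 4.67, 1.29, 0.22), c(3652, 12.16, 1.39, 0.28),
                c(13257, 3.28, 1.20, 0.23), c(50, 0.01, 2.5, 0.9))
  for (p in cases) {
    expect_equal(chevron_log10_kobs(u, p[1], p[2], p[3], p[4]),
                 brute(u, p[1], p[2], p[3], p[4], RT), tolerance = 1e-13)
  }
  # zero-denaturant limit
  expect_equal(10^chevron_log10_kobs(0, 10123, 4.67, 1.29, 0.22),
               10123 + 4.67, tolerance = 1e-12)
})

test_that("high-urea limb slope approaches the analytic unfolding slope", {
  RT <- 1.987e-3 * 298
  u <- seq(6.5, 8, by = 0.25)  # midpoint ~ 3.6 M, so u >= midpoint + 2
  lk <- chevron_log10_kobs(u, 10123, 4.67, 1.29, 0.22)
  slope <- stats::coef(stats::lm(lk ~ u))[2]
  expect_equal(unname(slope), 0.22 / (RT * log(10)), tolerance = 0.01)
})

test_that("chevron fit recovers all four parameters and the derived quantities", {
  cv <- simulate_chevron(k_f = 10123, k_u = 4.67, m_f = 1.29, m_u = 0.22,
                         sigma_log = 0)
  fit <- fit_chevron(cv)
  expect_sigfig(fit$k_f, 10123, 3)
  expect_sigfig(fit$k_u, 4.67, 3)
  expect_sigfig(fit$m_TS_D, 1.29, 3)
  expect_sigfig(fit$m_TS_N, 0.22, 3)
  expect_equal(fit$derived$m_kin_sum, fit$m_TS_D + fit$m_TS_N)
  expect_equal(fit$derived$beta_T, tanford_beta(fit$m_TS_D, fit$m_TS_N))
  # the fitted chevron is convex in log space with an interior minimum
  u <- seq(0.5, 8, length.out = 100)
  lk <- chevron_log10_kobs(u, fit$k_f, fit$k_u, fit$m_TS_D, fit$m_TS_N)
  expect_true(all(diff(lk, differences = 2) > -1e-10))
  expect_true(which.min(lk) > 1 && which.min(lk) < length(u))

  # noisy round trip within 3 standard errors
  cvn <- simulate_chevron(k_f = 10123, k_u = 4.67, m_f = 1.29, m_u = 0.22,
                          sigma_log = 0.02, seed = 3)
  fn <- fit_chevron(cvn)
  expect_lt(abs(fn$m_TS_D - 1.29), 3 * fn$std_errors["m_TS_D"])
  expect_lt(abs(log(fn$k_f / 10123)), 3 * fn$std_errors["k_f"] / fn$k_f * 1.5)
})

test_that("single-limb chevron data are rejected as under-determined", {
  u <- seq(4, 8, length.out = 8)
  lk <- chevron_log10_kobs(u, 10123, 4.67, 1.29, 0.22)
  expect_error(fit_chevron(chevron_dataset(u, 10^lk)),
               class = "fk_underdetermined_fit")
})

test_that("dG_from_rates and tanford_beta match published arithmetic and are scale-invariant", {
  expect_equal(round(dG_from_rates(10123, 4.67), 2), 4.55)
  expect_equal(round(dG_from_rates(13257, 3.28), 2), 4.92)
  expect_equal(dG_from_rates(7, 7), 0)
  expect_error(dG_from_rates(-1, 2), class = "fk_invalid_input")

  expect_equal(round(tanford_beta(1.29, 0.22), 2), 0.85)
  expect_equal(round(tanford_beta(1.39, 0.28), 2), 0.83)
  expect_equal(tanford_beta(1.2, 0), 1)
  expect_error(tanford_beta(0, 0), class = "fk_invalid_input")

  for (c_scale in c(0.1, 3, 100)) {
    expect_equal(dG_from_rates(10123 * c_scale, 4.67 * c_scale),
                 dG_from_rates(10123, 4.67))
    expect_equal(tanford_beta(1.29 * c_scale, 0.22 * c_scale),
                 tanford_beta(1.29, 0.22))
  }
})

test_that("consistency report flags two-state agreement", {
  # published Lh values: m discrepancy ~ 8.3 %
  rep_lh <- consistency_report(list(dG = 5.07, m = 1.64),
                               list(dG = 4.55, m_sum = 1.29 + 0.22))
  expect_equal(unname(rep_lh$rel_discrepancy["m"]),
               abs(1.64 - 1.51) / mean(c(1.64, 1.51)))
  expect_true(rep_lh$consistent)
  # published Nc values: dG discrepancy ~ 2.9 %
  rep_nc <- consistency_report(list(dG = 3.48, m = 1.59),
                               list(dG = 3.38, m_sum = 1.39 + 0.28))
  expect_equal(unname(rep_nc$rel_discrepancy["dG"]),
               abs(3.48 - 3.38) / mean(c(3.48, 3.38)))
  expect_true(rep_nc$consistent)
  # identical parameter sets: zero discrepancy
  rep0 <- consistency_report(list(dG = 4.5, m = 1.5),
                             list(dG = 4.5, m_sum = 1.5))
  expect_equal(unname(rep0$rel_discrepancy), c(0, 0))
  # gross disagreement is flagged
  expect_false(consistency_report(list(dG = 5, m = 1.5),
                                  list(dG = 2, m_sum = 1.5))$consistent)
})
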
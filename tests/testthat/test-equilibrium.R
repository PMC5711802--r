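test_that("two_state_signal matches direct evaluation of the closed form", {
  # independent oracle: literal transcription of the two-state observable
  direct <- function(P, dG, b, RT) {
    (b[1] + b[2] * P + (b[3] + b[4] * P) * exp(-dG / RT)) / (1 + exp(-dG / RT))
  }
  RT <- 1.987e-3 * 298
  b <- c(1, -0.01, 0.2, -0.005)
  dG <- 5.07 - 1.64 * 2.0
  expect_equal(two_state_signal(2.0, dG, b), direct(2.0, dG, b, RT),
               tolerance = 1e-12)
  # grid of parameter sets
  for (m in c(0.5, 1.6, 3)) {
    for (mid in c(1, 3, 6)) {
      P <- seq(0, 8, length.out = 17)
      dGs <- m * (mid - P)
      expect_equal(two_state_signal(P, dGs, b), direct(P, dGs, b, RT),
                   tolerance = 1e-12)
    }
  }
})

test_that("two_state_signal limits: midpoint, native limit, numerical stability", {
  flat <- c(1, 0, 0, 0)
  expect_equal(two_state_signal(3.09, 0, flat), 0.5)
  expect_equal(two_state_signal(0, 10, flat), 1.0, tolerance = 1e-6)
  # |dG/RT| ~ 800: no overflow, clean saturation to the baselines
  big <- two_state_signal(c(0, 8), c(500, -500), flat)
  expect_equal(big, c(1, 0), tolerance = 1e-12)
  expect_error(two_state_signal(1, NaN, flat), class = "fk_invalid_input")
})

test_that("Gibbs-Helmholtz free energy vanishes at Tm and has the van't Hoff limit", {
  for (dHm in c(30, 54.8, 80)) {
    for (dCp in c(0, 1.8, 3)) {
      expect_equal(dG_gibbs_helmholtz(329.9, dHm, 329.9, dCp), 0)
    }
  }
  T <- seq(280, 360, by = 5)
  expect_equal(dG_gibbs_helmholtz(T, 54.8, 329.9, 0), 54.8 * (1 - T / 329.9),
               tolerance = 1e-12)
})

test_that("chemical denaturation fit recovers generating parameters", {
  # noise-free: published Lh CD scenario, 4 significant figures
  curve <- simulate_chemical_curve(m = 1.64, midpoint = 3.09,
                                   baselines = c(1, -0.005, 0.1, -0.002),
                                   sigma = 0)
  fit <- fit_chemical_denaturation(curve)
  expect_sigfig(fit$m_DN, 1.64, 4)
  expect_sigfig(fit$urea50, 3.09, 4)
  expect_equal(fit$dG_DN, fit$m_DN * fit$urea50)  # identity by construction

  # published Nc CD scenario: dG rounds to 3.48 kcal/mol
  fit_nc <- fit_chemical_denaturation(
    simulate_chemical_curve(m = 1.59, midpoint = 2.19, sigma = 0))
  expect_equal(round(fit_nc$dG_DN, 2), 3.48)

  # noisy: recovered m within 3 fitted standard errors of truth
  noisy <- simulate_chemical_curve(m = 1.64, midpoint = 3.09, sigma = 0.01,
                                   seed = 42)
  fit_n <- fit_chemical_denaturation(noisy)
  expect_lt(abs(fit_n$m_DN - 1.64), 3 * fit_n$std_errors["m"])
  expect_lt(abs(fit_n$urea50 - 3.09), 3 * fit_n$std_errors["mid"])
})

test_that("chemical fit is accurate across the physiological parameter range", {
  for (m in c(0.5, 1.5, 3)) {
    for (mid in c(1.2, 3.5, 6)) {
      curve <- simulate_chemical_curve(m = m, midpoint = mid, sigma = 0,
                                       grid = seq(0, 8, length.out = 41))
      fit <- fit_chemical_denaturation(curve)
      expect_sigfig(fit$m_DN, m, 4)
      expect_sigfig(fit$urea50, mid, 4)
    }
  }
})

test_that("degenerate (transition-free) curves are rejected by the AIC gate", {
  P <- seq(0, 8, length.out = 33)
  set.seed(100)
  curve <- denaturation_curve(P, 1 - 0.05 * P + rnorm(33, 0, 0.01),
                              mode = "chemical")
  expect_error(fit_chemical_denaturation(curve), class = "fk_fit_failure")
  expect_error(fit_chemical_denaturation(curve),
               "no resolvable two-state transition|did not converge")
})

test_that("thermal denaturation fit recovers enthalpy and melting temperature", {
  melt <- simulate_thermal_curve(dHm = 54.8, Tm = 329.9, n_residues = 130,
                                 sigma = 0)
  fit <- fit_thermal_denaturation(melt, n_residues = 130)
  expect_sigfig(fit$dH_m, 54.8, 3)
  expect_sigfig(fit$T_m, 329.9, 4)
  expect_equal(fit$dCp, 0.014 * 130)
  # dG at the fitted midpoint is zero by definition
  expect_equal(dG_gibbs_helmholtz(fit$T_m, fit$dH_m, fit$T_m, fit$dCp), 0)

  noisy <- simulate_thermal_curve(dHm = 67.5, Tm = 337.0, n_residues = 130,
                                  sigma = 0.01, seed = 7)
  fit_n <- fit_thermal_denaturation(noisy, n_residues = 130)
  expect_lt(abs(fit_n$dH_m - 67.5), 3 * fit_n$std_errors["dHm"])
  expect_lt(abs(fit_n$T_m - 337.0), 3 * fit_n$std_errors["Tm"])

  expect_error(fit_thermal_denaturation(melt), class = "fk_invalid_input")
})

test_that("dG derivation and error propagation follow the stated arithmetic", {
  expect_equal(round(dG_from_m_and_midpoint(1.64, 3.09), 2), 5.07)
  expect_equal(round(dG_from_m_and_midpoint(1.67, 2.18), 2), 3.64)
  expect_equal(dG_from_m_and_midpoint(0, 5), 0)

  expect_equal(propagate_dG_error(1.64, 3.09, 0.04, 0.01),
               sqrt((3.09 * 0.04)^2 + (1.64 * 0.01)^2))
  expect_equal(round(propagate_dG_error(1.64, 3.09, 0.04, 0.01), 3), 0.125)
  expect_equal(propagate_dG_error(1.64, 3.09, 0, 0), 0)
  # positive covariance only inflates the propagated error
  expect_lte(propagate_dG_error(1.64, 3.09, 0.04, 0.01),
             propagate_dG_error(1.64, 3.09, 0.04, 0.01, cov_m_mid = 1e-4))
  expect_error(propagate_dG_error(1.64, 3.09, 0.04, 0.01, cov_m_mid = -1),
               class = "fk_numerical_error")
})

test_that("Schellman midpoint-shift conversion is proportional", {
  expect_equal(schellman_ddG(54.8, 329.9, 0), 0)
  expect_equal(schellman_ddG(54.8, 329.9, 5.0), 54.8 / 329.9 * 5.0)
  expect_equal(round(schellman_ddG(54.8, 329.9, 5.0), 4), 0.8306)
  expect_gt(schellman_ddG(54.8, 329.9, 2), 0)
  expect_lt(schellman_ddG(54.8, 329.9, -2), 0)
})

test_that("folded-fraction normalization inverts the baselines", {
  curve <- simulate_chemical_curve(m = 1.64, midpoint = 3.09,
                                   baselines = c(1, -0.005, 0.1, -0.002),
                                   grid = seq(0, 8, length.out = 41), sigma = 0)
  fit <- fit_chemical_denaturation(curve)
  fN <- folded_fraction(curve, fit)
  # noise-free model data map onto the two-state population exactly
  pop <- stats::plogis(1.64 * (3.09 - curve$perturbation) / (1.987e-3 * 298))
  expect_equal(fN, pop, tolerance = 1e-6)
  # round trip: refit the normalized curve, same m and midpoint
  norm_curve <- denaturation_curve(curve$perturbation, fN, mode = "chemical")
  fit2 <- fit_chemical_denaturation(norm_curve)
  expect_sigfig(fit2$m_DN, fit$m_DN, 4)
  expect_sigfig(fit2$urea50, fit$urea50, 4)

  # coincident baselines are flagged
  fit_flat <- fit
  fit_flat$baselines <- c(alpha_N = 1, beta_N = 0, alpha_D = 1, beta_D = 0)
  expect_error(folded_fraction(curve, fit_flat),
               class = "fk_degenerate_normalization")
})
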
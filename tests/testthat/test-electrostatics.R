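test_that("thermal series convert to stability changes via Schellman", {
  s <- salt_series(c(0.041, 0.2, 1.0), Tm = c(329.9, 333.9, 340.2),
                   dHm = 54.8, source = "thermal")
  ddG <- thermal_series_to_ddG(s)
  expect_equal(ddG$dG[1], 0)  # reference point anchors at zero
  expect_equal(ddG$dG[2], 54.8 / 329.9 * 4.0)  # Schellman hand arithmetic
  expect_true(all(diff(ddG$dG) > 0))  # monotone Tm implies monotone ddG
  expect_error(
    thermal_series_to_ddG(salt_series(c(0.041, 0.2, 1.0),
                                      Tm = c(329.9, 333.9, 340.2),
                                      dHm = c(NA, 54, 54), source = "thermal")),
    class = "fk_invalid_input")
})

test_that("Debye-Hueckel slope fit matches the closed-form normal equations", {
  I <- c(0.041, 0.1, 0.2, 0.5, 1.0)
  s <- simulate_salt_series(m_eq_prime = 3.5, intercept = 2.0,
                            ionic_strength = I, sigma = 0)
  fit <- fit_debye_huckel_slope(s)
  expect_equal(fit$m_eq_prime, 3.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.0, tolerance = 1e-12)

  # oracle: normal equations solved directly
  noisy <- simulate_salt_series(m_eq_prime = 3.5, intercept = 2.0,
                                ionic_strength = I, sigma = 0.1, seed = 9)
  fit_n <- fit_debye_huckel_slope(noisy)
  X <- cbind(1, sqrt(I))
  beta <- solve(t(X) %*% X, t(X) %*% noisy$dG)
  expect_equal(fit_n$intercept, beta[1, 1], tolerance = 1e-12)
  expect_equal(fit_n$m_eq_prime, beta[2, 1], tolerance = 1e-12)
  # 0.1 kcal/mol noise on 5 points: slope constrained to a few tenths
  expect_lt(abs(fit_n$m_eq_prime - 3.5), 0.5)

  # flat stability: zero slope
  flat <- salt_series(I, dG = rep(4.2, 5))
  expect_equal(fit_debye_huckel_slope(flat)$m_eq_prime, 0, tolerance = 1e-12)

  expect_error(salt_series(c(0.1, 0.2), dG = c(1, 2)),
               class = "fk_invalid_input")
})

test_that("changing the ddG reference shifts the intercept, not the slope", {
  s <- salt_series(c(0.041, 0.1, 0.2, 0.5, 1.0),
                   Tm = c(329.9, 331.5, 333.4, 336.9, 340.0),
                   dHm = 54.8, source = "thermal")
  fit1 <- fit_debye_huckel_slope(thermal_series_to_ddG(s, reference = 1L))
  fit3 <- fit_debye_huckel_slope(thermal_series_to_ddG(s, reference = 3L))
  expect_equal(fit1$m_eq_prime, fit3$m_eq_prime, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(fit1$intercept, fit3$intercept)))
})

test_that("homologue summary averages the published slopes", {
  slopes <- c(Ea = 3.6, Nc = 3.4, Lh = 3.5, Lg = 3.4)
  sm <- homologue_summary(slopes)
  expect_equal(sm$mean, 3.475)
  expect_equal(round(sm$mean, 1), 3.5)
  expect_equal(sm$sem, stats::sd(slopes) / 2)
  # single fit: no SEM
  expect_true(is.na(homologue_summary(c(Lh = 3.5))$sem))
  # permutation invariance of the mean
  expect_equal(homologue_summary(rev(slopes))$mean, sm$mean)
})

test_that("full salt pipeline recovers the generating slope from melts", {
  melts <- simulate_salt_melts(m_eq_prime = 3.5, dHm = 54.8, Tm_ref = 329.9,
                               n_residues = 130, sigma = 0)
  truth <- attr(melts, "truth")
  fits <- lapply(melts, fit_thermal_denaturation, n_residues = 130)
  s <- salt_series(truth$ionic_strength,
                   Tm = vapply(fits, function(f) f$T_m, numeric(1)),
                   dHm = fits[[1]]$dH_m, source = "thermal")
  slope <- fit_debye_huckel_slope(thermal_series_to_ddG(s))$m_eq_prime
  expect_equal(slope, 3.5, tolerance = 1e-3)
})
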
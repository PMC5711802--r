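test_that("dimer_signal evaluates the second-order closed form", {
  expect_equal(dimer_signal(0, S0 = 1, S_amp = -0.5, k_app = 200), 1)
  expect_equal(dimer_signal(1 / 200, S0 = 1, S_amp = -0.5, k_app = 200),
               1 - 0.25)
  expect_equal(dimer_signal(0.01, S0 = 1, S_amp = -0.5, k_app = 200),
               1 - 0.5 * 2 / 3)
  t <- exp(seq(log(1e-4), log(100), length.out = 200))
  s <- dimer_signal(t, 0.2, 0.8, 50)
  expect_true(all(diff(s) > 0))
  expect_equal(s[length(s)], 0.2 + 0.8, tolerance = 1e-3)
  expect_error(dimer_signal(-1, 1, 1, 1), class = "fk_invalid_input")
})

test_that("closed form agrees with numerical ODE integration for both conventions", {
  for (sf in c(1, 2)) {
    k_ass <- 2.19e9
    c0 <- 1e-7
    k_app <- sf * c0 * k_ass
    times <- c(0, exp(seq(log(1e-5), log(10 / k_app), length.out = 60)))
    sol <- deSolve::ode(y = c(N = c0), times = times,
                        func = function(t, y, p) list(-sf * k_ass * y[1]^2),
                        parms = NULL, rtol = 1e-10, atol = 1e-16)
    # signal proportional to the dimerized fraction of monomers
    s_ode <- 1 - 0.5 * (c0 - sol[, "N"]) / c0
    s_closed <- dimer_signal(times, S0 = 1, S_amp = -0.5, k_app = k_app)
    expect_lt(max(abs(s_closed - s_ode) / abs(s_ode)), 1e-6)
  }
})

test_that("association fit recovers the bimolecular rate constant", {
  # published Lh scenario: k_ass = 2.19e9 1/(M s) at 100 nM post-mix
  tr <- simulate_association_transient(k_ass = 2.19e9, c_N = 1e-7, sigma = 0)
  fit <- fit_association(tr, c_N = 1e-7)
  expect_sigfig(fit$k_app, 219, 4)
  expect_sigfig(fit$k_ass, 2.19e9, 3)
  expect_equal(fit$k_app, fit$c_N * fit$k_ass)  # identity by construction

  # published Ea scenario at 500 nM
  tr_ea <- simulate_association_transient(k_ass = 1.58e9, c_N = 5e-7, sigma = 0)
  expect_sigfig(fit_association(tr_ea, c_N = 5e-7)$k_ass, 1.58e9, 4)

  # doubling the concentration doubles k_app but not k_ass
  tr2 <- simulate_association_transient(k_ass = 2.19e9, c_N = 2e-7, sigma = 0)
  fit2 <- fit_association(tr2, c_N = 2e-7)
  expect_sigfig(fit2$k_app, 2 * fit$k_app, 4)
  expect_sigfig(fit2$k_ass, fit$k_ass, 4)

  # monomer-loss stoichiometric convention halves the inferred k_ass
  fit_s2 <- fit_association(tr, c_N = 1e-7, stoichiometry_factor = 2)
  expect_equal(fit_s2$k_ass, fit$k_ass / 2)

  expect_error(fit_association(tr, c_N = 0), class = "fk_invalid_input")
})

test_that("dissociation fit recovers the chasing rate constant", {
  for (k in c(0.31, 1.88)) {
    tr <- simulate_dissociation_transient(k_diss = k, sigma = 0)
    expect_sigfig(fit_dissociation(tr)$k_diss, k, 5)
  }
  tr_n <- simulate_dissociation_transient(k_diss = 0.64, sigma = 0.02, seed = 5)
  fit_n <- fit_dissociation(tr_n)
  expect_lt(abs(fit_n$k_diss - 0.64), 3 * fit_n$std_errors["k_diss"])

  # zero amplitude: rate unidentifiable
  flat <- kinetic_transient(seq(0, 10, length.out = 50), rep(0.5, 50),
                            experiment = "dissociation")
  expect_error(suppressWarnings(fit_dissociation(flat)),
               class = "fk_fit_failure")
  # falling transient: warn, wrong experiment suspected
  fall <- simulate_folding_transient(a = 0.5, k_obs = 1, b = 0, c0 = 0.2,
                                     grid = seq(0.01, 10, length.out = 100),
                                     sigma = 0)
  fall$meta$experiment <- "dissociation"
  expect_warning(try(fit_dissociation(fall), silent = TRUE), "does not rise")
})

test_that("K_d derivation and error propagation", {
  expect_equal(round(compute_Kd(0.31, 2.19e9)$K_d * 1e9, 2), 0.14)
  expect_equal(compute_Kd(5, 5)$K_d, 1)  # unit ratio is 1 M
  kd <- compute_Kd(0.31, 2.19e9, se_k_diss = 0.02, se_k_ass = 0.30e9)
  expect_equal(kd$se,
               kd$K_d * sqrt((0.02 / 0.31)^2 + (0.30 / 2.19)^2))
  expect_error(compute_Kd(0, 1e9), class = "fk_invalid_input")
})

test_that("post-mix concentration follows the volumetric ratio convention", {
  expect_equal(postmix_concentration(1.2e-6, "1:11"), 1e-7)
  expect_equal(postmix_concentration(1e-6, "1:1"), 5e-7)
  expect_error(postmix_concentration(1e-6, "oops"), class = "fk_invalid_input")
})
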
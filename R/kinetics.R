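#' Fit a single-exponential transient with linear baseline drift
#'
#' Stopped-flow folding/unfolding traces are fitted to
#' \eqn{S(t) = a\,e^{-k_{obs} t} + b t + c}: a single relaxation plus a slow
#' linear drift (photobleaching, sample diffusion in the mixing zone). The
#' initial rate guess comes from a log-linear regression of
#' \eqn{|S - \bar S_{tail}|} over the early trace; the amplitude sign is
#' free, so decays (refolding) and rises (unfolding) are handled alike.
#'
#' @param transient A [kinetic_transient()].
#' @param dead_time Instrument dead time (s); points earlier than this are
#'   excluded before fitting. Default 0.
#' @param n_starts Maximum number of jittered starts.
#'
#' @return An object of class `exponential_fit` with `a` (amplitude),
#'   `k_obs` (1/s), drift `b` (signal/s), offset `c`, `std_errors`,
#'   `covariance` and residual diagnostics. A warning is issued when the
#'   trace covers less than 3 relaxation times.
#' @examples
#' tr <- simulate_folding_transient(a = 1, k_obs = 100, b = -0.01, c0 = 0.2,
#'                                  sigma = 0)
#' fit <- fit_exponential_with_drift(tr)
#' fit$k_obs
#' @export
fit_exponential_with_drift <- function(transient, dead_time = 0, n_starts = 5L) {
  if (!inherits(transient, "kinetic_transient"))
    fk_invalid_input("fit_exponential_with_drift needs a kinetic_transient")
  keep <- transient$time >= dead_time
  t <- transient$time[keep]
  S <- transient$signal[keep]
  if (length(t) < 5L)
    fk_invalid_input("need at least 5 points after dead-time exclusion")
  # tail mean approximates b*t + c at late times; its excess decays as |a| e^-kt
  n_tail <- max(3L, floor(length(t) / 10))
  tail_mean <- mean(S[seq(length(S) - n_tail + 1L, length(S))])
  excess <- abs(S - tail_mean)
  early <- which(excess > max(excess) * 0.05)
  early <- early[seq_len(min(length(early), max(5L, floor(length(t) / 3))))]
  lf <- stats::lm(log(pmax(excess[early], 1e-12)) ~ t[early])
  k0 <- max(-unname(stats::coef(lf)[2]), 1 / max(diff(range(t)), 1e-12))
  a0 <- S[1] - tail_mean
  if (a0 == 0) a0 <- max(excess)
  start <- list(a = a0, k = k0, b = 0, c0 = tail_mean)
  fit <- fk_fit_nls(S ~ a * exp(-k * t) + b * t + c0,
                    data = data.frame(t = t, S = S), start = start,
                    lower = c(a = -Inf, k = 1e-12, b = -Inf, c0 = -Inf),
                    n_starts = n_starts, context = "exponential transient")
  fs <- fk_fit_summary(fit)
  k_obs <- unname(fs$par["k"])
  if (max(t) - t[1] < 3 / k_obs)
    warning(sprintf("transient covers only %.2f relaxation times (< 3); k_obs poorly constrained",
                    (max(t) - t[1]) * k_obs))
  structure(list(a = unname(fs$par["a"]), k_obs = k_obs,
                 b = unname(fs$par["b"]), c = unname(fs$par["c0"]),
                 std_errors = c(a = unname(fs$se["a"]), k_obs = unname(fs$se["k"]),
                                b = unname(fs$se["b"]), c = unname(fs$se["c0"])),
                 covariance = fs$cov, residual_norm = sqrt(fs$deviance),
                 fitted = fs$fitted, residuals = fs$residuals,
                 dead_time = dead_time, transient = transient),
            class = c("exponential_fit", "fk_fit"))
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Single-exponential fit: k_obs = %.4g +/- %.2g 1/s (a = %.3g, drift b = %.3g/s)\n",
              x$k_obs, x$std_errors["k_obs"], x$a, x$b))
  invisible(x)
}

#' Chevron model for the observed relaxation rate
#'
#' The barrier-limited two-state chevron,
#' \deqn{\log k_{obs}([urea]) = \log[k_f e^{-m_{TS-D}[urea]/RT} +
#'   k_u e^{+m_{TS-N}[urea]/RT}],}
#' evaluated in log10 space via a log-sum-exp formulation that cannot
#' overflow for large m-values or urea concentrations.
#'
#' @param urea Urea concentrations (M).
#' @param k_f,k_u Folding and unfolding rate constants in water (1/s).
#' @param m_f,m_u Kinetic m-values \eqn{m_{TS-D}} and \eqn{m_{TS-N}},
#'   kcal/(mol M), both positive for a canonical chevron.
#' @param temperature Temperature (K).
#' @param R Gas constant, kcal/(mol K).
#' @return log10 of the observed rate constant, same length as `urea`.
#' @export
chevron_log10_kobs <- function(urea, k_f, k_u, m_f, m_u,
                               temperature = 298, R = 1.987e-3) {
  RT <- R * temperature
  lf <- log(k_f) - m_f * urea / RT
  lu <- log(k_u) + m_u * urea / RT
  hi <- pmax(lf, lu)
  (hi + log1p(exp(pmin(lf, lu) - hi))) / log(10)
}

#' Chevron analysis of folding kinetics
#'
#' Fits the four-parameter two-state chevron ([chevron_log10_kobs()]) to
#' observed rate constants versus denaturant. Residuals are computed in
#' log10(k_obs) space, which equalizes the influence of the two limbs when
#' rates span several orders of magnitude. Rates are parameterized on the
#' log scale internally (positivity for free); standard errors for `k_f` and
#' `k_u` are delta-method transforms of the log-scale errors. Initial
#' guesses come from log-linear fits to the points on either side of the
#' empirical minimum.
#'
#' @param data A [chevron_dataset()]; both limbs must be sampled (at least
#'   2 points on each side of the empirical minimum).
#' @param constants A [fk_constants()] list; RT is evaluated at the
#'   dataset's temperature.
#' @param n_starts Maximum number of jittered starts.
#'
#' @return An object of class `chevron_fit`: `k_f`, `k_u` (1/s), `m_TS_D`,
#'   `m_TS_N` (kcal/(mol M)), `std_errors`, `covariance` (log-scale rates),
#'   and a `derived` list with `dG_kin` ([dG_from_rates()]), `beta_T`
#'   ([tanford_beta()]) and `m_kin_sum = m_TS_D + m_TS_N`.
#' @examples
#' cv <- simulate_chevron(k_f = 10123, k_u = 4.67, m_f = 1.29, m_u = 0.22,
#'                        sigma_log = 0)
#' fit <- fit_chevron(cv)
#' fit$derived$beta_T
#' @export
fit_chevron <- function(data, constants = fk_constants(), n_starts = 5L) {
  if (!inherits(data, "chevron_dataset"))
    fk_invalid_input("fit_chevron needs a chevron_dataset")
  u <- data$urea
  lk <- log10(data$k_obs)
  i_min <- which.min(lk)
  if (i_min < 3L || i_min > length(u) - 2L)
    fk_stop(c("fk_underdetermined_fit", "fk_fit_failure"),
            "chevron minimum not bracketed: need at least 2 points on each limb")
  Rgas <- constants$R
  temp <- data$temperature
  RT <- Rgas * temp
  ln10 <- log(10)
  fold <- seq_len(i_min)
  unf <- seq(i_min, length(u))
  cf <- stats::coef(stats::lm(lk[fold] ~ u[fold]))
  cu <- stats::coef(stats::lm(lk[unf] ~ u[unf]))
  start <- list(lkf = unname(cf[1]) * ln10,
                mf = max(-unname(cf[2]) * ln10 * RT, 0.1),
                lku = unname(cu[1]) * ln10,
                mu = max(unname(cu[2]) * ln10 * RT, 0.02))
  fit <- fk_fit_nls(
    lk ~ chevron_log10_kobs(u, exp(lkf), exp(lku), mf, mu,
                            temperature = temp, R = Rgas),
    data = data.frame(u = u, lk = lk), start = start,
    lower = c(lkf = -Inf, mf = 1e-6, lku = -Inf, mu = 1e-6),
    n_starts = n_starts, context = "chevron")
  fs <- fk_fit_summary(fit)
  k_f <- exp(unname(fs$par["lkf"]))
  k_u <- exp(unname(fs$par["lku"]))
  m_f <- unname(fs$par["mf"])
  m_u <- unname(fs$par["mu"])
  se <- c(k_f = k_f * unname(fs$se["lkf"]), m_TS_D = unname(fs$se["mf"]),
          k_u = k_u * unname(fs$se["lku"]), m_TS_N = unname(fs$se["mu"]))
  structure(list(
    k_f = k_f, k_u = k_u, m_TS_D = m_f, m_TS_N = m_u,
    std_errors = se, covariance = fs$cov,
    derived = list(dG_kin = dG_from_rates(k_f, k_u, data$temperature,
                                          R = constants$R),
                   beta_T = tanford_beta(m_f, m_u),
                   m_kin_sum = m_f + m_u),
    temperature = data$temperature,
    residual_norm = sqrt(fs$deviance),
    fitted = fs$fitted, residuals = fs$residuals,
    constants = constants, data = data),
    class = c("chevron_fit", "fk_fit"))
}

#' @export
print.chevron_fit <- function(x, ...) {
  cat("Two-state chevron fit\n")
  cat(sprintf("  k_f = %.4g 1/s, m_TS-D = %.2f kcal/(mol M)\n", x$k_f, x$m_TS_D))
  cat(sprintf("  k_u = %.4g 1/s, m_TS-N = %.2f kcal/(mol M)\n", x$k_u, x$m_TS_N))
  cat(sprintf("  dG_kin = %.2f kcal/mol, beta_T = %.2f\n",
              x$derived$dG_kin, x$derived$beta_T))
  invisible(x)
}

#' Folding free energy from microscopic rate constants
#'
#' \eqn{\Delta G = -RT \ln(k_u/k_f)}: the equilibrium constant of unfolding
#' expressed through the extrapolated rates in water.
#'
#' @param k_f,k_u Folding and unfolding rate constants (1/s), positive.
#' @param temperature Temperature (K).
#' @param R Gas constant, kcal/(mol K).
#' @return Free energy of unfolding, kcal/mol.
#' @examples
#' dG_from_rates(10123, 4.67) # 4.55 kcal/mol
#' @export
dG_from_rates <- function(k_f, k_u, temperature = 298, R = 1.987e-3) {
  if (any(c(k_f, k_u) <= 0) || any(!is.finite(c(k_f, k_u))))
    fk_invalid_input("rate constants must be positive and finite")
  -R * temperature * log(k_u / k_f)
}

#' Tanford beta value
#'
#' \eqn{\beta_T = m_f / (m_f + m_u)}: the fractional change in solvent
#' accessibility at the transition state relative to the full unfolding
#' transition (1 = fully native-like).
#'
#' @param m_f,m_u Kinetic m-values of folding and unfolding, kcal/(mol M).
#' @return Dimensionless value in (0, 1) for positive inputs.
#' @examples
#' tanford_beta(1.29, 0.22) # 0.85
#' @export
tanford_beta <- function(m_f, m_u) {
  if (m_f + m_u == 0) fk_invalid_input("m_f + m_u must be nonzero")
  m_f / (m_f + m_u)
}

#' Equilibrium/kinetic two-state consistency check
#'
#' For a genuine two-state folder the equilibrium m-value should match the
#' sum of the kinetic m-values, and the equilibrium free energy should match
#' \eqn{-RT\ln(k_u/k_f)}. This reports both pairs with their relative
#' discrepancies \eqn{|\Delta|/\mathrm{mean}} and flags the protein
#' two-state consistent when both fall at or below `threshold`.
#'
#' @param eq A `chemical_fit`, or a list/vector with elements `dG` and `m`.
#' @param kin A `chevron_fit`, or a list/vector with elements `dG` and
#'   `m_sum`.
#' @param threshold Maximum relative discrepancy (default 0.2).
#' @return A list of class `consistency_report`: `dG_eq`, `dG_kin`, `m_eq`,
#'   `m_kin_sum`, `rel_discrepancy` (named, `dG` and `m`), `threshold`,
#'   `consistent`.
#' @examples
#' consistency_report(list(dG = 5.07, m = 1.64),
#'                    list(dG = 4.55, m_sum = 1.29 + 0.22))
#' @export
consistency_report <- function(eq, kin, threshold = 0.2) {
  if (inherits(eq, "chemical_fit")) eq <- list(dG = eq$dG_DN, m = eq$m_DN)
  if (inherits(kin, "chevron_fit"))
    kin <- list(dG = kin$derived$dG_kin, m_sum = kin$derived$m_kin_sum)
  eq <- as.list(eq)
  kin <- as.list(kin)
  rel <- function(a, b) abs(a - b) / mean(c(a, b))
  disc <- c(dG = rel(eq$dG, kin$dG), m = rel(eq$m, kin$m_sum))
  structure(list(dG_eq = eq$dG, dG_kin = kin$dG, m_eq = eq$m,
                 m_kin_sum = kin$m_sum, rel_discrepancy = disc,
                 threshold = threshold, consistent = all(disc <= threshold)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("dG: %.2f (eq) vs %.2f (kin) kcal/mol  [%.1f%%]\n",
              x$dG_eq, x$dG_kin, 100 * x$rel_discrepancy["dG"]))
  cat(sprintf("m:  %.2f (eq) vs %.2f (m_f + m_u) kcal/(mol M)  [%.1f%%]\n",
              x$m_eq, x$m_kin_sum, 100 * x$rel_discrepancy["m"]))
  cat(if (x$consistent) "-> two-state consistent\n"
      else sprintf("-> NOT consistent at the %.0f%% threshold\n", 100 * x$threshold))
  invisible(x)
}
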
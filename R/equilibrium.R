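#' Two-state spectroscopic signal
#'
#' Evaluates the two-state equilibrium observable with linearly sloping
#' native and denatured baselines,
#' \deqn{S(P) = \frac{\alpha_N + \beta_N P + (\alpha_D + \beta_D P)
#'   e^{-\Delta G(P)/RT}}{1 + e^{-\Delta G(P)/RT}},}
#' i.e. the population-weighted average of the two baseline signals. The
#' implementation uses the logistic form \eqn{f_N = 1/(1 + e^{-\Delta G/RT})}
#' via [stats::plogis()], so it is overflow-free for arbitrarily large
#' \eqn{|\Delta G|/RT}.
#'
#' @param P Perturbation values (urea in M, or temperature in K).
#' @param dG Unfolding free energies \eqn{\Delta G_{D-N}(P)} in kcal/mol:
#'   either a numeric vector matching `P` or a function of `P`.
#' @param baselines Numeric length-4 vector
#'   `(alpha_N, beta_N, alpha_D, beta_D)`: intercepts and slopes of the
#'   native and denatured baselines, in signal units and signal units per
#'   perturbation unit.
#' @param temperature Temperature (K) at which RT is evaluated.
#' @param R Gas constant, kcal/(mol K).
#'
#' @return Signal values, same length as `P`. At a transition midpoint
#'   (\eqn{\Delta G = 0}) the native and denatured baselines contribute
#'   equally.
#' @examples
#' # flat baselines: the signal is the native population itself
#' two_state_signal(3, function(P) 1.64 * (3.09 - P), c(1, 0, 0, 0))
#' @export
two_state_signal <- function(P, dG, baselines, temperature = 298, R = 1.987e-3) {
  if (temperature <= 0) fk_invalid_input("temperature must be positive")
  if (length(baselines) != 4L) fk_invalid_input("baselines must have length 4")
  if (is.function(dG)) dG <- dG(P)
  dG <- as.numeric(dG)
  if (length(dG) == 1L) dG <- rep(dG, length(P))
  if (length(dG) != length(P))
    fk_invalid_input("dG must be scalar or match the length of P")
  if (any(!is.finite(dG)))
    fk_invalid_input("dG is non-finite at some perturbation values")
  fN <- stats::plogis(dG / (R * temperature))
  native <- baselines[1] + baselines[2] * P
  denatured <- baselines[3] + baselines[4] * P
  fN * native + (1 - fN) * denatured
}

#' Free-energy models underlying the two-state fits
#'
#' `dG_linear_urea()` is the linear free-energy relationship for chemical
#' denaturation, \eqn{\Delta G([urea]) = m_{D-N}([urea]_{50\%} - [urea])},
#' whose value at zero denaturant is \eqn{\Delta G_{D-N} = m_{D-N} \cdot
#' [urea]_{50\%}}. `dG_gibbs_helmholtz()` is the temperature dependence
#' around the melting point,
#' \deqn{\Delta G(T) = \Delta H_m (1 - T/T_m) -
#'   \Delta C_p [T_m - T + T \ln(T/T_m)],}
#' with \eqn{\Delta C_p} the heat-capacity change of unfolding.
#'
#' @param urea Urea concentration (M).
#' @param m m-value, kcal/(mol M).
#' @param midpoint Transition midpoint \eqn{[urea]_{50\%}} (M).
#' @param temperature Temperature (K).
#' @param dHm van't Hoff enthalpy of unfolding at the midpoint (kcal/mol).
#' @param Tm Melting temperature (K).
#' @param dCp Heat-capacity change of unfolding, kcal/(K mol); `dCp = 0`
#'   reduces to the van't Hoff limit \eqn{\Delta H_m (1 - T/T_m)}.
#'
#' @return Free energies in kcal/mol.
#' @export
dG_linear_urea <- function(urea, m, midpoint) {
  m * (midpoint - urea)
}

#' @rdname dG_linear_urea
#' @export
dG_gibbs_helmholtz <- function(temperature, dHm, Tm, dCp) {
  dHm * (1 - temperature / Tm) -
    dCp * (Tm - temperature + temperature * log(temperature / Tm))
}

#' Unfolding free energy from m-value and midpoint
#'
#' The linear free-energy relationship evaluated at zero denaturant:
#' \eqn{\Delta G_{D-N} = m_{D-N} \cdot [urea]_{50\%}}.
#'
#' @param m m-value, kcal/(mol M).
#' @param urea50 Transition midpoint (M).
#' @return Free energy of unfolding in water, kcal/mol.
#' @examples
#' dG_from_m_and_midpoint(1.64, 3.09) # 5.07 kcal/mol
#' @export
dG_from_m_and_midpoint <- function(m, urea50) {
  if (!all(is.finite(c(m, urea50))))
    fk_invalid_input("m and urea50 must be finite")
  m * urea50
}

#' Propagated standard error of the unfolding free energy
#'
#' First-order error propagation for \eqn{\Delta G = m \cdot [urea]_{50\%}}:
#' \deqn{\sigma_{\Delta G} = \sqrt{([urea]_{50\%}\,\sigma_m)^2 +
#'   (m\,\sigma_{mid})^2 + 2\,m\,[urea]_{50\%}\,\mathrm{cov}(m, mid)}.}
#' With `cov_m_mid = 0` this is the independent-error form; a nonlinear fit
#' typically yields a nonzero (often negative) covariance between the two.
#'
#' @param m,urea50 Fitted m-value and midpoint.
#' @param se_m,se_urea50 Their standard errors (non-negative).
#' @param cov_m_mid Covariance of the two estimates (default 0).
#' @return Standard error of \eqn{\Delta G}, kcal/mol.
#' @export
propagate_dG_error <- function(m, urea50, se_m, se_urea50, cov_m_mid = 0) {
  if (se_m < 0 || se_urea50 < 0)
    fk_invalid_input("standard errors must be non-negative")
  v <- (urea50 * se_m)^2 + (m * se_urea50)^2 + 2 * m * urea50 * cov_m_mid
  if (v < 0)
    fk_stop("fk_numerical_error",
            "negative variance after covariance term in dG error propagation")
  sqrt(v)
}

#' Stability change from a melting-temperature shift (Schellman)
#'
#' Converts a shift of the thermal midpoint into a change of unfolding free
#' energy assuming the midpoint entropy is conserved:
#' \eqn{\Delta\Delta G = (\Delta H_m / T_m)\,\Delta T_m}.
#'
#' @param dHm Enthalpy of unfolding at the reference midpoint (kcal/mol).
#' @param Tm Reference melting temperature (K), positive.
#' @param dTm Midpoint shift (K).
#' @return \eqn{\Delta\Delta G} in kcal/mol.
#' @examples
#' schellman_ddG(54.8, 329.9, 5.0)
#' @export
schellman_ddG <- function(dHm, Tm, dTm) {
  if (Tm <= 0) fk_invalid_input("Tm must be positive")
  dHm / Tm * dTm
}

# Thermal two-state observable: Gibbs-Helmholtz free energy with RT at the
# running temperature of each point.
fk_thermal_signal <- function(P, dHm, Tm, dCp, aN, bN, aD, bD, R) {
  fN <- stats::plogis(dG_gibbs_helmholtz(P, dHm, Tm, dCp) / (R * P))
  fN * (aN + bN * P) + (1 - fN) * (aD + bD * P)
}

# Chemical-curve initial guesses: locate the transition by the extremum of
# the smoothed derivative of the (approximately normalized) signal.
fk_transition_guess <- function(P, S, RT) {
  bl <- fk_edge_baselines(P, S)
  native <- bl$low["intercept"] + bl$low["slope"] * P
  denat <- bl$high["intercept"] + bl$high["slope"] * P
  sep <- native - denat
  f <- if (all(abs(sep) > 1e-12)) (S - denat) / sep
       else (S - min(S)) / max(diff(range(S)), 1e-12)
  fs <- fk_smooth5(f)
  dfdP <- diff(fs) / diff(P)
  mid_idx <- which.max(abs(dfdP))
  midpoint <- (P[mid_idx] + P[mid_idx + 1L]) / 2
  # |df_N/dP| at the midpoint is |dG'(P)|/(4RT) for a logistic transition
  steep <- 4 * RT * abs(dfdP[mid_idx])
  list(midpoint = midpoint, steepness = steep, baselines = bl)
}

# Thermal-specific initial guesses. Works on the raw smoothed signal: the
# heat transition is the steepest descent (cold denaturation, when present
# at the low-temperature edge, rises and is ignored), and baselines are
# estimated from windows adjacent to the transition rather than the grid
# edges, which may already be partially unfolded.
fk_thermal_guess <- function(P, S, R) {
  Ss <- fk_smooth5(S)
  d <- diff(Ss) / diff(P)
  i <- which.min(d)
  mid <- (P[i] + P[i + 1L]) / 2
  # half-width of the derivative trough ~ transition width
  half <- d[i] / 2
  li <- i
  while (li > 1L && d[li] < half) li <- li - 1L
  ri <- i
  while (ri < length(d) && d[ri] < half) ri <- ri + 1L
  h <- max((P[ri] - P[li]) / 2, diff(range(P)) / 30)
  pick <- function(idx, fallback) if (length(idx) >= 3L) idx else fallback
  n <- length(P)
  nat_idx <- pick(which(P < mid - 1.5 * h & P > mid - 8 * h),
                  pick(which(P < mid - 1.5 * h), seq_len(5L)))
  den_idx <- pick(which(P > mid + 1.5 * h & P < mid + 8 * h),
                  pick(which(P > mid + 1.5 * h), seq(n - 4L, n)))
  cN <- stats::coef(stats::lm(S[nat_idx] ~ P[nat_idx]))
  cD <- stats::coef(stats::lm(S[den_idx] ~ P[den_idx]))
  sep_mid <- (cN[1] + cN[2] * mid) - (cD[1] + cD[2] * mid)
  # |dS/dT| at Tm is |sep| dHm / (4 R Tm^2) for the two-state melt
  dHm0 <- 4 * R * mid^2 * abs(d[i]) / max(abs(sep_mid), 1e-12)
  list(Tm0 = mid, dHm0 = min(max(dHm0, 10), 300),
       aN = unname(cN[1]), bN = unname(cN[2]),
       aD = unname(cD[1]), bD = unname(cD[2]))
}

# Two-state vs straight-line model comparison: reject the 6-parameter fit on
# a featureless (monotone, non-sigmoidal) curve unless it beats a line by a
# decisive AIC margin.
fk_check_not_degenerate <- function(P, S, fit_aic, min_delta = 10) {
  line_aic <- stats::AIC(stats::lm(S ~ P))
  if (!is.finite(fit_aic) || (line_aic - fit_aic) < min_delta)
    fk_stop(c("fk_degenerate_curve", "fk_fit_failure"),
            sprintf(paste0("curve shows no resolvable two-state transition ",
                           "(AIC two-state %.1f vs line %.1f; need a margin of %g)"),
                    fit_aic, line_aic, min_delta))
  invisible(TRUE)
}

#' Fit a chemical (urea) equilibrium denaturation curve
#'
#' Least-squares fit of the two-state observable ([two_state_signal()]) with
#' the linear free-energy relationship \eqn{\Delta G([urea]) =
#' m_{D-N}([urea]_{50\%} - [urea])}. Six free parameters: m-value, midpoint,
#' and the four baseline coefficients. Initial guesses are automatic (edge
#' baselines, midpoint from the steepest smoothed descent, m-value from the
#' transition steepness), refined by Levenberg-Marquardt with up to
#' `n_starts` jittered restarts. A fit that does not beat a straight line by
#' at least 10 AIC units is rejected as degenerate.
#'
#' @param curve A [denaturation_curve()] with `mode = "chemical"`.
#' @param temperature Temperature (K) at which RT is evaluated; defaults to
#'   the curve's metadata temperature, else the 298 K reference.
#' @param constants A [fk_constants()] list.
#' @param n_starts Maximum number of jittered starts before declaring
#'   failure.
#'
#' @return An object of class `chemical_fit`: fitted `m_DN` (kcal/(mol M)),
#'   `urea50` (M), derived `dG_DN = m_DN * urea50` with propagated standard
#'   error (`dG_se` includes the m-midpoint covariance, `dG_se_independent`
#'   does not), `baselines`, per-parameter `std_errors`, the full parameter
#'   `covariance`, residuals and the residual norm.
#' @examples
#' curve <- simulate_chemical_curve(m = 1.64, midpoint = 3.09, sigma = 0)
#' fit <- fit_chemical_denaturation(curve)
#' c(fit$m_DN, fit$urea50, fit$dG_DN)
#' @export
fit_chemical_denaturation <- function(curve, temperature = NULL,
                                      constants = fk_constants(),
                                      n_starts = 5L) {
  if (!inherits(curve, "denaturation_curve") || curve$mode != "chemical")
    fk_invalid_input("fit_chemical_denaturation needs a chemical-mode denaturation_curve")
  temp <- temperature
  if (is.null(temp)) temp <- curve$condition$temperature
  if (is.null(temp) || is.na(temp)) temp <- constants$T_ref
  Rgas <- constants$R
  RT <- Rgas * temp
  P <- curve$perturbation
  S <- curve$signal
  g <- fk_transition_guess(P, S, RT)
  start <- list(m = min(max(g$steepness, 0.3), 6),
                mid = min(max(g$midpoint, min(P)), max(P)),
                aN = unname(g$baselines$low["intercept"]),
                bN = unname(g$baselines$low["slope"]),
                aD = unname(g$baselines$high["intercept"]),
                bD = unname(g$baselines$high["slope"]))
  dat <- data.frame(P = P, S = S)
  w <- if (is.null(curve$sigma)) NULL else 1 / curve$sigma^2
  fit <- fk_fit_nls(
    S ~ two_state_signal(P, m * (mid - P), c(aN, bN, aD, bD),
                         temperature = temp, R = Rgas),
    data = dat, start = start, weights = w, n_starts = n_starts,
    context = "chemical denaturation")
  fs <- fk_fit_summary(fit)
  fk_check_not_degenerate(P, S, fs$aic)
  m <- unname(fs$par["m"])
  mid <- unname(fs$par["mid"])
  cov_mm <- fs$cov["m", "mid"]
  dG_se_cov <- tryCatch(
    propagate_dG_error(m, mid, fs$se["m"], fs$se["mid"], cov_mm),
    fk_numerical_error = function(e) NA_real_)
  structure(list(
    m_DN = m, urea50 = mid,
    dG_DN = dG_from_m_and_midpoint(m, mid),
    dG_se = dG_se_cov,
    dG_se_independent = propagate_dG_error(m, mid, fs$se["m"], fs$se["mid"], 0),
    baselines = c(alpha_N = unname(fs$par["aN"]), beta_N = unname(fs$par["bN"]),
                  alpha_D = unname(fs$par["aD"]), beta_D = unname(fs$par["bD"])),
    std_errors = fs$se, covariance = fs$cov,
    residual_norm = sqrt(fs$deviance), aic = fs$aic,
    fitted = fs$fitted, residuals = fs$residuals,
    temperature = temp, constants = constants, curve = curve),
    class = c("chemical_fit", "fk_fit"))
}

#' @export
print.chemical_fit <- function(x, ...) {
  cat("Two-state chemical denaturation fit\n")
  cat(sprintf("  m_D-N      = %.2f +/- %.2f kcal/(mol M)\n",
              x$m_DN, x$std_errors["m"]))
  cat(sprintf("  [urea]50%%  = %.2f +/- %.2f M\n",
              x$urea50, x$std_errors["mid"]))
  cat(sprintf("  dG_D-N     = %.2f +/- %.2f kcal/mol\n", x$dG_DN, x$dG_se))
  invisible(x)
}

#' Fit a thermal denaturation (melting) curve
#'
#' Least-squares fit of the two-state observable with the Gibbs-Helmholtz
#' free energy ([dG_gibbs_helmholtz()]). The heat-capacity change is held
#' fixed at `dCp_per_residue * n_residues` (0.014 kcal/(K mol) per residue by
#' default); free parameters are \eqn{\Delta H_m}, \eqn{T_m} and the four
#' baseline coefficients. RT inside the Boltzmann factor uses the running
#' temperature of each point.
#'
#' @param curve A [denaturation_curve()] with `mode = "thermal"`.
#' @param n_residues Residue count of the domain (>= 1); required because
#'   the fixed \eqn{\Delta C_p} scales with chain length.
#' @param constants A [fk_constants()] list.
#' @param n_starts Maximum number of jittered starts.
#'
#' @return An object of class `thermal_fit` with `dH_m` (kcal/mol), `T_m`
#'   (K), the fixed `dCp`, `baselines`, `std_errors`, `covariance`, and
#'   residual diagnostics.
#' @examples
#' melt <- simulate_thermal_curve(dHm = 54.8, Tm = 329.9, n_residues = 137,
#'                                sigma = 0)
#' fit <- fit_thermal_denaturation(melt, n_residues = 137)
#' c(fit$dH_m, fit$T_m)
#' @export
fit_thermal_denaturation <- function(curve, n_residues,
                                     constants = fk_constants(),
                                     n_starts = 5L) {
  if (!inherits(curve, "denaturation_curve") || curve$mode != "thermal")
    fk_invalid_input("fit_thermal_denaturation needs a thermal-mode denaturation_curve")
  if (missing(n_residues) || !is.finite(n_residues) || n_residues < 1)
    fk_invalid_input("n_residues (>= 1) is required to fix dCp")
  dCp <- constants$dCp_per_residue * n_residues
  Rgas <- constants$R
  P <- curve$perturbation
  S <- curve$signal
  g <- fk_thermal_guess(P, S, Rgas)
  Tm0 <- min(max(g$Tm0, min(P) + 1), max(P) - 1)
  start <- list(dHm = g$dHm0, Tm = Tm0,
                aN = g$aN, bN = g$bN, aD = g$aD, bD = g$bD)
  # alternative start: plain edge baselines and a generic enthalpy, in case
  # the transition-adjacent windows were contaminated by the transition
  bl <- fk_edge_baselines(P, S)
  alt <- list(dHm = 60, Tm = Tm0,
              aN = unname(bl$low["intercept"]), bN = unname(bl$low["slope"]),
              aD = unname(bl$high["intercept"]), bD = unname(bl$high["slope"]))
  dat <- data.frame(P = P, S = S)
  w <- if (is.null(curve$sigma)) NULL else 1 / curve$sigma^2
  # box constraints keep the fit physical: positive unfolding enthalpy and a
  # midpoint inside the scanned range (rules out a spurious mode that fits
  # the cold-denaturation limb with dHm < 0)
  fit <- fk_fit_nls(
    S ~ fk_thermal_signal(P, dHm, Tm, dCp, aN, bN, aD, bD, Rgas),
    data = dat, start = start, weights = w, n_starts = n_starts,
    extra_starts = list(alt),
    lower = c(dHm = 0.01, Tm = min(P), aN = -Inf, bN = -Inf,
              aD = -Inf, bD = -Inf),
    upper = c(dHm = 2000, Tm = max(P), aN = Inf, bN = Inf,
              aD = Inf, bD = Inf),
    context = "thermal denaturation")
  fs <- fk_fit_summary(fit)
  fk_check_not_degenerate(P, S, fs$aic)
  structure(list(
    dH_m = unname(fs$par["dHm"]), T_m = unname(fs$par["Tm"]), dCp = dCp,
    n_residues = n_residues,
    baselines = c(alpha_N = unname(fs$par["aN"]), beta_N = unname(fs$par["bN"]),
                  alpha_D = unname(fs$par["aD"]), beta_D = unname(fs$par["bD"])),
    std_errors = fs$se, covariance = fs$cov,
    residual_norm = sqrt(fs$deviance), aic = fs$aic,
    fitted = fs$fitted, residuals = fs$residuals,
    constants = constants, curve = curve),
    class = c("thermal_fit", "fk_fit"))
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat("Two-state thermal denaturation fit\n")
  cat(sprintf("  T_m  = %.1f +/- %.1f K\n", x$T_m, x$std_errors["Tm"]))
  cat(sprintf("  dH_m = %.1f +/- %.1f kcal/mol\n", x$dH_m, x$std_errors["dHm"]))
  cat(sprintf("  dCp  = %.2f kcal/(K mol), fixed (%d residues)\n",
              x$dCp, as.integer(x$n_residues)))
  invisible(x)
}

#' Normalize a denaturation curve to the folded fraction
#'
#' Removes the fitted baselines:
#' \eqn{f_N(P) = (S - (\alpha_D + \beta_D P)) /
#' ((\alpha_N + \beta_N P) - (\alpha_D + \beta_D P))}. Noise-free model data
#' map exactly onto the two-state native population.
#'
#' @param curve The [denaturation_curve()] the fit was obtained from (or any
#'   curve on the same axes).
#' @param fit A converged `chemical_fit` or `thermal_fit`.
#' @return A numeric vector of folded fractions, approximately in \[0, 1\].
#' @export
folded_fraction <- function(curve, fit) {
  if (!inherits(fit, "fk_fit"))
    fk_invalid_input("fit must be a chemical_fit or thermal_fit")
  P <- curve$perturbation
  b <- fit$baselines
  native <- b["alpha_N"] + b["beta_N"] * P
  denatured <- b["alpha_D"] + b["beta_D"] * P
  sep <- native - denatured
  if (any(abs(sep) < 1e-12))
    fk_stop("fk_degenerate_normalization",
            "native and denatured baselines coincide at some perturbation value")
  unname((curve$signal - denatured) / sep)
}
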
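#' Second-order dimerization signal
#'
#' Closed-form observable for the irreversible dimerization
#' \eqn{2N \rightarrow N_2} followed by a fluorescence change:
#' \deqn{S(t) = S_{t=0} + S\,\frac{k_{app} t}{1 + k_{app} t},}
#' the solution of the second-order rate law mapped onto the dimerized
#' fraction. Monotone in `t` with asymptote `S0 + S_amp`.
#'
#' @param t Times (s), non-negative.
#' @param S0 Signal at `t = 0`.
#' @param S_amp Total amplitude change (may be negative: Trp fluorescence is
#'   quenched on dimerization).
#' @param k_app Apparent rate constant (1/s), `k_app = c_N * k_ass`.
#' @return Signal values, same length as `t`.
#' @examples
#' dimer_signal(0.01, S0 = 1, S_amp = -0.5, k_app = 200) # 2/3 saturated
#' @export
dimer_signal <- function(t, S0, S_amp, k_app) {
  if (any(t < 0)) fk_invalid_input("t must be non-negative")
  if (k_app <= 0) fk_invalid_input("k_app must be positive")
  x <- k_app * t
  S0 + S_amp * x / (1 + x)
}

#' Fit an association transient to the dimerization model
#'
#' Fits [dimer_signal()] to a stopped-flow association trace, then converts
#' the apparent rate to the bimolecular association rate constant via
#' \eqn{k_{app} = f \cdot c_N \cdot k_{ass}} with stoichiometry factor
#' \eqn{f = 1} by default (the convention under which `k_ass` is defined
#' directly by the observed hyperbolic saturation; set
#' `stoichiometry_factor = 2` for the monomer-loss convention
#' \eqn{d[N]/dt = -2 k_{ass} [N]^2}).
#'
#' @param transient A [kinetic_transient()] (experiment `"association"`).
#' @param c_N Post-mixing monomer concentration (M), positive. Defaults to
#'   the transient's metadata.
#' @param stoichiometry_factor 1 (default) or 2; see above.
#' @param t_start Optional fit-window start (s) to exclude early-time
#'   deviations from small oligomeric populations. Default 0.
#' @param n_starts Maximum number of jittered starts.
#'
#' @return An object of class `association_fit` with `k_app` (1/s), `k_ass`
#'   (1/(M s), error propagated assuming `c_N` exact), `c_N`, `S0`, `S_amp`,
#'   `std_errors` and residual diagnostics.
#' @examples
#' tr <- simulate_association_transient(k_ass = 2.19e9, c_N = 1e-7, sigma = 0)
#' fit <- fit_association(tr, c_N = 1e-7)
#' fit$k_ass
#' @export
fit_association <- function(transient, c_N = transient$meta$c_N,
                            stoichiometry_factor = 1, t_start = 0,
                            n_starts = 5L) {
  if (!inherits(transient, "kinetic_transient"))
    fk_invalid_input("fit_association needs a kinetic_transient")
  if (is.null(c_N) || is.na(c_N) || c_N <= 0)
    fk_invalid_input("c_N (post-mixing monomer concentration, M) must be positive")
  if (!stoichiometry_factor %in% c(1, 2))
    fk_invalid_input("stoichiometry_factor must be 1 or 2")
  keep <- transient$time >= t_start
  t <- transient$time[keep]
  S <- transient$signal[keep]
  if (length(t) < 5L)
    fk_invalid_input("need at least 5 points after the fit-window start")
  n_tail <- max(3L, floor(length(t) / 10))
  S_inf <- mean(S[seq(length(S) - n_tail + 1L, length(S))])
  S0_0 <- S[1]
  amp0 <- S_inf - S0_0
  if (amp0 == 0) amp0 <- diff(range(S))
  # half-saturation time t_1/2 = 1/k_app
  half <- S0_0 + amp0 / 2
  i_half <- which.min(abs(S - half))
  k0 <- 1 / max(t[max(i_half, 2L)], 1e-12)
  start <- list(S0 = S0_0, Samp = amp0, kapp = k0)
  fit <- fk_fit_nls(S ~ S0 + Samp * (kapp * t) / (1 + kapp * t),
                    data = data.frame(t = t, S = S), start = start,
                    lower = c(S0 = -Inf, Samp = -Inf, kapp = 1e-12),
                    n_starts = n_starts, context = "association")
  fs <- fk_fit_summary(fit)
  k_app <- unname(fs$par["kapp"])
  denom <- stoichiometry_factor * c_N
  structure(list(k_app = k_app, k_ass = k_app / denom, c_N = c_N,
                 stoichiometry_factor = stoichiometry_factor,
                 S0 = unname(fs$par["S0"]), S_amp = unname(fs$par["Samp"]),
                 std_errors = c(k_app = unname(fs$se["kapp"]),
                                k_ass = unname(fs$se["kapp"]) / denom,
                                S0 = unname(fs$se["S0"]),
                                S_amp = unname(fs$se["Samp"])),
                 covariance = fs$cov, residual_norm = sqrt(fs$deviance),
                 fitted = fs$fitted, residuals = fs$residuals,
                 transient = transient),
            class = c("association_fit", "fk_fit"))
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf("Dimerization fit: k_app = %.4g 1/s, k_ass = %.3g 1/(M s) at c_N = %.3g M\n",
              x$k_app, x$k_ass, x$c_N))
  invisible(x)
}

#' Fit a chasing-dissociation transient
#'
#' Dissociation measured by chasing a labelled dimer with excess unlabelled
#' monomer gives a mono-exponential fluorescence rise,
#' \eqn{S(t) = c + a(1 - e^{-k_{diss} t})}.
#'
#' @param transient A [kinetic_transient()] (experiment `"dissociation"`).
#'   A falling trace triggers a warning (the chase should produce a rise).
#' @param n_starts Maximum number of jittered starts.
#'
#' @return An object of class `dissociation_fit` with `k_diss` (1/s),
#'   `amplitude`, `offset`, `std_errors` and residual diagnostics.
#' @examples
#' tr <- simulate_dissociation_transient(k_diss = 0.31, sigma = 0)
#' fit_dissociation(tr)$k_diss
#' @export
fit_dissociation <- function(transient, n_starts = 5L) {
  if (!inherits(transient, "kinetic_transient"))
    fk_invalid_input("fit_dissociation needs a kinetic_transient")
  t <- transient$time
  S <- transient$signal
  n_edge <- max(3L, floor(length(t) / 10))
  init_mean <- mean(S[seq_len(n_edge)])
  final_mean <- mean(S[seq(length(S) - n_edge + 1L, length(S))])
  if (final_mean <= init_mean)
    warning("dissociation transient does not rise; check the experiment type")
  amp_scale <- max(abs(S), 1e-300)
  if (diff(range(S)) < 1e-10 * amp_scale)
    fk_fit_failure("no signal change: dissociation amplitude is degenerate, k_diss unidentifiable")
  # initial rate from log-linear decay of the remaining amplitude
  excess <- abs(final_mean - S)
  early <- which(excess > max(excess) * 0.05)
  early <- early[seq_len(min(length(early), max(5L, floor(length(t) / 3))))]
  lf <- stats::lm(log(pmax(excess[early], 1e-12)) ~ t[early])
  k0 <- max(-unname(stats::coef(lf)[2]), 1 / max(diff(range(t)), 1e-12))
  start <- list(c0 = init_mean, a = final_mean - init_mean, k = k0)
  fit <- fk_fit_nls(S ~ c0 + a * (1 - exp(-k * t)),
                    data = data.frame(t = t, S = S), start = start,
                    lower = c(c0 = -Inf, a = -Inf, k = 1e-12),
                    n_starts = n_starts, context = "dissociation")
  fs <- fk_fit_summary(fit)
  structure(list(k_diss = unname(fs$par["k"]), amplitude = unname(fs$par["a"]),
                 offset = unname(fs$par["c0"]),
                 std_errors = c(k_diss = unname(fs$se["k"]),
                                amplitude = unname(fs$se["a"]),
                                offset = unname(fs$se["c0"])),
                 covariance = fs$cov, residual_norm = sqrt(fs$deviance),
                 fitted = fs$fitted, residuals = fs$residuals,
                 transient = transient),
            class = c("dissociation_fit", "fk_fit"))
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential rise fit: k_diss = %.4g +/- %.2g 1/s\n",
              x$k_diss, x$std_errors["k_diss"]))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' \eqn{K_d = k_{diss}/k_{ass}}, with the standard error propagated from the
#' relative errors of the two rates:
#' \eqn{\sigma_{K_d} = K_d \sqrt{(\sigma_{diss}/k_{diss})^2 +
#' (\sigma_{ass}/k_{ass})^2}}.
#'
#' @param k_diss Dissociation rate constant (1/s), positive.
#' @param k_ass Association rate constant (1/(M s)), positive.
#' @param se_k_diss,se_k_ass Standard errors (default 0).
#' @return An object of class `affinity` with `K_d` (M) and `se` (M).
#' @examples
#' compute_Kd(0.31, 2.19e9) # 0.14 nM
#' @export
compute_Kd <- function(k_diss, k_ass, se_k_diss = 0, se_k_ass = 0) {
  if (k_diss <= 0 || k_ass <= 0)
    fk_invalid_input("rate constants must be positive")
  K_d <- k_diss / k_ass
  se <- K_d * sqrt((se_k_diss / k_diss)^2 + (se_k_ass / k_ass)^2)
  structure(list(K_d = K_d, se = se), class = "affinity")
}

#' @export
print.affinity <- function(x, ...) {
  cat(sprintf("K_d = %.2f +/- %.2f nM\n", x$K_d * 1e9, x$se * 1e9))
  invisible(x)
}

#' Post-mixing concentration from a volumetric mixing ratio
#'
#' Stopped-flow experiments report the pre-mix protein concentration and a
#' volumetric mixing ratio such as `"1:11"` (1 part sample into 11 parts
#' buffer); the post-mix concentration is `premix * 1 / (1 + 11)`.
#'
#' @param c_premix Pre-mix concentration (M).
#' @param mix_ratio Ratio string `"a:b"` (sample:buffer parts).
#' @return Post-mix concentration (M).
#' @examples
#' postmix_concentration(1.2e-6, "1:11") # 1e-7 M
#' @export
postmix_concentration <- function(c_premix, mix_ratio) {
  parts <- suppressWarnings(as.numeric(strsplit(mix_ratio, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2L || anyNA(parts) || any(parts <= 0))
    fk_invalid_input(sprintf("malformed mixing ratio '%s' (expected 'a:b')", mix_ratio))
  c_premix * parts[1] / sum(parts)
}
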
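#' Equilibrium denaturation curve
#'
#' Container for one equilibrium denaturation experiment: a spectroscopic
#' signal (CD ellipticity at 222 nm or Trp fluorescence at 330 nm) recorded
#' along a perturbation axis, either urea concentration (chemical mode, M) or
#' temperature (thermal mode, K).
#'
#' @param perturbation Strictly increasing numeric vector; urea in \[0, 12\] M
#'   for chemical mode, temperature in \[250, 400\] K for thermal mode. At
#'   least 8 points (the two-state model has 6 free parameters).
#' @param signal Numeric vector of spectroscopic readings, same length.
#' @param probe `"CD222"` or `"TrpFluorescence"`.
#' @param mode `"chemical"` or `"thermal"`.
#' @param sigma Optional per-point standard deviations (same length); used as
#'   weights when present.
#' @param pH,ionic_strength,temperature,label Condition metadata. Ionic
#'   strength in M; `temperature` is the measurement temperature of a
#'   chemical denaturation (K).
#'
#' @return An object of class `denaturation_curve`.
#' @seealso [fit_chemical_denaturation()], [fit_thermal_denaturation()]
#' @export
denaturation_curve <- function(perturbation, signal,
                               probe = c("CD222", "TrpFluorescence"),
                               mode = c("chemical", "thermal"),
                               sigma = NULL, pH = NA_real_,
                               ionic_strength = NA_real_,
                               temperature = NA_real_, label = "") {
  probe <- match.arg(probe)
  mode <- match.arg(mode)
  perturbation <- as.numeric(perturbation)
  signal <- as.numeric(signal)
  if (length(perturbation) != length(signal))
    fk_invalid_input("perturbation and signal must have equal length")
  if (length(perturbation) < 8L)
    fk_invalid_input("need at least 8 points to constrain a 6-parameter two-state fit")
  if (anyNA(perturbation) || anyNA(signal))
    fk_invalid_input("NA values in curve data")
  if (any(diff(perturbation) <= 0))
    fk_invalid_input("perturbation axis must be strictly increasing")
  rng <- if (mode == "chemical") c(0, 12) else c(250, 400)
  if (any(perturbation < rng[1] | perturbation > rng[2]))
    fk_invalid_input(sprintf("%s-mode perturbation values must lie in [%g, %g]",
                             mode, rng[1], rng[2]))
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(signal) || any(!is.finite(sigma)) || any(sigma <= 0))
      fk_invalid_input("sigma must be positive and match the signal length")
  }
  structure(list(perturbation = perturbation, signal = signal, sigma = sigma,
                 probe = probe, mode = mode,
                 condition = list(pH = pH, ionic_strength = ionic_strength,
                                  temperature = temperature, label = label)),
            class = "denaturation_curve")
}

#' @export
print.denaturation_curve <- function(x, ...) {
  cat(sprintf("<denaturation_curve> %s, %s probe, %d points, %s %.3g-%.3g %s\n",
              x$mode, x$probe, length(x$perturbation),
              if (x$mode == "chemical") "[urea]" else "T",
              min(x$perturbation), max(x$perturbation),
              if (x$mode == "chemical") "M" else "K"))
  invisible(x)
}

#' Stopped-flow kinetic transient
#'
#' One stopped-flow fluorescence trace: signal versus time. The experiment
#' type records what was mixed (refolding/unfolding jump, association after a
#' pH drop, or a chasing-dissociation experiment).
#'
#' @param time Strictly increasing times (s), `time[1] >= 0`, at least 20
#'   points.
#' @param signal Fluorescence signal, arbitrary units, same length.
#' @param experiment One of `"folding"`, `"unfolding"`, `"association"`,
#'   `"dissociation"`.
#' @param final_urea Post-mix urea concentration (M), for folding/unfolding
#'   jumps; `NA` otherwise.
#' @param c_N Post-mix monomer concentration (M), for association
#'   experiments; `NA` otherwise.
#' @param label Free-text label.
#'
#' @return An object of class `kinetic_transient`.
#' @seealso [fit_exponential_with_drift()], [fit_association()],
#'   [fit_dissociation()]
#' @export
kinetic_transient <- function(time, signal,
                              experiment = c("folding", "unfolding",
                                             "association", "dissociation"),
                              final_urea = NA_real_, c_N = NA_real_,
                              label = "") {
  experiment <- match.arg(experiment)
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal))
    fk_invalid_input("time and signal must have equal length")
  if (length(time) < 20L)
    fk_invalid_input("a kinetic transient needs at least 20 points")
  if (anyNA(time) || anyNA(signal))
    fk_invalid_input("NA values in transient data")
  if (time[1] < 0)
    fk_invalid_input("time must start at or after 0")
  d <- diff(time)
  if (any(d == 0)) {
    i <- which(d == 0)[1] + 1L
    fk_invalid_input(sprintf("duplicate time stamp at point %d (t = %g s)", i, time[i]))
  }
  if (any(d < 0))
    fk_invalid_input("time axis must be strictly increasing")
  structure(list(time = time, signal = signal,
                 meta = list(experiment = experiment, final_urea = final_urea,
                             c_N = c_N, label = label)),
            class = "kinetic_transient")
}

#' @export
print.kinetic_transient <- function(x, ...) {
  cat(sprintf("<kinetic_transient> %s, %d points, t = %.3g-%.3g s\n",
              x$meta$experiment, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Chevron dataset
#'
#' Observed relaxation rate constants of folding/unfolding jumps as a
#' function of final denaturant concentration, the input to chevron analysis.
#'
#' @param urea Final urea concentrations (M).
#' @param k_obs Observed rate constants (1/s), all positive; at least 6
#'   points.
#' @param sigma Optional standard errors of `k_obs`.
#' @param temperature Measurement temperature (K).
#'
#' @return An object of class `chevron_dataset`.
#' @seealso [fit_chevron()]
#' @export
chevron_dataset <- function(urea, k_obs, sigma = NULL, temperature = 298.0) {
  urea <- as.numeric(urea)
  k_obs <- as.numeric(k_obs)
  if (length(urea) != length(k_obs))
    fk_invalid_input("urea and k_obs must have equal length")
  if (length(urea) < 6L)
    fk_invalid_input("chevron analysis needs at least 6 points spanning both limbs")
  if (anyNA(urea) || anyNA(k_obs) || any(k_obs <= 0))
    fk_invalid_input("all k_obs must be positive and finite")
  o <- order(urea)
  structure(list(urea = urea[o], k_obs = k_obs[o],
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma)[o],
                 temperature = temperature),
            class = "chevron_dataset")
}

#' @export
print.chevron_dataset <- function(x, ...) {
  cat(sprintf("<chevron_dataset> %d points, [urea] %.2g-%.2g M, T = %g K\n",
              length(x$urea), min(x$urea), max(x$urea), x$temperature))
  invisible(x)
}

#' Ionic-strength series
#'
#' Stability as a function of solution ionic strength, either directly as
#' unfolding free energies (chemical-denaturation source) or as melting
#' parameters (thermal source) to be converted to stability changes with
#' [thermal_series_to_ddG()].
#'
#' @param ionic_strength Ionic strengths (M), all positive; at least 3 points.
#' @param dG Unfolding free energies (kcal/mol), for `source = "chemical"`.
#' @param Tm,dHm Melting temperatures (K) and van't Hoff enthalpies
#'   (kcal/mol), for `source = "thermal"`.
#' @param source `"chemical"` or `"thermal"`.
#' @param label Free-text label (homologue name).
#'
#' @return An object of class `salt_series`.
#' @seealso [fit_debye_huckel_slope()]
#' @export
salt_series <- function(ionic_strength, dG = NULL, Tm = NULL, dHm = NULL,
                        source = c("chemical", "thermal"), label = "") {
  source <- match.arg(source)
  I <- as.numeric(ionic_strength)
  if (length(I) < 3L)
    fk_invalid_input("need at least 3 ionic strengths for a slope with an error")
  if (anyNA(I) || any(I <= 0))
    fk_invalid_input("ionic strengths must be positive")
  if (source == "chemical") {
    if (is.null(dG) || length(dG) != length(I))
      fk_invalid_input("chemical salt series needs a dG value per ionic strength")
    out <- list(ionic_strength = I, dG = as.numeric(dG), Tm = NULL, dHm = NULL)
  } else {
    if (is.null(Tm) || length(Tm) != length(I))
      fk_invalid_input("thermal salt series needs a Tm value per ionic strength")
    if (is.null(dHm))
      fk_invalid_input("thermal salt series needs dHm (per point, or one value)")
    dHm <- as.numeric(dHm)
    if (length(dHm) == 1L) dHm <- rep(dHm, length(I))
    if (length(dHm) != length(I))
      fk_invalid_input("dHm must be a single value or one per ionic strength")
    out <- list(ionic_strength = I, dG = NULL, Tm = as.numeric(Tm), dHm = dHm)
  }
  o <- order(I)
  out <- lapply(out, function(v) if (is.null(v)) NULL else v[o])
  structure(c(out, list(source = source, label = label)), class = "salt_series")
}

#' @export
print.salt_series <- function(x, ...) {
  cat(sprintf("<salt_series> %s, %d points, I %.3g-%.3g M%s\n",
              x$source, length(x$ionic_strength),
              min(x$ionic_strength), max(x$ionic_strength),
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}
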
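# Seeded generators for every data kind the pipeline consumes. Each forward
# model is the same closed form the corresponding fit uses; generators return
# the data container with the generating truth attached as attribute "truth"
# so parameter-recovery tests can compare refits against ground truth.

#' Homologue parameter presets
#'
#' Published equilibrium, thermal, kinetic and association parameters for
#' the four spidroin N-terminal domain homologues studied comparatively:
#' Lh (*Latrodectus hesperus*), Lg (*L. geometricus*), Nc (*Nephila
#' clavipes*) and Ea (*Euprosthenops australis*). Used as ground-truth
#' scenarios by the synthetic-data generators.
#'
#' @param label One of `"Lh"`, `"Lg"`, `"Nc"`, `"Ea"`.
#' @return A list of class `homologue_preset` with elements
#'   `equilibrium` (per-probe `m` kcal/(mol M) and `midpoint` M),
#'   `thermal` (`Tm` K, `dHm` kcal/mol), `kinetic` (`k_f`, `k_u` 1/s,
#'   `m_f`, `m_u` kcal/(mol M)) and `association` (`k_ass` 1/(M s),
#'   `k_diss` 1/s).
#' @examples
#' preset("Lh")$association$k_ass
#' @export
preset <- function(label) {
  presets <- list(
    Lh = list(
      equilibrium = list(CD = list(m = 1.64, midpoint = 3.09),
                         Fluo = list(m = 1.58, midpoint = 3.20)),
      thermal = list(Tm = 329.9, dHm = 54.8),
      kinetic = list(k_f = 10123, k_u = 4.67, m_f = 1.29, m_u = 0.22),
      association = list(k_ass = 2.19e9, k_diss = 0.31)),
    Lg = list(
      equilibrium = list(CD = list(m = 1.46, midpoint = 3.39),
                         Fluo = list(m = 1.53, midpoint = 3.34)),
      thermal = list(Tm = 331.0, dHm = 50.1),
      kinetic = list(k_f = 11899, k_u = 5.34, m_f = 1.09, m_u = 0.22),
      association = list(k_ass = 1.39e9, k_diss = 0.64)),
    Nc = list(
      equilibrium = list(CD = list(m = 1.59, midpoint = 2.19),
                         Fluo = list(m = 1.67, midpoint = 2.18)),
      thermal = list(Tm = 326.8, dHm = 54.3),
      kinetic = list(k_f = 3652, k_u = 12.16, m_f = 1.39, m_u = 0.28),
      association = list(k_ass = 2.58e9, k_diss = 1.88)),
    Ea = list(
      equilibrium = list(CD = list(m = 1.69, midpoint = 3.30),
                         Fluo = list(m = 1.69, midpoint = 3.31)),
      thermal = list(Tm = 337.0, dHm = 67.5),
      kinetic = list(k_f = 13257, k_u = 3.28, m_f = 1.20, m_u = 0.23),
      association = list(k_ass = 1.58e9, k_diss = 1.68)))
  if (!label %in% names(presets))
    fk_invalid_input(sprintf("unknown homologue label '%s' (use Lh, Lg, Nc or Ea)", label))
  structure(c(list(label = label), presets[[label]]),
            class = "homologue_preset")
}

#' @export
print.homologue_preset <- function(x, ...) {
  cat(sprintf("<homologue_preset> %s: Tm = %.1f K, k_f = %.4g 1/s, k_ass = %.3g 1/(M s)\n",
              x$label, x$thermal$Tm, x$kinetic$k_f, x$association$k_ass))
  invisible(x)
}

# Gaussian noise scaled to the model amplitude; returns model unchanged at
# sigma = 0 (no RNG draw, so sigma = 0 is bit-identical across seeds).
fk_add_noise <- function(model, sigma, seed, absolute = FALSE) {
  if (sigma < 0) fk_invalid_input("sigma must be non-negative")
  if (sigma == 0) return(model)
  if (is.null(seed)) fk_invalid_input("a seed is required when sigma > 0")
  sd_abs <- if (absolute) sigma else sigma * max(diff(range(model)), 1e-300)
  model + fk_with_seed(seed, stats::rnorm(length(model), 0, sd_abs))
}

#' Simulate equilibrium denaturation curves
#'
#' `simulate_chemical_curve()` evaluates the two-state urea-denaturation
#' observable on a grid and adds i.i.d. Gaussian noise of standard deviation
#' `sigma` times the signal range; `simulate_thermal_curve()` does the same
#' for a Gibbs-Helmholtz melt with `dCp = 0.014 * n_residues` kcal/(K mol).
#' Identical `(parameters, seed)` give identical output; `sigma = 0` gives
#' the noise-free model.
#'
#' @param m,midpoint Chemical-mode truth: m-value (kcal/(mol M)) and
#'   midpoint (M).
#' @param dHm,Tm,n_residues Thermal-mode truth: enthalpy (kcal/mol), melting
#'   temperature (K) and residue count fixing dCp.
#' @param baselines `(alpha_N, beta_N, alpha_D, beta_D)`; defaults emulate a
#'   sloping CD baseline.
#' @param grid Perturbation grid (urea M / temperature K).
#' @param sigma Noise standard deviation as a fraction of the signal range.
#' @param seed Integer seed (any integer, 0 included); only used when
#'   `sigma > 0`.
#' @param probe,temperature,constants Passed through to the curve container
#'   / forward model.
#'
#' @return A [denaturation_curve()] with the generating parameters attached
#'   as `attr(, "truth")`.
#' @examples
#' curve <- simulate_chemical_curve(m = 1.64, midpoint = 3.09,
#'                                  sigma = 0.01, seed = 1)
#' attr(curve, "truth")$m
#' @export
simulate_chemical_curve <- function(m, midpoint,
                                    baselines = c(1, -0.005, 0.1, -0.002),
                                    grid = seq(0, 8, length.out = 33),
                                    sigma = 0, seed = NULL,
                                    probe = "CD222", temperature = 298,
                                    constants = fk_constants()) {
  model <- two_state_signal(grid, dG_linear_urea(grid, m, midpoint), baselines,
                            temperature = temperature, R = constants$R)
  curve <- denaturation_curve(grid, fk_add_noise(model, sigma, seed),
                              probe = probe, mode = "chemical",
                              temperature = temperature)
  attr(curve, "truth") <- list(m = m, midpoint = midpoint,
                               baselines = baselines, sigma = sigma)
  curve
}

#' @rdname simulate_chemical_curve
#' @export
simulate_thermal_curve <- function(dHm, Tm, n_residues = 137,
                                   baselines = c(1, -0.002, 0.05, -0.0005),
                                   grid = seq(278, 368, by = 1),
                                   sigma = 0, seed = NULL,
                                   probe = "CD222",
                                   constants = fk_constants()) {
  dCp <- constants$dCp_per_residue * n_residues
  fN <- stats::plogis(dG_gibbs_helmholtz(grid, dHm, Tm, dCp) /
                        (constants$R * grid))
  model <- fN * (baselines[1] + baselines[2] * grid) +
    (1 - fN) * (baselines[3] + baselines[4] * grid)
  curve <- denaturation_curve(grid, fk_add_noise(model, sigma, seed),
                              probe = probe, mode = "thermal")
  attr(curve, "truth") <- list(dHm = dHm, Tm = Tm, n_residues = n_residues,
                               dCp = dCp, baselines = baselines, sigma = sigma)
  curve
}

#' Simulate stopped-flow transients
#'
#' Forward models for the three transient experiments:
#' `simulate_folding_transient()` is the single exponential with linear
#' drift, `simulate_association_transient()` the second-order dimerization
#' hyperbola with `k_app = c_N * k_ass`, and
#' `simulate_dissociation_transient()` the mono-exponential chasing rise.
#' Time grids are log-spaced by default, emulating logarithmic stopped-flow
#' sampling.
#'
#' @param a,k_obs,b,c0 Exponential-transient truth (amplitude, rate 1/s,
#'   drift signal/s, offset).
#' @param k_ass,c_N,S0,S_amp Association truth: bimolecular rate (1/(M s)),
#'   post-mix monomer concentration (M), initial signal and amplitude (the
#'   default negative amplitude emulates Trp quenching on dimerization).
#' @param k_diss,offset,amplitude Dissociation truth (rate 1/s, baseline,
#'   rise amplitude).
#' @param grid Time grid (s).
#' @param sigma Gaussian noise sd as a fraction of the model amplitude.
#' @param seed Integer seed; required when `sigma > 0`.
#' @return A [kinetic_transient()] with `attr(, "truth")`.
#' @examples
#' tr <- simulate_association_transient(k_ass = 2.19e9, c_N = 1e-7,
#'                                      sigma = 0.02, seed = 7)
#' attr(tr, "truth")$k_app
#' @export
simulate_folding_transient <- function(a = 1, k_obs = 100, b = 0, c0 = 0.2,
                                       grid = exp(seq(log(1e-4), log(10),
                                                      length.out = 500)),
                                       sigma = 0, seed = NULL) {
  model <- a * exp(-k_obs * grid) + b * grid + c0
  tr <- kinetic_transient(grid, fk_add_noise(model, sigma, seed),
                          experiment = if (a >= 0) "folding" else "unfolding")
  attr(tr, "truth") <- list(a = a, k_obs = k_obs, b = b, c0 = c0, sigma = sigma)
  tr
}

#' @rdname simulate_folding_transient
#' @export
simulate_association_transient <- function(k_ass, c_N, S0 = 1, S_amp = -0.5,
                                           grid = exp(seq(log(1e-4), log(10),
                                                          length.out = 500)),
                                           sigma = 0, seed = NULL) {
  if (c_N <= 0) fk_invalid_input("c_N must be positive")
  k_app <- c_N * k_ass
  model <- dimer_signal(grid, S0, S_amp, k_app)
  tr <- kinetic_transient(grid, fk_add_noise(model, sigma, seed),
                          experiment = "association", c_N = c_N)
  attr(tr, "truth") <- list(k_ass = k_ass, c_N = c_N, k_app = k_app,
                            S0 = S0, S_amp = S_amp, sigma = sigma)
  tr
}

#' @rdname simulate_folding_transient
#' @export
simulate_dissociation_transient <- function(k_diss, offset = 0.5,
                                            amplitude = 0.5,
                                            grid = exp(seq(log(1e-3), log(30),
                                                           length.out = 500)),
                                            sigma = 0, seed = NULL) {
  model <- offset + amplitude * (1 - exp(-k_diss * grid))
  tr <- kinetic_transient(grid, fk_add_noise(model, sigma, seed),
                          experiment = "dissociation")
  attr(tr, "truth") <- list(k_diss = k_diss, offset = offset,
                            amplitude = amplitude, sigma = sigma)
  tr
}

#' Simulate a chevron dataset
#'
#' Evaluates the two-state chevron ([chevron_log10_kobs()]) on a urea grid
#' and adds Gaussian noise of standard deviation `sigma_log` on
#' log10(k_obs), the scale on which chevron data are fitted.
#'
#' @param k_f,k_u,m_f,m_u Truth parameters (1/s; kcal/(mol M)).
#' @param grid Urea grid (M).
#' @param sigma_log Noise sd on log10(k_obs) (absolute).
#' @param seed Integer seed; required when `sigma_log > 0`.
#' @param temperature Temperature (K).
#' @param constants A [fk_constants()] list.
#' @return A [chevron_dataset()] with `attr(, "truth")`.
#' @export
simulate_chevron <- function(k_f, k_u, m_f, m_u,
                             grid = seq(0.5, 8, length.out = 16),
                             sigma_log = 0, seed = NULL, temperature = 298,
                             constants = fk_constants()) {
  lk <- chevron_log10_kobs(grid, k_f, k_u, m_f, m_u,
                           temperature = temperature, R = constants$R)
  lk <- fk_add_noise(lk, sigma_log, seed, absolute = TRUE)
  cv <- chevron_dataset(grid, 10^lk, temperature = temperature)
  attr(cv, "truth") <- list(k_f = k_f, k_u = k_u, m_f = m_f, m_u = m_u,
                            sigma_log = sigma_log)
  cv
}

#' Simulate an ionic-strength stability series
#'
#' `simulate_salt_series()` draws \eqn{\Delta G} values linear in
#' \eqn{\sqrt{I}} with slope `m_eq_prime`. `simulate_salt_melts()` builds
#' the full thermal pipeline input: for each ionic strength it shifts the
#' melting temperature by \eqn{\Delta T_m = \Delta\Delta G \cdot T_{m,ref} /
#' \Delta H_m} (the Schellman relation inverted) and generates a complete
#' melting curve, so that fitting the melts, converting with
#' [thermal_series_to_ddG()] and regressing on \eqn{\sqrt{I}} recovers
#' `m_eq_prime`.
#'
#' @param m_eq_prime Truth slope, kcal mol^-1 M^-0.5.
#' @param intercept Intercept of the \eqn{\Delta G} line (kcal/mol).
#' @param ionic_strength Ionic strengths (M).
#' @param sigma Gaussian noise sd on \eqn{\Delta G} (kcal/mol, absolute) for
#'   the series; fractional signal noise per melt for the melt generator.
#' @param seed Integer seed.
#' @param dHm,Tm_ref,n_residues Reference melt parameters for
#'   `simulate_salt_melts()`.
#' @return `simulate_salt_series()`: a chemical-source [salt_series()] with
#'   `attr(, "truth")`. `simulate_salt_melts()`: a list of
#'   [denaturation_curve()] melts (one per ionic strength, in order) with
#'   the shared truth attached to the list.
#' @export
simulate_salt_series <- function(m_eq_prime = 3.5, intercept = 2.0,
                                 ionic_strength = c(0.041, 0.1, 0.2, 0.5, 1.0),
                                 sigma = 0, seed = NULL) {
  dG <- intercept + m_eq_prime * sqrt(ionic_strength)
  dG <- fk_add_noise(dG, sigma, seed, absolute = TRUE)
  s <- salt_series(ionic_strength, dG = dG, source = "chemical")
  attr(s, "truth") <- list(m_eq_prime = m_eq_prime, intercept = intercept,
                           sigma = sigma)
  s
}

#' @rdname simulate_salt_series
#' @export
simulate_salt_melts <- function(m_eq_prime = 3.5, dHm = 54.8, Tm_ref = 329.9,
                                n_residues = 137,
                                ionic_strength = c(0.041, 0.1, 0.2, 0.5, 1.0),
                                sigma = 0, seed = NULL) {
  ddG <- m_eq_prime * (sqrt(ionic_strength) - sqrt(ionic_strength[1]))
  Tm <- Tm_ref + ddG * Tm_ref / dHm
  melts <- lapply(seq_along(ionic_strength), function(i) {
    simulate_thermal_curve(dHm = dHm, Tm = Tm[i], n_residues = n_residues,
                           sigma = sigma,
                           seed = if (is.null(seed)) NULL else seed + i)
  })
  attr(melts, "truth") <- list(m_eq_prime = m_eq_prime, dHm = dHm,
                               Tm = Tm, ionic_strength = ionic_strength,
                               n_residues = n_residues, sigma = sigma)
  melts
}

#' Generate synthetic data from a scenario description
#'
#' Single dispatch point over all generators: a scenario is a data kind, a
#' truth record (defaults drawn from a homologue [preset()]), an optional
#' grid, a noise level and a seed. Identical scenarios with identical seeds
#' produce identical data.
#'
#' @param kind One of `"chemical_curve"`, `"thermal_curve"`,
#'   `"folding_transient"`, `"association_transient"`,
#'   `"dissociation_transient"`, `"chevron"`, `"salt_series"`.
#' @param truth Named list of truth parameters for the kind (see the
#'   individual `simulate_*` functions). When a `preset_label` is given,
#'   missing entries are filled from that homologue's preset.
#' @param preset_label Optional homologue label (`"Lh"`, `"Lg"`, `"Nc"`,
#'   `"Ea"`).
#' @param grid Optional sampling grid override.
#' @param sigma Noise level (fraction of amplitude; absolute on log10 k_obs
#'   for chevrons and on dG for salt series).
#' @param seed Integer seed; required when `sigma > 0`.
#' @param probe For curves generated from a preset: which equilibrium probe
#'   parameters to use (`"CD"` or `"Fluo"`).
#' @return The corresponding data container with `attr(, "truth")`.
#' @examples
#' cv <- generate("chevron", preset_label = "Lh")
#' attr(cv, "truth")$k_f
#' @export
generate <- function(kind, truth = list(), preset_label = NULL, grid = NULL,
                     sigma = 0, seed = NULL, probe = "CD") {
  kinds <- c("chemical_curve", "thermal_curve", "folding_transient",
             "association_transient", "dissociation_transient", "chevron",
             "salt_series")
  if (!kind %in% kinds)
    fk_invalid_input(sprintf("unknown scenario kind '%s'", kind))
  if (!is.null(preset_label)) {
    p <- preset(preset_label)
    defaults <- switch(kind,
      chemical_curve = list(m = p$equilibrium[[probe]]$m,
                            midpoint = p$equilibrium[[probe]]$midpoint),
      thermal_curve = list(dHm = p$thermal$dHm, Tm = p$thermal$Tm),
      folding_transient = list(k_obs = with(p$kinetic, {
        RT <- 1.987e-3 * 298
        k_f * exp(-m_f * 3 / RT) + k_u * exp(m_u * 3 / RT)  # at 3 M urea
      })),
      association_transient = list(k_ass = p$association$k_ass, c_N = 1e-7),
      dissociation_transient = list(k_diss = p$association$k_diss),
      chevron = p$kinetic,
      salt_series = list())
    truth <- utils::modifyList(defaults, truth)
  }
  args <- c(truth, list(sigma = sigma, seed = seed))
  if (!is.null(grid)) args$grid <- grid
  gen <- switch(kind,
    chemical_curve = simulate_chemical_curve,
    thermal_curve = simulate_thermal_curve,
    folding_transient = simulate_folding_transient,
    association_transient = simulate_association_transient,
    dissociation_transient = simulate_dissociation_transient,
    chevron = function(...) {
      a <- list(...)
      names(a)[names(a) == "sigma"] <- "sigma_log"
      do.call(simulate_chevron, a)
    },
    salt_series = simulate_salt_series)
  do.call(gen, args)
}
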
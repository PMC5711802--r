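---
title: "Models and numerical methods in foldkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in foldkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldkin)
```

`foldkin` analyses the folding thermodynamics, folding kinetics and
self-association of small two-state protein domains, with the spidroin
N-terminal domain (NTD) family as its reference system. This vignette
documents the models, the assumptions behind them, the numerical choices
made where the analysis is genuinely open, and what the synthetic-data
generators do and do not emulate.

## Units and constants

Free energies are in kcal/mol, concentrations in M, temperatures in K,
unimolecular rates in s⁻¹ and bimolecular rates in M⁻¹ s⁻¹ throughout. The
gas constant is R = 1.987 × 10⁻³ kcal mol⁻¹ K⁻¹. Chemical-denaturation and
chevron fits evaluate RT at a reference temperature of 298 K, the
temperature at which such titrations and stopped-flow measurements are
standardly thermostatted; thermal fits use the running temperature of each
point inside the Boltzmann factor, since the temperature is the
perturbation itself. All three constants can be overridden through
`fk_constants()`.

## The two-state equilibrium model

Both equilibrium fits share the observable

$$S(P) = f_N(P)\,(\alpha_N + \beta_N P) + (1 - f_N(P))\,(\alpha_D + \beta_D P),
\qquad f_N = \frac{1}{1 + e^{-\Delta G(P)/RT}},$$

the population-weighted average of two linearly sloping baseline signals.
The assumptions are the usual ones: exactly two thermodynamic states, no
populated intermediates, and instrument response linear in the state
populations. Writing $f_N$ as a logistic (`stats::plogis`) rather than the
ratio of exponentials makes the expression overflow-free for arbitrarily
large $|\Delta G|/RT$; the identity is exercised against a literal
transcription of the ratio form in the test suite.

For urea denaturation, $\Delta G([\mathrm{urea}]) = m_{D\text{-}N}
([\mathrm{urea}]_{50\%} - [\mathrm{urea}])$. Parameterizing by midpoint
rather than intercept makes $\Delta G_{D\text{-}N} = m \cdot
[\mathrm{urea}]_{50\%}$ an identity of the fit result and keeps the two
fitted quantities close to orthogonal. For thermal melts,

$$\Delta G(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right) -
\Delta C_p\left[T_m - T + T \ln\frac{T}{T_m}\right],$$

with $\Delta C_p$ *fixed* at 0.014 kcal K⁻¹ mol⁻¹ per residue — the
generic per-residue increment for an unstructured polypeptide — because a
single melt over ~90 K cannot constrain enthalpy, midpoint, heat capacity
and four baseline coefficients simultaneously. The residue count is
therefore a required argument with no default (the CLI refuses thermal
fits without `--n-residues`): inventing a chain length silently would bias
every melt's curvature. The synthetic generator defaults to 137 residues,
a typical spidroin-NTD construct length.

Two forms of the propagated error of $\Delta G = m \cdot u_{50}$ are
reported: the independent-error form
$\sqrt{(u_{50}\sigma_m)^2 + (m\sigma_{u50})^2}$ and the full form including
the fitted $m$–midpoint covariance. Published tables of this kind rarely
state which convention was used and the two differ noticeably (the
covariance of $m$ and midpoint from a single-curve fit is non-negligible),
so both are exposed; `dG_se` carries the covariance form.

## Initial guesses, multi-start, and degenerate curves

Nonlinear least squares is by Levenberg–Marquardt (`minpack.lm::nlsLM`,
`ftol = ptol = 1e-13`). Convergence from automatic starts is part of the
contract, so the guesses are built from the data:

* **Chemical curves.** Baselines from linear fits to the outer 20 % of
  points at each end; the signal is normalized with those baselines; the
  midpoint is the location of the extremum of the 5-point-smoothed
  derivative, and the m-value follows from the transition steepness via
  $|df_N/dP| = m/4RT$ at the midpoint.
* **Thermal melts.** The edge heuristic fails when $\Delta C_p$ produces
  incipient *cold denaturation* at the low-temperature edge — the "native
  baseline" window is then already partially unfolded. Thermal guesses
  therefore locate the heat transition as the steepest *descent* of the raw
  smoothed signal (the cold limb rises and is ignored) and estimate
  baselines from windows adjacent to the transition, at 1.5–8 half-widths
  on either side. The enthalpy guess uses $|dS/dT| = |\Delta S_{sep}|
  \Delta H_m / 4RT_m^2$ at the midpoint.
* **Chevrons.** The data are split at the empirical minimum of
  $\log_{10} k_{obs}$ and a log-linear fit per limb supplies starting
  rates and m-values.
* **Transients.** The initial rate comes from log-linear regression of the
  absolute excess over the tail mean; amplitude sign is free so folding
  decays and unfolding rises are handled identically.

Each fit then runs up to five jittered restarts (±20 %, deterministic
jitter so identical data give identical results) and keeps the
lowest-deviance converged solution; thermal fits add one structured
alternative start (plain edge baselines, generic 60 kcal/mol enthalpy) as
insurance against transition-contaminated baseline windows. Thermal fits
are box-constrained to $\Delta H_m > 0$ and $T_m$ inside the scanned
range: without the bound, melts whose midpoint approaches the grid edge
admit a spurious solution that fits the cold-denaturation limb with a
negative enthalpy.

A monotone curve with no resolvable sigmoid would let the six-parameter
model chase noise, so the two-state fit is compared with a straight line
and rejected (`fk_degenerate_curve`) unless it wins by at least 10 AIC
units — a decisive margin on any genuinely cooperative transition.

## Chevron analysis

The barrier-limited two-state chevron

$$\log k_{obs} = \log\left[k_f e^{-m_{TS\text{-}D}[\mathrm{urea}]/RT} +
k_u e^{+m_{TS\text{-}N}[\mathrm{urea}]/RT}\right]$$

is fitted with residuals in $\log_{10} k_{obs}$: the model is stated in
log form, observed rates span roughly four orders of magnitude across the
two limbs, and log residuals weight both limbs equally where linear
residuals would let the folding limb dominate. The model itself is
evaluated by log-sum-exp, and the rates are parameterized as $\ln k_f$,
$\ln k_u$ internally (positivity for free; reported standard errors are
delta-method transforms). Rate extraction from transients and chevron
fitting are deliberately separate stages — each transient is fitted on its
own and only the $(u, k_{obs})$ pairs enter the chevron — matching how
such experiments are analysed in practice; no global fit across transients
is attempted. Derived quantities are $\Delta G = -RT\ln(k_u/k_f)$,
$\beta_T = m_f/(m_f + m_u)$ and the kinetic m-value sum, and a
configurable consistency check (default 20 % relative discrepancy) flags
agreement between the equilibrium and kinetic routes.

## Dimerization kinetics

The association observable is the closed-form solution of second-order
monomer consumption mapped onto the dimerized fraction,
$S(t) = S_0 + S\,(k_{app}t)/(1+k_{app}t)$, with $k_{app} = c_N k_{ass}$.
This defining relation between the apparent and bimolecular rate constants
is adopted literally as the package's primary convention
(`stoichiometry_factor = 1`), because it is the convention under which the
reference $k_{ass}$ values of the NTD family are stated. The textbook
monomer-loss bookkeeping $d[N]/dt = -2k_{ass}[N]^2$, which makes
$k_{app} = 2c_N k_{ass}$, is available as `stoichiometry_factor = 2`; the
numerical ODE oracle in the tests integrates whichever convention is
active and agrees with the closed form to better than 10⁻⁶ relative error.
The amplitude sign is unconstrained (Trp fluorescence is quenched on
dimerization, so association amplitudes are typically negative), an
optional fit-window start time excludes early-time deviations from trace
oligomers, and $c_N$ can be derived from a pre-mix concentration and a
volumetric mixing ratio such as `1:11` (post-mix = premix/12).
Dissociation transients from chasing experiments are fitted to the
three-parameter rise $c + a(1 - e^{-k_{diss}t})$; a flat trace makes the
rate unidentifiable and raises a fit failure rather than returning an
arbitrary number. $K_d = k_{diss}/k_{ass}$ with the usual relative-error
propagation.

## Ionic-strength (Debye–Hückel) analysis

Counter-ion screening of surface charges makes the unfolding free energy
of a charged domain empirically linear in $\sqrt{I}$; the slope
$m'_{eq}$ (kcal mol⁻¹ M⁻⁰·⁵) is the ionic-strength analogue of a
denaturant m-value. The package fits it by unweighted ordinary least
squares — no ion-cloud physics is modelled, only the empirical linear law.
Thermal series are first converted to stability changes with the Schellman
relation $\Delta\Delta G = \Delta S_m \Delta T_m$, where the midpoint
entropy $\Delta S_m = \Delta H_m/T_m$ is taken from the
lowest-ionic-strength melt. Fixing the conversion entropy (rather than
re-deriving it from whichever point anchors $\Delta\Delta G = 0$) makes
the choice of anchor a pure intercept shift that provably cannot move the
fitted slope; per-point entropies are available as an option.
Chemical-denaturation series regress absolute $\Delta G$ — the slope is
invariant to that choice too.

## The synthetic-data generators

Each generator evaluates the exact forward model of the corresponding fit
on a realistic grid and adds i.i.d. Gaussian noise scaled to the signal
amplitude (absolute on $\log_{10} k_{obs}$ for chevrons, where the fit
residuals live). Default grids mirror standard practice: urea titrations
0–8 M at 33 points, melts 278–368 K at 1 K, transients log-spaced over
10⁻⁴–10 s at 500 points (emulating logarithmic stopped-flow sampling),
chevrons 0.5–8 M at 16 points, salt series over 0.041–1.0 M. The default
noise level of 1 % of amplitude reflects the residual scatter typical of
averaged CD and stopped-flow traces; true instrument noise levels are not
published for the reference data, so sigma remains a free scenario
parameter and is never asserted against published values. Seeding is
per-scenario (a seed of 0 is valid) and the generators save and restore
the caller's RNG state, so no global stream is disturbed; identical
scenario and seed give bit-identical data.

What the generators do **not** emulate: photon shot noise and other
heteroscedasticity, lamp flicker, mixing artefacts beyond a linear drift,
dead-time signal loss, thermal-ramp hysteresis, or the slow irreversible
aggregation that can follow thermal unfolding. Passing parameter-recovery
tests on these synthetics therefore demonstrates the correctness and
calibration of the estimators under the stated noise model — not
robustness to every instrumental pathology of real data. The published
per-homologue parameter sets (`preset()`) serve as ground-truth scenarios
for round-trip testing, which is the only curve-level validation possible:
the original raw spectroscopic datasets are not publicly deposited.

## Problem sizes and verification

The test suite verifies, among others: noise-free round trips of every fit
type for all four homologue presets to at least three significant figures;
closed-form/oracle equivalence (dimerization hyperbola vs. numerical ODE
integration, chevron vs. brute-force branch summation, OLS slope vs.
normal equations); and statistical calibration over 100 seeded noisy
replicates per scenario at 1–2 % noise, requiring median parameter bias
below 5 % and at least 90 % empirical coverage of ±2σ intervals. The
ionic-strength pipeline is verified end-to-end (melts → Schellman →
regression) to recover a known slope within 5 % at 1 % signal noise; the
chemical-denaturation route to $m'_{eq}$ is intrinsically less precise —
with four ionic strengths and realistic noise its slope carries a standard
error of several tenths, consistent with the larger uncertainty published
for that route. These sizes were chosen to exercise realistic experimental
designs while keeping the full suite fast enough to run on every change.

## Known limitations

* Strictly two-state: no intermediate or three-state models, no
  double-exponential transients, and no global multi-curve fitting.
* $\Delta C_p$ is fixed, never fitted; thermal enthalpies inherit any
  error in the per-residue heat-capacity estimate.
* The chasing-dissociation experiment is reduced to a mono-exponential;
  the labelled/unlabelled exchange equilibrium is not modelled explicitly.
* Reported uncertainties are asymptotic least-squares errors; replicate
  scatter across repeated experiments, where available, is typically
  larger.
* No CD spectral deconvolution, mean-residue-ellipticity conversion, or
  molecular-structure computation.
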
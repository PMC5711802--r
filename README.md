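# foldkin

Thermodynamic and kinetic analysis of two-state protein folding and
self-association, built around the N-terminal domain (NTD) of spider silk
proteins (spidroins). The NTD is a small, ~14 kDa five-helix bundle that
works as a pH-driven dimerization switch during silk spinning: it folds on
sub-millisecond time scales, dimerizes with low-nanomolar affinity when the
pH drops along the spinning duct, and its stability is tuned by
Debye-Hückel screening of its unusually clustered surface charges. The
package implements the complete analysis chain such experiments need, for
anyone fitting equilibrium denaturation curves, stopped-flow transients or
chevron plots of small two-state folders.

## What it computes

**Equilibrium denaturation.** A spectroscopic signal (CD at 222 nm, Trp
fluorescence) along a perturbation *P* (urea or temperature) is fitted to
the two-state observable with linearly sloping baselines,

    S(P) = [α_N + β_N·P + (α_D + β_D·P)·exp(−ΔG(P)/RT)] / [1 + exp(−ΔG(P)/RT)]

with ΔG([urea]) = ΔG_D−N − m_D−N·[urea] (linear free-energy relationship;
ΔG_D−N = m_D−N·[urea]₅₀%) for chemical denaturation, and the
Gibbs-Helmholtz form ΔG(T) = ΔH_m(1 − T/T_m) − ΔC_p[T_m − T + T·ln(T/T_m)]
for thermal melts, ΔC_p fixed at 0.014 kcal K⁻¹ mol⁻¹ per residue.
Midpoint shifts convert to stability changes via the Schellman relation
ΔΔG = (ΔH_m/T_m)·ΔT_m.

**Folding kinetics.** Stopped-flow transients are fitted to
S(t) = a·exp(−k_obs·t) + b·t + c (single exponential plus instrumental
drift); observed rates versus denaturant are fitted to the two-state
chevron log k_obs = log[k_f·e^(−m_TS−D[urea]/RT) + k_u·e^(+m_TS−N[urea]/RT)],
giving ΔG = −RT·ln(k_u/k_f) and the Tanford value β_T = m_f/(m_f + m_u).

**Dimerization.** Association transients follow the second-order closed
form S(t) = S₀ + S·(k_app·t)/(1 + k_app·t) with k_app = c_N·k_ass;
chasing-dissociation transients are mono-exponential rises yielding k_diss;
the affinity is K_d = k_diss/k_ass.

**Electrostatics.** Stability versus ionic strength *I* is summarized by
the slope m_eq′ of ΔG against √I (ordinary least squares), the
ionic-strength analogue of a denaturant m-value.

A seeded generator (`simulate_*`, `generate()`, `preset()`) emulates every
data kind with known ground truth, including presets for the four published
NTD homologues (Lh, Lg, Nc, Ea).

## Worked example

```r
library(foldkin)

# a urea denaturation curve with 1 % noise, truth m = 1.64, midpoint = 3.09
curve <- simulate_chemical_curve(m = 1.64, midpoint = 3.09, sigma = 0.01, seed = 1)
eq <- fit_chemical_denaturation(curve)
eq
#> Two-state chemical denaturation fit
#>   m_D-N      = 1.64 +/- 0.05 kcal/(mol M)
#>   [urea]50%  = 3.07 +/- 0.01 M
#>   dG_D-N     = 5.04 +/- 0.16 kcal/mol

# chevron analysis of observed folding/unfolding rates
chev <- simulate_chevron(k_f = 10123, k_u = 4.67, m_f = 1.29, m_u = 0.22,
                         sigma_log = 0.02, seed = 1)
kin <- fit_chevron(chev)
kin
#> Two-state chevron fit
#>   k_f = 9922 1/s, m_TS-D = 1.28 kcal/(mol M)
#>   k_u = 4.877 1/s, m_TS-N = 0.22 kcal/(mol M)
#>   dG_kin = 4.51 kcal/mol, beta_T = 0.86

# is the protein two-state? equilibrium vs kinetic free energies and m-values
consistency_report(eq, kin)
#> dG: 5.04 (eq) vs 4.51 (kin) kcal/mol  [11.1%]
#> m:  1.64 (eq) vs 1.50 (m_f + m_u) kcal/(mol M)  [9.2%]
#> -> two-state consistent

# dimer affinity from measured rate constants
compute_Kd(0.31, 2.19e9, se_k_diss = 0.02, se_k_ass = 0.30e9)
#> K_d = 0.14 +/- 0.02 nM
```

The fitted m-value and midpoint reproduce the generating truth within their
standard errors; ΔG from rates (4.51 kcal/mol) agrees with the equilibrium
value (5.04 kcal/mol) within the ~20 % band expected of a two-state folder,
and the sub-nanomolar K_d reflects diffusion-limited association (~10⁹
M⁻¹ s⁻¹) against ~0.3 s⁻¹ dissociation.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/foldkin.R simulate --kind chevron --preset Lh --sigma 0.02 --seed 42 --out chev.csv
Rscript inst/cli/foldkin.R fit-chevron chev.csv
Rscript inst/cli/foldkin.R kd --k-ass 2.19e9 --k-diss 0.31
```

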
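#' Convert a thermal ionic-strength series to stability changes
#'
#' Applies the Schellman relation ([schellman_ddG()]) across an
#' ionic-strength series of melting temperatures:
#' \eqn{\Delta\Delta G_i = \Delta S_m (T_{m,i} - T_{m,ref})} with the
#' midpoint entropy \eqn{\Delta S_m = \Delta H_m / T_m} taken from the
#' lowest-ionic-strength melt. The `reference` argument only chooses which
#' point is anchored at \eqn{\Delta\Delta G = 0}; because the conversion
#' entropy is fixed, changing the anchor shifts all values by a constant
#' and leaves any subsequent slope fit unchanged.
#'
#' @param series A [salt_series()] with `source = "thermal"`.
#' @param reference Index of the zero-anchor point (default: lowest ionic
#'   strength, i.e. 1 after sorting).
#' @param dHm_source `"reference"` (default): use the lowest-ionic-strength
#'   melt's entropy throughout; `"per_point"`: use each point's own
#'   \eqn{\Delta H_m / T_m}.
#' @return A chemical-source [salt_series()] whose `dG` column holds the
#'   \eqn{\Delta\Delta G} values (kcal/mol).
#' @export
thermal_series_to_ddG <- function(series, reference = 1L,
                                  dHm_source = c("reference", "per_point")) {
  dHm_source <- match.arg(dHm_source)
  if (!inherits(series, "salt_series") || series$source != "thermal")
    fk_invalid_input("thermal_series_to_ddG needs a thermal-source salt_series")
  n <- length(series$ionic_strength)
  if (reference < 1L || reference > n)
    fk_invalid_input("reference index out of range")
  if (!is.finite(series$dHm[1]))
    fk_invalid_input("missing dHm at the lowest-ionic-strength point")
  dS <- if (dHm_source == "reference") rep(series$dHm[1] / series$Tm[1], n)
        else series$dHm / series$Tm
  Tm_ref <- series$Tm[reference]
  ddG <- dS * (series$Tm - Tm_ref)
  salt_series(series$ionic_strength, dG = ddG, source = "chemical",
              label = series$label)
}

#' Debye-Hueckel slope of stability versus ionic strength
#'
#' Counter-ion clouds screen Coulombic interactions over a length that
#' scales with \eqn{1/\sqrt{I}}; empirically the unfolding free energy of a
#' charged domain is linear in \eqn{\sqrt{I}}. This fits
#' \eqn{\Delta G = m_{eq}' \sqrt{I} + b} by ordinary least squares; the
#' slope \eqn{m_{eq}'} (kcal mol^-1 M^-0.5) plays the role of an
#' ionic-strength m-value.
#'
#' @param series A chemical-source [salt_series()] (absolute \eqn{\Delta G}
#'   or Schellman \eqn{\Delta\Delta G}; the slope is invariant to the
#'   choice of reference).
#' @return An object of class `salt_fit` with `m_eq_prime`, `intercept`,
#'   `std_errors`, `r_squared` and the underlying data.
#' @examples
#' s <- salt_series(c(0.041, 0.1, 0.2, 0.5, 1),
#'                  dG = 2 + 3.5 * sqrt(c(0.041, 0.1, 0.2, 0.5, 1)))
#' fit_debye_huckel_slope(s)$m_eq_prime
#' @export
fit_debye_huckel_slope <- function(series) {
  if (!inherits(series, "salt_series") || series$source != "chemical" ||
      is.null(series$dG))
    fk_invalid_input("fit_debye_huckel_slope needs a salt_series carrying dG values")
  sqrtI <- sqrt(series$ionic_strength)
  fit <- stats::lm(series$dG ~ sqrtI)
  # summary.lm warns on noise-free data ("essentially perfect fit")
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(m_eq_prime = unname(co["sqrtI", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 std_errors = c(m_eq_prime = unname(co["sqrtI", "Std. Error"]),
                                intercept = unname(co["(Intercept)", "Std. Error"])),
                 r_squared = sm$r.squared,
                 sqrt_I = sqrtI, dG = series$dG, label = series$label),
            class = c("salt_fit", "fk_fit"))
}

#' @export
print.salt_fit <- function(x, ...) {
  cat(sprintf("Debye-Hueckel slope: m_eq' = %.2f +/- %.2f kcal/(mol M^0.5)  (R^2 = %.3f)\n",
              x$m_eq_prime, x$std_errors["m_eq_prime"], x$r_squared))
  invisible(x)
}

#' Summarize Debye-Hueckel slopes across homologues
#'
#' Mean and standard error of the mean of the per-homologue
#' \eqn{m_{eq}'} slopes.
#'
#' @param fits A named list of `salt_fit` objects, or a named numeric vector
#'   of slopes.
#' @return A list with `slopes` (named), `mean` and `sem` (`NA` for a single
#'   slope).
#' @examples
#' homologue_summary(c(Ea = 3.6, Nc = 3.4, Lh = 3.5, Lg = 3.4))
#' @export
homologue_summary <- function(fits) {
  if (length(fits) < 1L) fk_invalid_input("need at least one fit")
  slopes <- if (is.numeric(fits)) fits
            else vapply(fits, function(f) f$m_eq_prime, numeric(1))
  sem <- if (length(slopes) > 1L) stats::sd(slopes) / sqrt(length(slopes))
         else NA_real_
  list(slopes = slopes, mean = mean(slopes), sem = sem)
}
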
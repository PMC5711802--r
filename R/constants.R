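#' Physical constants and unit conventions
#'
#' All free energies in the package are in kcal/mol, concentrations in M,
#' temperatures in K, unimolecular rate constants in 1/s and bimolecular rate
#' constants in 1/(M s). `fk_constants()` collects the constants every fit
#' uses; pass a modified copy to override them.
#'
#' @param R Gas constant, kcal/(mol K).
#' @param T_ref Reference temperature (K) at which RT is evaluated for
#'   chemical-denaturation and chevron fits.
#' @param dCp_per_residue Empirical heat-capacity increment of unfolding per
#'   residue, kcal/(K mol). Multiplied by the residue count to fix the total
#'   heat-capacity change of a thermal melt.
#'
#' @return A list of class `fk_constants` with elements `R`, `T_ref`,
#'   `dCp_per_residue`.
#' @examples
#' cst <- fk_constants()
#' cst$R * cst$T_ref  # RT at the reference temperature, kcal/mol
#' @export
fk_constants <- function(R = 1.987e-3, T_ref = 298.0, dCp_per_residue = 0.014) {
  stopifnot(R > 0, T_ref > 0, dCp_per_residue >= 0)
  structure(list(R = R, T_ref = T_ref, dCp_per_residue = dCp_per_residue),
            class = "fk_constants")
}

# Shared condition constructors. All package errors carry a subclass so
# callers (and the CLI) can distinguish bad input from a failed optimisation.
fk_stop <- function(subclass, message, ...) {
  stop(structure(class = c(subclass, "fk_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

fk_invalid_input <- function(message, ...) fk_stop("fk_invalid_input", message, ...)
fk_fit_failure <- function(message, ...) fk_stop("fk_fit_failure", message, ...)
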
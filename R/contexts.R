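#' Boltzmann constant in kJ mol^-1 K^-1
#'
#' Molar Boltzmann (gas) constant used throughout the package, both for the
#' Boltzmann weighting of per-simulation free energies and as R in the
#' Cheng-Prusoff free-energy conversion.
#'
#' @format Length-one numeric, 0.0083145 kJ mol^-1 K^-1.
#' @export
KB_KJ_PER_MOL_K <- 0.0083145

#' Thermodynamic context for weighting and affinity conversion
#'
#' Bundles the two temperatures the method needs: the simulation temperature
#' at which per-simulation free energies are Boltzmann-weighted, and the
#' assay temperature entering \eqn{RT \ln K_i} when experimental IC50 values
#' are converted to binding free energies.
#'
#' @param temperature_weighting Simulation temperature in kelvin used in the
#'   Boltzmann weights. Default 300 K, the production-MD temperature of the
#'   packaged dataset.
#' @param temperature_assay Assay temperature in kelvin used in the
#'   Cheng-Prusoff conversion. Default 310 K (physiological), which
#'   reproduces the packaged dataset's tabulated free energies.
#'
#' @return An object of class `thermo_context` with fields
#'   `temperature_weighting`, `temperature_assay` and `k_B`.
#' @seealso [assay_context()], [boltzmann_weights()], [dg_from_ic50()]
#' @examples
#' thermo_context()
#' thermo_context(temperature_weighting = 298)
#' @export
thermo_context <- function(temperature_weighting = 300,
                           temperature_assay = 310) {
  stopifnot(is.numeric(temperature_weighting), length(temperature_weighting) == 1,
            is.numeric(temperature_assay), length(temperature_assay) == 1)
  if (!is.finite(temperature_weighting) || temperature_weighting <= 0)
    stop("`temperature_weighting` must be a positive, finite kelvin value", call. = FALSE)
  if (!is.finite(temperature_assay) || temperature_assay <= 0)
    stop("`temperature_assay` must be a positive, finite kelvin value", call. = FALSE)
  structure(
    list(temperature_weighting = temperature_weighting,
         temperature_assay = temperature_assay,
         k_B = KB_KJ_PER_MOL_K),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat("<thermo_context>\n",
      "  weighting T: ", x$temperature_weighting, " K\n",
      "  assay T:     ", x$temperature_assay, " K\n",
      "  k_B:         ", x$k_B, " kJ mol^-1 K^-1\n", sep = "")
  invisible(x)
}

#' Enzyme-assay context for the Cheng-Prusoff conversion
#'
#' Substrate concentration and Michaelis constant of the competitive
#' inhibition assay, both in molar units. They enter the Cheng-Prusoff
#' relation \eqn{K_i = IC_{50} / (1 + [S]/K_m)}.
#'
#' @param substrate_conc Substrate concentration \[S\] in mol/L; must be >= 0
#'   (zero recovers the no-substrate limit \eqn{K_i = IC_{50}}).
#' @param km Michaelis constant K_m in mol/L; must be > 0.
#'
#' @return An object of class `assay_context`.
#' @seealso [ki_from_ic50()], [aryloxypropanolamine_assay()]
#' @examples
#' assay_context(substrate_conc = 1.5e-6, km = 0.5e-6)
#' @export
assay_context <- function(substrate_conc, km) {
  stopifnot(is.numeric(substrate_conc), length(substrate_conc) == 1,
            is.numeric(km), length(km) == 1)
  if (!is.finite(substrate_conc) || substrate_conc < 0)
    stop("`substrate_conc` must be finite and >= 0 (molar)", call. = FALSE)
  if (!is.finite(km) || km <= 0)
    stop("`km` must be finite and > 0 (molar)", call. = FALSE)
  structure(list(substrate_conc = substrate_conc, km = km),
            class = "assay_context")
}

#' @export
print.assay_context <- function(x, ...) {
  cat("<assay_context> [S] = ", x$substrate_conc * 1e6, " uM, Km = ",
      x$km * 1e6, " uM\n", sep = "")
  invisible(x)
}

#' Assay constants of the packaged aryloxypropanolamine dataset
#'
#' The AMMC-conversion inhibition assay behind the packaged CYP 2D6 dataset:
#' substrate concentration 1.5 uM and Michaelis constant 0.5 uM, so
#' \eqn{K_i = IC_{50}/4}.
#'
#' @return An [assay_context()] with `substrate_conc = 1.5e-6` and
#'   `km = 0.5e-6` mol/L.
#' @export
aryloxypropanolamine_assay <- function() {
  assay_context(substrate_conc = 1.5e-6, km = 0.5e-6)
}
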
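#' Inhibition constant from IC50 via the Cheng-Prusoff relation
#'
#' For a competitive inhibitor measured against a substrate at concentration
#' \[S\] with Michaelis constant K_m,
#' \deqn{K_i = \frac{IC_{50}}{1 + [S]/K_m}.}
#'
#' @param ic50 IC50 in mol/L; strictly positive. Vectorized.
#' @param assay An [assay_context()].
#' @return K_i in mol/L.
#' @examples
#' # [S] = 1.5 uM, Km = 0.5 uM: Ki = IC50 / 4
#' ki_from_ic50(18e-6, aryloxypropanolamine_assay())
#' @export
ki_from_ic50 <- function(ic50, assay) {
  stopifnot(inherits(assay, "assay_context"), is.numeric(ic50))
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("`ic50` must be finite and > 0 (molar)", call. = FALSE)
  ic50 / (1 + assay$substrate_conc / assay$km)
}

#' Binding free energy from IC50 via Cheng-Prusoff
#'
#' Converts an IC50 to an experimental binding free energy estimate,
#' \deqn{\Delta G_{exp} = R T \ln\left(K_i / 1\,\mathrm{M}\right),}
#' with \eqn{K_i} from [ki_from_ic50()], R = 0.0083145 kJ mol^-1 K^-1 and
#' T the assay temperature of `thermo`. The 1 M standard state makes the
#' logarithm's argument dimensionless; sub-molar K_i gives negative
#' free energies.
#'
#' @inheritParams ki_from_ic50
#' @param thermo A [thermo_context()]; its `temperature_assay` is used.
#' @return Binding free energy in kJ mol^-1. Vectorized over `ic50`.
#' @examples
#' dg_from_ic50(18e-6, aryloxypropanolamine_assay(), thermo_context())
#' # -31.73 kJ/mol
#' @export
dg_from_ic50 <- function(ic50, assay, thermo = thermo_context()) {
  stopifnot(inherits(thermo, "thermo_context"))
  ki <- ki_from_ic50(ic50, assay)
  thermo$k_B * thermo$temperature_assay * log(ki)
}

#' Fill experimental free energies for a compound table
#'
#' For every compound whose `dg_exp` is missing, computes it from `ic50` via
#' [dg_from_ic50()]; compounds with a preexisting `dg_exp` pass through
#' unchanged. Train/test compounds with neither field raise an error naming
#' the compound.
#'
#' @param compounds Compound data frame with at least `compound_id`, `ic50`,
#'   `dg_exp` columns (see [aryloxypropanolamine_compounds()] for the
#'   layout).
#' @inheritParams dg_from_ic50
#' @return The compound data frame with `dg_exp` filled; the range of the
#'   newly converted values is reported via `message()` when any conversion
#'   happened.
#' @export
convert_compounds <- function(compounds, assay, thermo = thermo_context()) {
  compounds <- as.data.frame(compounds)
  check_columns(compounds, c("compound_id", "ic50", "dg_exp"), "compounds")
  if (nrow(compounds) == 0) return(compounds)
  neither <- is.na(compounds$ic50) & is.na(compounds$dg_exp)
  if ("role" %in% names(compounds))
    neither <- neither & compounds$role %in% c("train", "test")
  if (any(neither))
    stop("compound(s) with neither ic50 nor dg_exp: ",
         paste(compounds$compound_id[neither], collapse = ", "),
         call. = FALSE)
  todo <- is.na(compounds$dg_exp) & !is.na(compounds$ic50)
  if (any(todo)) {
    compounds$dg_exp[todo] <-
      dg_from_ic50(compounds$ic50[todo], assay, thermo)
    message(sprintf("converted %d IC50 value(s); dg_exp range %.2f .. %.2f kJ/mol",
                    sum(todo), min(compounds$dg_exp[todo]),
                    max(compounds$dg_exp[todo])))
  }
  compounds
}
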
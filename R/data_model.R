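# Tabular containers. A dataset is three plain data.frames:
#   simulations: one row per (compound, template, pose, replicate) bound-state
#                MD average
#   free_states: one row per compound, the unbound ligand-in-water averages
#   compounds:   experimental/bookkeeping record per compound (optional)
# All energies in kJ mol^-1, concentrations in mol/L.

SIM_COLS      <- c("compound_id", "template_id", "pose_id", "replicate_id",
                   "v_vdw_bound", "v_el_bound")
FREE_COLS     <- c("compound_id", "v_vdw_free", "v_el_free")
COMPOUND_COLS <- c("compound_id", "ic50", "dg_exp", "molar_mass",
                   "net_charge", "role")

sim_key <- function(sim) {
  paste(sim$compound_id, sim$template_id, sim$pose_id, sim$replicate_id,
        sep = "\r")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

check_finite <- function(df, cols, what) {
  for (cl in cols) {
    bad <- !is.finite(df[[cl]])
    if (any(bad))
      stop(sprintf("%s table has non-finite values in `%s` (rows %s)",
                   what, cl, paste(which(bad), collapse = ", ")),
           call. = FALSE)
  }
  invisible(df)
}

#' Assemble and validate an interaction-energy dataset
#'
#' Bundles bound-state simulation averages, free-state averages and (optional)
#' compound records into a validated `energy_dataset`. Validation enforces:
#' unique (compound, template, pose, replicate) simulation keys; finite
#' energies; exactly one free-state row per compound; a free-state entry for
#' every simulated compound; and, when compound records are given, that every
#' train/test compound carries an affinity (`ic50` or `dg_exp`) and at least
#' one simulation.
#'
#' @param simulations Data frame with columns `compound_id`, `template_id`,
#'   `pose_id`, `replicate_id`, `v_vdw_bound`, `v_el_bound` and optionally
#'   `n_frames`. One row per bound-state MD simulation average (kJ mol^-1).
#' @param free_states Data frame with columns `compound_id`, `v_vdw_free`,
#'   `v_el_free`; one row per compound (kJ mol^-1).
#' @param compounds Optional data frame with columns `compound_id`, `ic50`
#'   (mol/L, may be `NA`), `dg_exp` (kJ mol^-1, may be `NA`), `molar_mass`,
#'   `net_charge`, `role` (`"train"`, `"test"` or `"query"`).
#'
#' @return An object of class `energy_dataset`: a list with elements
#'   `simulations`, `free_states`, `compounds`.
#' @seealso [read_energy_dataset()], [write_energy_dataset()]
#' @export
energy_dataset <- function(simulations, free_states, compounds = NULL) {
  simulations <- as.data.frame(simulations)
  free_states <- as.data.frame(free_states)
  check_columns(simulations, SIM_COLS, "simulations")
  check_columns(free_states, FREE_COLS, "free_states")
  if (!"n_frames" %in% names(simulations))
    simulations$n_frames <- rep(NA_real_, nrow(simulations))

  if (nrow(simulations) > 0) {
    check_finite(simulations, c("v_vdw_bound", "v_el_bound"), "simulations")
    key <- sim_key(simulations)
    if (anyDuplicated(key)) {
      dup <- which(key %in% key[duplicated(key)])
      stop("duplicate (compound, template, pose, replicate) key(s) in rows: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(free_states) > 0) {
    check_finite(free_states, c("v_vdw_free", "v_el_free"), "free_states")
    if (anyDuplicated(free_states$compound_id))
      stop("free_states must have exactly one row per compound; duplicated: ",
           paste(unique(free_states$compound_id[
             duplicated(free_states$compound_id)]), collapse = ", "),
           call. = FALSE)
  }
  orphan <- setdiff(unique(simulations$compound_id), free_states$compound_id)
  if (length(orphan) > 0)
    stop("simulated compound(s) without a free-state entry: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  if (!is.null(compounds)) {
    compounds <- as.data.frame(compounds)
    check_columns(compounds, COMPOUND_COLS, "compounds")
    if (anyDuplicated(compounds$compound_id))
      stop("duplicated compound_id in compounds table", call. = FALSE)
    bad_role <- !compounds$role %in% c("train", "test", "query")
    if (any(bad_role))
      stop("compound role must be train/test/query; offending: ",
           paste(compounds$compound_id[bad_role], collapse = ", "),
           call. = FALSE)
    tt <- compounds$role %in% c("train", "test")
    no_aff <- tt & is.na(compounds$ic50) & is.na(compounds$dg_exp)
    if (any(no_aff))
      stop("train/test compound(s) without ic50 or dg_exp: ",
           paste(compounds$compound_id[no_aff], collapse = ", "),
           call. = FALSE)
    bad_ic50 <- !is.na(compounds$ic50) & compounds$ic50 <= 0
    if (any(bad_ic50))
      stop("non-positive ic50 for compound(s): ",
           paste(compounds$compound_id[bad_ic50], collapse = ", "),
           call. = FALSE)
    unsim <- tt & !compounds$compound_id %in% simulations$compound_id
    if (any(unsim))
      stop("train/test compound(s) without any simulation: ",
           paste(compounds$compound_id[unsim], collapse = ", "),
           call. = FALSE)
  }

  structure(list(simulations = simulations,
                 free_states = free_states,
                 compounds = compounds),
            class = "energy_dataset")
}

#' @export
print.energy_dataset <- function(x, ...) {
  cat("<energy_dataset> ",
      nrow(x$simulations), " simulation rows, ",
      nrow(x$free_states), " free-state compounds",
      if (!is.null(x$compounds))
        paste0(", ", nrow(x$compounds), " compound records"),
      "\n", sep = "")
  invisible(x)
}

#' Compound records of the packaged aryloxypropanolamine dataset
#'
#' Loads the packaged set of 17 aryloxypropanolamine CYP 2D6 inhibitors:
#' 9 training and 8 test compounds with assay IC50 (converted from uM to
#' mol/L on load), tabulated binding free energy, molar mass and net charge.
#'
#' One caveat travels with the data: the IC50 of compound `lig08` is stored
#' to two significant figures (0.28 uM), and recomputing its free energy from
#' that rounded IC50 gives a value about 0.1 kJ mol^-1 away from the
#' tabulated -42.56 kJ mol^-1; all other 16 compounds recompute to within
#' 0.005 kJ mol^-1 (see [dg_from_ic50()]).
#'
#' @return Data frame with columns `compound_id`, `ic50` (mol/L), `dg_exp`
#'   (kJ mol^-1), `molar_mass` (g/mol), `net_charge` (e), `role`.
#' @seealso [aryloxypropanolamine_assay()], [convert_compounds()]
#' @examples
#' cmp <- aryloxypropanolamine_compounds()
#' table(cmp$role)
#' range(cmp$dg_exp)
#' @export
aryloxypropanolamine_compounds <- function() {
  path <- system.file("extdata", "aryloxypropanolamines.csv",
                      package = "boltzlie", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(compound_id = raw$compound_id,
             ic50 = raw$ic50_uM * 1e-6,
             dg_exp = raw$dg_exp_kJ_mol,
             molar_mass = raw$molar_mass_g_mol,
             net_charge = raw$net_charge_e,
             role = raw$role,
             stringsAsFactors = FALSE)
}
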
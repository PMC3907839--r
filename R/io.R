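# CSV readers/writers for the two-table energy schema. UTF-8, decimal point,
# header required. Numbers are written at full double precision so a
# write/read round trip is an identity on the data.

read_checked_csv <- function(path, required, what, numeric_cols) {
  if (!file.exists(path))
    stop(sprintf("%s file does not exist: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_columns(df, required, what)
  for (cl in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[cl]])) {
      suppressWarnings(converted <- as.numeric(df[[cl]]))
      bad <- is.na(converted) & !is.na(df[[cl]]) & df[[cl]] != "NA"
      if (any(bad))
        stop(sprintf("%s table column `%s` has non-numeric entries (rows %s)",
                     what, cl, paste(which(bad), collapse = ", ")),
             call. = FALSE)
      df[[cl]] <- converted
    }
  }
  df
}

#' Read an interaction-energy dataset from CSV tables
#'
#' Reads the flat two/three-table CSV schema: a bound-state table with header
#' `compound_id,template_id,pose_id,replicate_id,v_vdw_bound,v_el_bound[,n_frames]`
#' (one row per simulation, replicates un-merged), a free-state table with
#' header `compound_id,v_vdw_free,v_el_free`, and optionally a compounds
#' table with header
#' `compound_id,ic50,dg_exp,molar_mass,net_charge,role`. The assembled
#' dataset is validated by [energy_dataset()]; schema violations (missing
#' columns, duplicated simulation keys, non-finite energies) raise errors
#' naming the offending column or rows — rows are never silently dropped.
#'
#' @param bound_path Path to the bound-state simulations CSV.
#' @param free_path Path to the free-state CSV.
#' @param compounds_path Optional path to the compounds CSV.
#' @return A validated [energy_dataset()].
#' @seealso [write_energy_dataset()]
#' @export
read_energy_dataset <- function(bound_path, free_path, compounds_path = NULL) {
  sims <- read_checked_csv(bound_path, SIM_COLS, "simulations",
                           c("v_vdw_bound", "v_el_bound", "n_frames"))
  free <- read_checked_csv(free_path, FREE_COLS, "free_states",
                           c("v_vdw_free", "v_el_free"))
  compounds <- NULL
  if (!is.null(compounds_path))
    compounds <- read_checked_csv(compounds_path, COMPOUND_COLS, "compounds",
                                  c("ic50", "dg_exp", "molar_mass",
                                    "net_charge"))
  energy_dataset(sims, free, compounds)
}

write_full_precision_csv <- function(df, path) {
  out <- df
  for (cl in names(out))
    if (is.double(out[[cl]]))
      out[[cl]] <- vapply(out[[cl]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17, trim = TRUE),
        character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
}

#' Write an interaction-energy dataset to CSV tables
#'
#' Inverse of [read_energy_dataset()]: writes the simulations, free-state and
#' (if present) compounds tables with the documented headers. Doubles are
#' written with 17 significant digits, so reading the files back reproduces
#' the dataset exactly.
#'
#' @param dataset A validated [energy_dataset()].
#' @param bound_path,free_path Output CSV paths.
#' @param compounds_path Optional output path for the compounds table;
#'   required when the dataset carries compound records and ignored
#'   otherwise.
#' @return Invisibly, the dataset.
#' @export
write_energy_dataset <- function(dataset, bound_path, free_path,
                                 compounds_path = NULL) {
  stopifnot(inherits(dataset, "energy_dataset"))
  write_full_precision_csv(dataset$simulations, bound_path)
  write_full_precision_csv(dataset$free_states, free_path)
  if (!is.null(dataset$compounds)) {
    if (is.null(compounds_path))
      stop("dataset has compound records; supply `compounds_path`",
           call. = FALSE)
    write_full_precision_csv(dataset$compounds, compounds_path)
  }
  invisible(dataset)
}
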
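# Multi-model PDB in/out for docked poses, via bio3d. PDB files are in
# angstrom; pose_set coordinates are in nm, converted at the boundary.

#' Read docked poses from a multi-model PDB file
#'
#' Reads a MODEL/ENDMDL multi-model PDB (one model per docking pose) with
#' [bio3d::read.pdb()], drops hydrogens by default (docking protonation is
#' unreliable), and converts angstrom to nm.
#'
#' @param path PDB file path.
#' @param ligand_id,template_id Identifiers for the resulting [pose_set()];
#'   `ligand_id` defaults to the file name.
#' @param heavy_only Drop hydrogen atoms (element H). Default `TRUE`.
#' @return A [pose_set()] with one pose per PDB model (nm).
#' @export
read_pose_pdb <- function(path, ligand_id = NULL, template_id = "template",
                          heavy_only = TRUE) {
  if (!file.exists(path))
    stop("PDB file does not exist: ", path, call. = FALSE)
  if (is.null(ligand_id))
    ligand_id <- sub("\\.pdb$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # n_models x 3*n_atoms, angstrom
  keep <- rep(TRUE, nrow(pdb$atom))
  if (heavy_only) {
    elesy <- pdb$atom$elesy
    guess <- toupper(substr(trimws(pdb$atom$elety), 1, 1))
    elem <- ifelse(!is.na(elesy) & nzchar(trimws(elesy)),
                   toupper(trimws(elesy)), guess)
    keep <- elem != "H"
  }
  if (!any(keep))
    stop("no heavy atoms left after hydrogen removal", call. = FALSE)
  atom_idx <- which(keep)
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    full <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    full[atom_idx, , drop = FALSE] / 10  # angstrom -> nm
  })
  ps <- pose_set(coords, ligand_id = ligand_id, template_id = template_id)
  attr(ps, "atom") <- pdb$atom[atom_idx, , drop = FALSE]
  ps
}

#' Write selected poses as single-model PDB files
#'
#' Writes every pose of a [pose_set()] to its own PDB file named
#' `<ligand>_<template>_pose<ID>.pdb` (nm converted back to angstrom).
#' When the set came from [read_pose_pdb()], the original atom records
#' (names, residues) are reused; otherwise generic carbon atoms are emitted.
#'
#' @param poses A [pose_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_pose_pdb <- function(poses, dir = ".") {
  stopifnot(inherits(poses, "pose_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atom <- attr(poses, "atom")
  paths <- character(length(poses))
  for (k in seq_along(poses$coords)) {
    xyz <- as.numeric(t(poses$coords[[k]])) * 10  # nm -> angstrom
    path <- file.path(dir, sprintf("%s_%s_pose%s.pdb", poses$ligand_id,
                                   poses$template_id, poses$pose_ids[k]))
    if (!is.null(atom)) {
      bio3d::write.pdb(file = path, xyz = xyz,
                       resno = atom$resno, resid = atom$resid,
                       eleno = atom$eleno, elety = atom$elety,
                       chain = atom$chain)
    } else {
      n <- poses$n_atoms
      bio3d::write.pdb(file = path, xyz = xyz,
                       resno = rep(1L, n), resid = rep("LIG", n),
                       eleno = seq_len(n),
                       elety = paste0("C", seq_len(n)))
    }
    paths[k] <- path
  }
  invisible(paths)
}
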
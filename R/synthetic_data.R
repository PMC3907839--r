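# Synthetic interaction-energy datasets with known ground truth (alpha*,
# beta*, per-compound true free energies and weights), so the calibration
# fixed point, permutation scanning and the applicability check can be
# validated end-to-end without any MD.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic energy-dataset generator
#'
#' Defaults mirror the structure of the packaged CYP 2D6 study: 17
#' compounds, 2 protein templates x 3 poses x 2 replicate runs (12
#' bound-state simulations per ligand before replicate merging), true
#' coefficients (0.22, 0.10), and an inter-simulation free-energy spread of
#' a few k_B T so the Boltzmann weighting is non-trivial.
#'
#' @param n_compounds Number of compounds (default 17).
#' @param n_templates,n_poses_per_template,n_replicates Simulation grid per
#'   compound (defaults 2, 3, 2).
#' @param true_alpha,true_beta Ground-truth LIE coefficients (defaults 0.22,
#'   0.10).
#' @param pose_dg_spread Standard deviation (kJ mol^-1) of the
#'   per-simulation true free energies around each compound's central value;
#'   default 7.5 kJ mol^-1, about 3 k_B T at 300 K.
#' @param replicate_noise_sigma Per-replicate noise on the bound-state
#'   averages (kJ mol^-1); default 0.5.
#' @param experimental_noise_sigma Noise added to the true free energy to
#'   form `dg_exp` (kJ mol^-1); default 2, a typical experimental
#'   uncertainty.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 17, n_templates = 2,
                             n_poses_per_template = 3, n_replicates = 2,
                             true_alpha = 0.22, true_beta = 0.10,
                             pose_dg_spread = 7.5,
                             replicate_noise_sigma = 0.5,
                             experimental_noise_sigma = 2,
                             seed = 1) {
  counts <- c(n_compounds, n_templates, n_poses_per_template, n_replicates)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1", call. = FALSE)
  if (pose_dg_spread < 0 || replicate_noise_sigma < 0 ||
      experimental_noise_sigma < 0)
    stop("spread and noise sigmas must be >= 0", call. = FALSE)
  stopifnot(is.finite(true_alpha), is.finite(true_beta))
  structure(list(n_compounds = n_compounds, n_templates = n_templates,
                 n_poses_per_template = n_poses_per_template,
                 n_replicates = n_replicates,
                 true_alpha = true_alpha, true_beta = true_beta,
                 pose_dg_spread = pose_dg_spread,
                 replicate_noise_sigma = replicate_noise_sigma,
                 experimental_noise_sigma = experimental_noise_sigma,
                 seed = seed),
            class = "generator_config")
}

#' Generate a synthetic interaction-energy dataset with known truth
#'
#' Draws, for every compound, a compound-level pair of bound-minus-free
#' energy differences (van der Waals around -100 +/- 20, electrostatic
#' around -30 +/- 15 kJ mol^-1) and per-simulation deviations scaled so the
#' per-simulation free energies at the true coefficients spread by
#' `pose_dg_spread`. True weights and the true combined free energy follow
#' the exact Boltzmann-weighted expression at (`true_alpha`, `true_beta`).
#' Free-state averages are drawn per compound and added back so the dataset
#' carries bound/free state averages just like real MD output; replicate
#' rows are the bound averages plus independent replicate noise; `dg_exp`
#' is the true free energy plus experimental noise. With both noise sigmas
#' zero, calibration recovers the true coefficients and free energies to
#' solver tolerance.
#'
#' Roles: the first `ceiling(n/2)` compounds are `"train"`, the rest
#' `"test"`, matching the 9/8 split of a 17-compound set.
#'
#' @param config A [generator_config()].
#' @param thermo A [thermo_context()]; its weighting temperature defines the
#'   true weights.
#' @return List with `dataset` (an [energy_dataset()]) and `truth` (list:
#'   `config`, `compounds` data frame with `compound_id`, `dg_true`, and
#'   `weights`, a named list of per-compound data frames with the true
#'   per-simulation free energies and weights).
#' @export
generate_energy_dataset <- function(config = generator_config(),
                                    thermo = thermo_context()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(thermo, "thermo_context"))
  with_seed(config$seed, {
    n_sim <- config$n_templates * config$n_poses_per_template
    template_ids <- if (config$n_templates == 2) c("CHZ170", "PPD70")
                    else sprintf("T%02d", seq_len(config$n_templates))
    pose_ids <- if (config$n_poses_per_template <= 3)
      c("I", "II", "III")[seq_len(config$n_poses_per_template)]
    else sprintf("p%02d", seq_len(config$n_poses_per_template))
    ids <- sprintf("cmp%02d", seq_len(config$n_compounds))

    sim_rows <- list(); free_rows <- list(); truth_w <- list()
    dg_true <- numeric(config$n_compounds)
    for (c_i in seq_len(config$n_compounds)) {
      d_vdw0 <- stats::rnorm(1, -100, 20)
      d_el0 <- stats::rnorm(1, -30, 15)
      if (config$pose_dg_spread > 0) {
        s_u <- config$pose_dg_spread / (sqrt(2) * abs(config$true_alpha))
        s_v <- config$pose_dg_spread / (sqrt(2) * abs(config$true_beta))
        u <- stats::rnorm(n_sim, 0, s_u)
        v <- stats::rnorm(n_sim, 0, s_v)
      } else {
        u <- v <- rep(0, n_sim)
      }
      d_vdw <- d_vdw0 + u
      d_el <- d_el0 + v
      dg_i <- dg_single(config$true_alpha, config$true_beta, d_vdw, d_el)
      w <- boltzmann_weights(dg_i, thermo)
      dg_true[c_i] <- sum(w * dg_i)

      v_vdw_free <- stats::rnorm(1, -60, 8)
      v_el_free <- stats::rnorm(1, -180, 25)
      free_rows[[c_i]] <- data.frame(compound_id = ids[c_i],
                                     v_vdw_free = v_vdw_free,
                                     v_el_free = v_el_free,
                                     stringsAsFactors = FALSE)
      grid <- expand.grid(pose_id = pose_ids, template_id = template_ids,
                          stringsAsFactors = FALSE)[, c("template_id", "pose_id")]
      per_rep <- lapply(seq_len(config$n_replicates), function(r) {
        noise_vdw <- stats::rnorm(n_sim, 0, config$replicate_noise_sigma)
        noise_el <- stats::rnorm(n_sim, 0, config$replicate_noise_sigma)
        data.frame(compound_id = ids[c_i],
                   template_id = grid$template_id, pose_id = grid$pose_id,
                   replicate_id = sprintf("r%d", r),
                   v_vdw_bound = v_vdw_free + d_vdw + noise_vdw,
                   v_el_bound = v_el_free + d_el + noise_el,
                   stringsAsFactors = FALSE)
      })
      sim_rows[[c_i]] <- do.call(rbind, per_rep)
      truth_w[[ids[c_i]]] <- data.frame(template_id = grid$template_id,
                                        pose_id = grid$pose_id,
                                        dg_i = dg_i, weight = w,
                                        stringsAsFactors = FALSE)
    }
    n_train <- ceiling(config$n_compounds / 2)
    compounds <- data.frame(
      compound_id = ids, ic50 = NA_real_,
      dg_exp = dg_true + stats::rnorm(config$n_compounds, 0,
                                      config$experimental_noise_sigma),
      molar_mass = NA_real_, net_charge = NA_real_,
      role = c(rep("train", n_train),
               rep("test", config$n_compounds - n_train)),
      stringsAsFactors = FALSE)

    list(dataset = energy_dataset(do.call(rbind, sim_rows),
                                  do.call(rbind, free_rows), compounds),
         truth = list(config = config,
                      compounds = data.frame(compound_id = ids,
                                             dg_true = dg_true,
                                             stringsAsFactors = FALSE),
                      weights = truth_w))
  })
}

#' Generate a synthetic cloud of docked poses in Gaussian blobs
#'
#' Builds a pose set whose conformations fall into `n_blobs` well-separated
#' Gaussian blobs along the x axis (blob k centered at
#' `(k-1) * separation`), as a ground-truth fixture for the clustering
#' pipeline: with `separation` well above `blob_sigma`, pose selection must
#' recover exactly one central structure per blob.
#'
#' @param n_blobs Number of blobs (default 3).
#' @param poses_per_blob Poses per blob; scalar or length-`n_blobs` vector
#'   (default 50).
#' @param n_atoms Atoms per pose (default 10).
#' @param blob_sigma Per-atom coordinate jitter within a blob, nm
#'   (default 0.02).
#' @param separation Distance between adjacent blob centers, nm
#'   (default 0.5); must exceed `4 * blob_sigma` for well-separated blobs.
#' @param seed Integer seed.
#' @return List with `poses` (a [pose_set()]) and `truth` (integer blob
#'   assignment per pose).
#' @export
generate_pose_cloud <- function(n_blobs = 3, poses_per_blob = 50,
                                n_atoms = 10, blob_sigma = 0.02,
                                separation = 0.5, seed = 1) {
  stopifnot(n_blobs >= 1, all(poses_per_blob >= 1), n_atoms >= 1,
            blob_sigma >= 0, separation > 0)
  if (separation <= 4 * blob_sigma)
    stop("`separation` must exceed 4 * blob_sigma for well-separated blobs",
         call. = FALSE)
  if (length(poses_per_blob) == 1)
    poses_per_blob <- rep(poses_per_blob, n_blobs)
  stopifnot(length(poses_per_blob) == n_blobs)
  with_seed(seed, {
    base <- matrix(stats::rnorm(n_atoms * 3, 0, 0.15), ncol = 3)
    coords <- list(); truth <- integer(0)
    for (b in seq_len(n_blobs)) {
      center <- c((b - 1) * separation, 0, 0)
      for (p in seq_len(poses_per_blob[b])) {
        jitter <- matrix(stats::rnorm(n_atoms * 3, 0, blob_sigma), ncol = 3)
        coords[[length(coords) + 1]] <-
          sweep(base + jitter, 2, center, "+")
        truth <- c(truth, b)
      }
    }
    list(poses = pose_set(coords, ligand_id = "synthetic",
                          template_id = "synthetic"),
         truth = truth)
  })
}
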
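# Core iterative LIE machinery.
#
# Per simulation i of a compound:
#   dG_i = alpha * (<V_vdw>_bound,i - <V_vdw>_free)
#        + beta  * (<V_el>_bound,i  - <V_el>_free)
# Boltzmann weights over the N simulations of one compound:
#   W_i = exp(-dG_i / kT) / sum_j exp(-dG_j / kT)
# Combined free energy:
#   dG = alpha * sum_i W_i d_vdw,i + beta * sum_i W_i d_el,i
#      = sum_i W_i dG_i
# Calibration alternates a 2-parameter weighted least-squares fit of
# (alpha, beta) with weight refresh until both are self-consistent.

#' Merge replicate simulations of the same starting structure
#'
#' Replicate MD runs (same compound, template and pose, different initial
#' velocities) sample the same basin and are merged before any Boltzmann
#' weighting: the merged energies are the n_frames-weighted mean of the
#' replicate means (plain mean when frame counts are absent), so replicates
#' never count as separate Boltzmann states.
#'
#' @param simulations Simulation data frame (see [energy_dataset()]); may
#'   contain an `n_frames` column.
#' @return A simulation data frame with one row per (compound, template,
#'   pose); `replicate_id` is set to `"combined"`, `n_frames` to the summed
#'   frame count. Rows are ordered lexicographically by (compound, template,
#'   pose).
#' @export
combine_replicates <- function(simulations) {
  check_columns(simulations, SIM_COLS, "simulations")
  if (!"n_frames" %in% names(simulations))
    simulations$n_frames <- rep(NA_real_, nrow(simulations))
  if (nrow(simulations) == 0) return(simulations)
  grp <- interaction(simulations$compound_id, simulations$template_id,
                     simulations$pose_id, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(simulations, grp), function(g) {
    w <- g$n_frames
    if (anyNA(w)) w <- rep(1, nrow(g))
    data.frame(compound_id = g$compound_id[1],
               template_id = g$template_id[1],
               pose_id = g$pose_id[1],
               replicate_id = "combined",
               v_vdw_bound = sum(w * g$v_vdw_bound) / sum(w),
               v_el_bound = sum(w * g$v_el_bound) / sum(w),
               n_frames = if (anyNA(g$n_frames)) NA_real_ else sum(g$n_frames),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Bound-minus-free interaction-energy differences for one compound
#'
#' Combines replicates, then subtracts the compound's free-state averages
#' from each simulation's bound-state averages, yielding the van der Waals
#' and electrostatic differences that enter the LIE expression.
#'
#' @param dataset An [energy_dataset()].
#' @param compound_id Compound to extract.
#' @return Data frame with one row per replicate-combined simulation,
#'   ordered lexicographically by (template, pose): columns `compound_id`,
#'   `template_id`, `pose_id`, `d_vdw`, `d_el` (kJ mol^-1).
#' @export
delta_energies <- function(dataset, compound_id) {
  stopifnot(inherits(dataset, "energy_dataset"))
  free <- dataset$free_states[dataset$free_states$compound_id == compound_id, ]
  if (nrow(free) == 0)
    stop("no free-state entry for compound: ", compound_id, call. = FALSE)
  sims <- dataset$simulations[dataset$simulations$compound_id == compound_id, ]
  if (nrow(sims) == 0)
    stop("no simulations for compound: ", compound_id, call. = FALSE)
  comb <- combine_replicates(sims)
  ord <- order(comb$template_id, comb$pose_id)
  comb <- comb[ord, ]
  data.frame(compound_id = compound_id,
             template_id = comb$template_id,
             pose_id = comb$pose_id,
             d_vdw = comb$v_vdw_bound - free$v_vdw_free,
             d_el = comb$v_el_bound - free$v_el_free,
             stringsAsFactors = FALSE)
}

#' Single-simulation LIE free energy
#'
#' \eqn{\Delta G_{calc,i} = \alpha\, \Delta V^{vdW}_i + \beta\, \Delta V^{el}_i}.
#'
#' @param alpha,beta Dimensionless LIE coefficients.
#' @param d_vdw,d_el Bound-minus-free van der Waals and electrostatic
#'   interaction-energy differences (kJ mol^-1). Vectorized.
#' @return Free energy (kJ mol^-1), one value per simulation.
#' @export
dg_single <- function(alpha, beta, d_vdw, d_el) {
  stopifnot(is.finite(alpha), is.finite(beta))
  alpha * d_vdw + beta * d_el
}

#' Boltzmann weights over per-simulation free energies
#'
#' \eqn{W_i = e^{-\Delta G_i/k_B T} / \sum_j e^{-\Delta G_j/k_B T}},
#' computed in shifted log space (the minimum \eqn{\Delta G_i} is subtracted
#' before exponentiation) so arbitrarily large energy gaps neither overflow
#' nor underflow to an all-zero vector.
#'
#' @param dg_per_sim Non-empty numeric vector of per-simulation free
#'   energies (kJ mol^-1).
#' @param thermo A [thermo_context()]; its `temperature_weighting` is used.
#' @return Numeric weight vector of the same length: non-negative, summing
#'   to 1.
#' @examples
#' thermo <- thermo_context()
#' boltzmann_weights(c(0, 0), thermo)                      # 0.5 0.5
#' boltzmann_weights(c(0, thermo$k_B * 300 * log(3)), thermo)  # 0.75 0.25
#' @export
boltzmann_weights <- function(dg_per_sim, thermo = thermo_context()) {
  stopifnot(inherits(thermo, "thermo_context"))
  if (length(dg_per_sim) == 0)
    stop("`dg_per_sim` must be non-empty", call. = FALSE)
  if (any(!is.finite(dg_per_sim)))
    stop("`dg_per_sim` must be finite", call. = FALSE)
  kt <- thermo$k_B * thermo$temperature_weighting
  e <- exp(-(dg_per_sim - min(dg_per_sim)) / kt)
  e / sum(e)
}

#' Boltzmann-weighted combined LIE free energy for one compound
#'
#' Evaluates the full multi-simulation estimate: per-simulation free
#' energies via [dg_single()], weights via [boltzmann_weights()], and the
#' combination
#' \deqn{\Delta G_{calc} = \alpha \sum_i W_i \Delta V^{vdW}_i +
#'       \beta \sum_i W_i \Delta V^{el}_i = \sum_i W_i \Delta G_{calc,i}.}
#' With a single simulation this reduces exactly to [dg_single()].
#'
#' @param alpha,beta Dimensionless LIE coefficients.
#' @param deltas Data frame from [delta_energies()] (single compound).
#' @param thermo A [thermo_context()].
#' @return An object of class `lie_prediction`: list with `compound_id`,
#'   `dg_calc` (kJ mol^-1), `n_simulations`, and `weights` — a data frame
#'   with `template_id`, `pose_id`, `dg_i`, `weight`.
#' @export
dg_combined <- function(alpha, beta, deltas, thermo = thermo_context()) {
  if (nrow(deltas) == 0)
    stop("`deltas` must be non-empty", call. = FALSE)
  if (length(unique(deltas$compound_id)) != 1)
    stop("`deltas` mixes compound ids: ",
         paste(unique(deltas$compound_id), collapse = ", "), call. = FALSE)
  dg_i <- dg_single(alpha, beta, deltas$d_vdw, deltas$d_el)
  w <- boltzmann_weights(dg_i, thermo)
  structure(
    list(compound_id = deltas$compound_id[1],
         dg_calc = alpha * sum(w * deltas$d_vdw) + beta * sum(w * deltas$d_el),
         n_simulations = nrow(deltas),
         weights = data.frame(template_id = deltas$template_id,
                              pose_id = deltas$pose_id,
                              dg_i = dg_i, weight = w,
                              stringsAsFactors = FALSE)),
    class = "lie_prediction"
  )
}

#' @export
print.lie_prediction <- function(x, ...) {
  cat(sprintf("<lie_prediction> %s: dG_calc = %.2f kJ/mol over %d simulation(s)\n",
              x$compound_id, x$dg_calc, x$n_simulations))
  invisible(x)
}

fit_alpha_beta <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < 2)
    stop(paste("degenerate calibration design: the electrostatic differences",
               "are collinear with the van der Waals differences across the",
               "training compounds, so alpha and beta cannot be separated"),
         call. = FALSE)
  qr.coef(qrx, y)
}

#' Calibrate an iterative LIE model
#'
#' Self-consistent training of the coefficients \eqn{(\alpha, \beta)} and the
#' per-simulation Boltzmann weights on compounds with known experimental
#' free energies. Starting from uniform weights, the procedure alternates:
#' (a) an ordinary least-squares fit of \eqn{(\alpha, \beta)} minimizing
#' \eqn{\sum_c (\Delta G_{calc,c} - \Delta G_{exp,c})^2} with the weights
#' held fixed — a strictly 2-parameter linear problem in the weighted sums
#' (no intercept); and (b) recomputation of every compound's weights at the
#' new coefficients. Iteration stops when the largest absolute change in any
#' weight and in both coefficients falls below `tol`, or after
#' `max_iterations` sweeps (then `converged = FALSE`; the result is returned,
#' not discarded). An optional damping factor mixes old and new weights to
#' tame oscillating fixed points.
#'
#' @param dataset An [energy_dataset()] whose `compounds` table carries
#'   `dg_exp` for the training compounds.
#' @param thermo A [thermo_context()].
#' @param training_ids Compound ids to train on. Default: all compounds with
#'   `role == "train"`, or all compounds with non-missing `dg_exp` when no
#'   roles are set.
#' @param tol Convergence tolerance on weights and coefficients
#'   (default 1e-8).
#' @param max_iterations Iteration cap (default 1000).
#' @param damping Weight-update mixing factor in (0, 1]; 1 (default) takes
#'   each new weight vector outright.
#'
#' @return An object of class `lie_model`: `alpha`, `beta`, `thermo`,
#'   `training_compound_ids`, `converged`, `n_iterations`, `tol`,
#'   `final_weights` (named list of per-compound weight data frames),
#'   `dg_calc_train`, `rmse_train`.
#' @seealso [lie_predict()], [permutation_scan()]
#' @export
lie_calibrate <- function(dataset, thermo = thermo_context(),
                          training_ids = NULL, tol = 1e-8,
                          max_iterations = 1000, damping = 1) {
  stopifnot(inherits(dataset, "energy_dataset"),
            inherits(thermo, "thermo_context"),
            damping > 0, damping <= 1)
  cmp <- dataset$compounds
  if (is.null(cmp))
    stop("dataset has no compounds table; experimental dg_exp is required",
         call. = FALSE)
  if (is.null(training_ids)) {
    training_ids <- if (any(cmp$role == "train"))
      cmp$compound_id[cmp$role == "train"]
    else cmp$compound_id[!is.na(cmp$dg_exp)]
  }
  training_ids <- sort(training_ids)
  if (length(training_ids) < 2)
    stop("calibration needs at least 2 training compounds with dg_exp",
         call. = FALSE)
  dg_exp <- cmp$dg_exp[match(training_ids, cmp$compound_id)]
  if (anyNA(dg_exp))
    stop("training compound(s) without dg_exp: ",
         paste(training_ids[is.na(dg_exp)], collapse = ", "), call. = FALSE)

  deltas <- lapply(training_ids, function(id) delta_energies(dataset, id))
  names(deltas) <- training_ids
  weights <- lapply(deltas, function(d) rep(1 / nrow(d), nrow(d)))

  alpha <- beta <- NA_real_
  converged <- FALSE
  iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    X <- t(vapply(seq_along(deltas), function(k) {
      d <- deltas[[k]]; w <- weights[[k]]
      c(sum(w * d$d_vdw), sum(w * d$d_el))
    }, numeric(2)))
    ab <- fit_alpha_beta(X, dg_exp)
    new_weights <- lapply(deltas, function(d)
      boltzmann_weights(dg_single(ab[1], ab[2], d$d_vdw, d$d_el), thermo))
    if (damping < 1) {
      new_weights <- Map(function(w_old, w_new) {
        w <- damping * w_new + (1 - damping) * w_old
        w / sum(w)
      }, weights, new_weights)
    }
    d_w <- max(vapply(seq_along(weights), function(k)
      max(abs(new_weights[[k]] - weights[[k]])), numeric(1)))
    d_ab <- if (is.na(alpha)) Inf else max(abs(ab[1] - alpha), abs(ab[2] - beta))
    alpha <- unname(ab[1]); beta <- unname(ab[2])
    weights <- new_weights
    if (d_w < tol && d_ab < tol) {
      converged <- TRUE
      break
    }
  }
  if (alpha < 0 || beta < 0)
    warning(sprintf("calibrated coefficient(s) negative: alpha = %.4g, beta = %.4g",
                    alpha, beta), call. = FALSE)

  final_weights <- Map(function(d, w) {
    data.frame(template_id = d$template_id, pose_id = d$pose_id,
               dg_i = dg_single(alpha, beta, d$d_vdw, d$d_el),
               weight = w, stringsAsFactors = FALSE)
  }, deltas, weights)
  dg_calc <- vapply(seq_along(deltas), function(k) {
    d <- deltas[[k]]; w <- weights[[k]]
    alpha * sum(w * d$d_vdw) + beta * sum(w * d$d_el)
  }, numeric(1))
  names(dg_calc) <- training_ids

  structure(
    list(alpha = alpha, beta = beta, thermo = thermo,
         training_compound_ids = training_ids,
         converged = converged, n_iterations = iter, tol = tol,
         final_weights = final_weights,
         dg_calc_train = dg_calc,
         rmse_train = rmse(dg_calc, dg_exp)),
    class = "lie_model"
  )
}

#' @export
print.lie_model <- function(x, ...) {
  cat(sprintf("<lie_model> alpha = %.4f, beta = %.4f (%s after %d iteration(s))\n",
              x$alpha, x$beta,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations),
      sprintf("  %d training compounds, RMSE %.2f kJ/mol\n",
              length(x$training_compound_ids), x$rmse_train), sep = "")
  invisible(x)
}

#' Predict a binding free energy with a calibrated model
#'
#' Non-iterative application of a calibrated model to a compound: one LIE
#' free energy per replicate-combined simulation, Boltzmann weights, and the
#' weighted combination, all at the model's fixed \eqn{(\alpha, \beta)}.
#'
#' @param model A [lie_calibrate()] result (class `lie_model`).
#' @param dataset An [energy_dataset()] containing the compound's
#'   simulations and free state.
#' @param compound_id Compound to predict.
#' @return A `lie_prediction` (see [dg_combined()]).
#' @export
lie_predict <- function(model, dataset, compound_id) {
  stopifnot(inherits(model, "lie_model"))
  dg_combined(model$alpha, model$beta,
              delta_energies(dataset, compound_id), model$thermo)
}

#' Root-mean-square error between calculated and reference free energies
#'
#' \eqn{\sqrt{\mathrm{mean}((\Delta G_{calc} - \Delta G_{exp})^2)}}. The same
#' quadratic form serves as the training-set RMSE and, applied to the test
#' set, as the standard deviation of prediction errors (SDEP); [sdep()] is
#' an alias making that intent explicit in calling code. No mean-bias
#' subtraction and no n-1 correction are applied.
#'
#' @param calculated,reference Non-empty numeric vectors of equal length
#'   (kJ mol^-1).
#' @return RMSE in kJ mol^-1.
#' @export
rmse <- function(calculated, reference) {
  if (length(calculated) == 0)
    stop("cannot compute an error over an empty set", call. = FALSE)
  if (length(calculated) != length(reference))
    stop("`calculated` and `reference` lengths differ", call. = FALSE)
  sqrt(mean((calculated - reference)^2))
}

#' @rdname rmse
#' @export
sdep <- rmse

#' Serialize / restore a calibrated LIE model as JSON
#'
#' Writes alpha, beta, the thermodynamic context, convergence record and
#' per-compound final weights to a human-readable JSON file, and reads such
#' a file back into a `lie_model`.
#'
#' @param model A `lie_model`.
#' @param path JSON file path.
#' @return `write_lie_model()` returns the model invisibly;
#'   `read_lie_model()` returns a `lie_model`.
#' @export
write_lie_model <- function(model, path) {
  stopifnot(inherits(model, "lie_model"))
  obj <- list(
    alpha = model$alpha, beta = model$beta,
    temperature_weighting = model$thermo$temperature_weighting,
    temperature_assay = model$thermo$temperature_assay,
    training_compound_ids = model$training_compound_ids,
    converged = model$converged, n_iterations = model$n_iterations,
    tol = model$tol,
    rmse_train = model$rmse_train,
    dg_calc_train = as.list(model$dg_calc_train),
    final_weights = model$final_weights
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(model)
}

#' @rdname write_lie_model
#' @export
read_lie_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha = obj$alpha, beta = obj$beta,
         thermo = thermo_context(obj$temperature_weighting,
                                 obj$temperature_assay),
         training_compound_ids = obj$training_compound_ids,
         converged = obj$converged, n_iterations = obj$n_iterations,
         tol = obj$tol,
         final_weights = lapply(obj$final_weights, as.data.frame),
         dg_calc_train = unlist(obj$dg_calc_train),
         rmse_train = obj$rmse_train),
    class = "lie_model"
  )
}
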
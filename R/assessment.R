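# Model assessment: exhaustive train/test split scanning, per-template
# Boltzmann-weight decomposition, and a principal-axes applicability check
# in the (alpha * dV_vdw, beta * dV_el) plane.

#' Enumerate all train/test partitions of a fixed training size
#'
#' Deterministically lists every way to split a compound set into a training
#' set of `train_size` and a test set of the remainder, in lexicographic
#' order of the (sorted) training-set member indices. With 17 compounds and
#' a training size of 9 this yields choose(17, 9) = 24310 partitions.
#'
#' @param compound_ids Character vector of distinct compound ids.
#' @param train_size Training-set size, strictly between 0 and
#'   `length(compound_ids)`.
#' @return A list of `choose(n, train_size)` elements, each a list with
#'   character vectors `train` and `test`.
#' @export
enumerate_splits <- function(compound_ids, train_size) {
  compound_ids <- as.character(compound_ids)
  if (anyDuplicated(compound_ids))
    stop("`compound_ids` must be distinct", call. = FALSE)
  n <- length(compound_ids)
  if (!is.numeric(train_size) || length(train_size) != 1 ||
      train_size != round(train_size) || train_size <= 0 || train_size >= n)
    stop("`train_size` must be an integer strictly between 0 and ",
         n, call. = FALSE)
  ids <- sort(compound_ids)
  idx <- utils::combn(n, train_size)
  lapply(seq_len(ncol(idx)), function(j) {
    tr <- idx[, j]
    list(train = ids[tr], test = ids[-tr])
  })
}

#' Exhaustive train/test permutation scan
#'
#' Recalibrates the LIE model on the training side of every partition from
#' [enumerate_splits()] and evaluates it on all compounds: training RMSE,
#' test SDEP, and the total RMSE over every compound (the per-split model is
#' refit from scratch each time; nothing is reused across splits).
#' Non-converged calibrations are recorded with `converged = FALSE`, never
#' dropped. Output order is deterministic, so repeated scans of the same
#' dataset are identical.
#'
#' @param dataset An [energy_dataset()] whose compounds all carry `dg_exp`.
#' @param thermo A [thermo_context()].
#' @param train_size Training-set size per split.
#' @param compound_ids Compounds to scan; default: all in the compounds
#'   table.
#' @param out Optional CSV path; when given, result rows are streamed to it
#'   as they are produced (header first), bounding memory for large scans.
#' @param ... Passed to [lie_calibrate()] (`tol`, `max_iterations`,
#'   `damping`).
#' @return Data frame with one row per split: `split_id`, `train_ids`
#'   (semicolon-separated), `alpha`, `beta`, `rmse_train`, `sdep_test`,
#'   `rmse_tot`, `converged`; attribute `"best"` holds the row index of the
#'   minimum `rmse_tot`.
#' @export
permutation_scan <- function(dataset, thermo = thermo_context(), train_size,
                             compound_ids = NULL, out = NULL, ...) {
  stopifnot(inherits(dataset, "energy_dataset"))
  cmp <- dataset$compounds
  if (is.null(cmp))
    stop("dataset has no compounds table", call. = FALSE)
  if (is.null(compound_ids)) compound_ids <- cmp$compound_id
  dg_exp <- cmp$dg_exp[match(compound_ids, cmp$compound_id)]
  if (anyNA(dg_exp))
    stop("all scanned compounds need dg_exp; missing for: ",
         paste(compound_ids[is.na(dg_exp)], collapse = ", "), call. = FALSE)
  names(dg_exp) <- compound_ids

  splits <- enumerate_splits(compound_ids, train_size)
  con <- NULL
  if (!is.null(out)) {
    con <- file(out, open = "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    writeLines(paste("split_id", "train_ids", "alpha", "beta", "rmse_train",
                     "sdep_test", "rmse_tot", "converged", sep = ","), con)
  }

  rows <- vector("list", length(splits))
  for (j in seq_along(splits)) {
    sp <- splits[[j]]
    model <- lie_calibrate(dataset, thermo, training_ids = sp$train, ...)
    dg_calc <- vapply(compound_ids, function(id)
      lie_predict(model, dataset, id)$dg_calc, numeric(1))
    row <- data.frame(
      split_id = j,
      train_ids = paste(sp$train, collapse = ";"),
      alpha = model$alpha, beta = model$beta,
      rmse_train = rmse(dg_calc[sp$train], dg_exp[sp$train]),
      sdep_test = sdep(dg_calc[sp$test], dg_exp[sp$test]),
      rmse_tot = rmse(dg_calc, dg_exp),
      converged = model$converged,
      stringsAsFactors = FALSE)
    rows[[j]] <- row
    if (!is.null(con))
      writeLines(paste(row$split_id, row$train_ids,
                       format(row$alpha, digits = 17),
                       format(row$beta, digits = 17),
                       format(row$rmse_train, digits = 17),
                       format(row$sdep_test, digits = 17),
                       format(row$rmse_tot, digits = 17),
                       row$converged, sep = ","), con)
  }
  res <- do.call(rbind, rows)
  attr(res, "best") <- which.min(res$rmse_tot)
  res
}

#' Per-template sums of Boltzmann weights
#'
#' Decomposes each compound's Boltzmann weights by protein template,
#' answering which template's simulations dominate the combined free energy.
#' Per compound the template sums add to 1.
#'
#' @param model A `lie_model`.
#' @param dataset An [energy_dataset()].
#' @param compound_ids Compounds to decompose; default: every simulated
#'   compound.
#' @return Data frame with columns `compound_id`, `template_id`, `weight`
#'   (summed over the template's poses).
#' @export
weight_decomposition <- function(model, dataset, compound_ids = NULL) {
  stopifnot(inherits(model, "lie_model"), inherits(dataset, "energy_dataset"))
  if (is.null(compound_ids))
    compound_ids <- sort(unique(dataset$simulations$compound_id))
  pieces <- lapply(compound_ids, function(id) {
    w <- lie_predict(model, dataset, id)$weights
    agg <- tapply(w$weight, w$template_id, sum)
    data.frame(compound_id = id, template_id = names(agg),
               weight = as.numeric(agg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

weighted_coordinates <- function(model, dataset, ids) {
  coords <- t(vapply(ids, function(id) {
    d <- delta_energies(dataset, id)
    w <- boltzmann_weights(
      dg_single(model$alpha, model$beta, d$d_vdw, d$d_el), model$thermo)
    c(model$alpha * sum(w * d$d_vdw), model$beta * sum(w * d$d_el))
  }, numeric(2)))
  colnames(coords) <- c("coord_vdw", "coord_el")
  coords
}

#' Principal-axes applicability-domain check
#'
#' Locates compounds in the 2-D plane of weighted, coefficient-scaled
#' interaction-energy differences
#' \eqn{(\alpha \sum_i W_i \Delta V^{vdW}_i,\; \beta \sum_i W_i \Delta V^{el}_i)}.
#' The training compounds define a centroid and a 2x2 covariance whose
#' eigenvectors are the model's principal axes. Each query compound's
#' displacement from the centroid is projected onto the axes and divided by
#' the training spread along that axis; a compound is flagged as outside the
#' applicability domain when any standardized score exceeds
#' `threshold_multiplier`. This uses simulation outcomes only — no
#' experimental affinity of the query enters.
#'
#' @param model A `lie_model`.
#' @param dataset An [energy_dataset()] with simulations for the training
#'   and query compounds.
#' @param query_ids Compounds to score; default: all simulated compounds not
#'   in the training set.
#' @param threshold_multiplier Flagging threshold on the per-axis score
#'   (default 2).
#' @param spread Per-axis scale: `"sd"` (default) divides by the standard
#'   deviation along each principal axis (the per-axis Mahalanobis form),
#'   `"variance"` divides by the variance. The flag criterion of "more than
#'   twice the spread along at least one principal axis" is dimensionally
#'   ambiguous in the field; both readings are provided.
#' @return Data frame with one row per query: `compound_id`, `coord_vdw`,
#'   `coord_el` (kJ mol^-1), `pa_score_1`, `pa_score_2` (standardized
#'   displacements along the first/second principal axis), `flagged`.
#' @export
applicability_check <- function(model, dataset, query_ids = NULL,
                                threshold_multiplier = 2,
                                spread = c("sd", "variance")) {
  stopifnot(inherits(model, "lie_model"), inherits(dataset, "energy_dataset"))
  spread <- match.arg(spread)
  train_ids <- model$training_compound_ids
  if (length(train_ids) < 3)
    stop("applicability check needs >= 3 training compounds for a",
         " non-degenerate covariance", call. = FALSE)
  if (is.null(query_ids))
    query_ids <- setdiff(sort(unique(dataset$simulations$compound_id)),
                         train_ids)
  train_xy <- weighted_coordinates(model, dataset, train_ids)
  centroid <- colMeans(train_xy)
  covm <- stats::cov(train_xy)
  eig <- eigen(covm, symmetric = TRUE)
  if (min(eig$values) <= max(eig$values) * 1e-12 || max(eig$values) == 0)
    stop("training covariance is singular along a principal axis; ",
         "add more (or more diverse) training compounds", call. = FALSE)
  scale_k <- if (spread == "sd") sqrt(eig$values) else eig$values

  query_xy <- weighted_coordinates(model, dataset, query_ids)
  proj <- sweep(query_xy, 2, centroid) %*% eig$vectors
  scores <- abs(sweep(proj, 2, scale_k, "/"))
  data.frame(compound_id = query_ids,
             coord_vdw = query_xy[, 1], coord_el = query_xy[, 2],
             pa_score_1 = scores[, 1], pa_score_2 = scores[, 2],
             flagged = scores[, 1] > threshold_multiplier |
                       scores[, 2] > threshold_multiplier,
             stringsAsFactors = FALSE, row.names = NULL)
}
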
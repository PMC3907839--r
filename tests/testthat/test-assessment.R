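test_that("split enumeration is exhaustive, disjoint and lexicographic", {
  s <- enumerate_splits(c("a", "b", "c"), 1)
  expect_length(s, 3)
  expect_equal(s[[1]]$train, "a")
  expect_equal(s[[1]]$test, c("b", "c"))

  for (n in 4:8) {
    ids <- sprintf("c%02d", seq_len(n))
    for (k in seq_len(n - 1)) {
      s <- enumerate_splits(ids, k)
      expect_length(s, choose(n, k))
      keys <- vapply(s, function(x) paste(x$train, collapse = ","),
                     character(1))
      expect_false(anyDuplicated(keys) > 0)
      for (x in s) {
        expect_length(intersect(x$train, x$test), 0)
        expect_setequal(c(x$train, x$test), ids)
      }
    }
  }
  expect_error(enumerate_splits(c("a", "b"), 2), "train_size")
  expect_error(enumerate_splits(c("a", "b"), 0), "train_size")
})

test_that("permutation scan covers every split and the argmin is global", {
  g <- generate_energy_dataset(generator_config(
    n_compounds = 6, experimental_noise_sigma = 1, seed = 17))
  sc <- suppressWarnings(permutation_scan(g$dataset, train_size = 3))
  expect_equal(nrow(sc), choose(6, 3))
  best <- attr(sc, "best")
  expect_true(all(sc$rmse_tot >= sc$rmse_tot[best]))
  # the best exhaustive split is at least as good as any user-chosen split
  expect_lte(sc$rmse_tot[best], sc$rmse_tot[1])

  # quadratic-form consistency: n_tot * rmse_tot^2 decomposes exactly
  expect_equal(6 * sc$rmse_tot^2, 3 * sc$rmse_train^2 + 3 * sc$sdep_test^2)
})

test_that("scanning twice gives identical tables, streamed and in-memory", {
  g <- generate_energy_dataset(generator_config(n_compounds = 5, seed = 23))
  path <- withr::local_tempfile(fileext = ".csv")
  sc1 <- suppressWarnings(permutation_scan(g$dataset, train_size = 2,
                                           out = path))
  sc2 <- suppressWarnings(permutation_scan(g$dataset, train_size = 2))
  expect_identical(sc1$rmse_tot, sc2$rmse_tot)
  expect_identical(sc1$alpha, sc2$alpha)
  streamed <- utils::read.csv(path)
  expect_equal(nrow(streamed), nrow(sc1))
  expect_equal(streamed$rmse_tot, sc1$rmse_tot, tolerance = 1e-12)
})

test_that("per-template weight sums form a unit partition per compound", {
  g <- generate_energy_dataset(generator_config(n_compounds = 5, seed = 31))
  m <- suppressWarnings(lie_calibrate(g$dataset))
  dec <- weight_decomposition(m, g$dataset)
  sums <- tapply(dec$weight, dec$compound_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # brute-force cross-check against per-simulation weights
  p <- lie_predict(m, g$dataset, "cmp02")
  ref <- tapply(p$weights$weight, p$weights$template_id, sum)
  got <- dec[dec$compound_id == "cmp02", ]
  expect_equal(got$weight, as.numeric(ref[got$template_id]))
})

test_that("weight decomposition handles one-template and symmetric cases", {
  sims <- data.frame(compound_id = "c1", template_id = "CHZ170",
                     pose_id = c("I", "II"), replicate_id = "r1",
                     v_vdw_bound = c(-100, -90), v_el_bound = c(-40, -50))
  free <- data.frame(compound_id = "c1", v_vdw_free = -20, v_el_free = -35)
  d1 <- energy_dataset(sims, free)
  model <- structure(list(alpha = 0.22, beta = 0.10,
                          thermo = thermo_context(),
                          training_compound_ids = "c1"),
                     class = "lie_model")
  dec <- weight_decomposition(model, d1)
  expect_equal(dec$weight, 1.0)

  # two templates, all per-simulation free energies equal -> 0.5 / 0.5
  sims2 <- rbind(sims, transform(sims, template_id = "PPD70"))
  d2 <- energy_dataset(sims2, free)
  dec2 <- weight_decomposition(model, d2)
  expect_equal(sort(dec2$template_id), c("CHZ170", "PPD70"))
  expect_equal(dec2$weight, c(0.5, 0.5))
})

# Build a dataset in which every compound has exactly one simulation, so its
# applicability-plane coordinates are directly (alpha*d_vdw, beta*d_el).
coords_dataset <- function(xy, alpha, beta) {
  ids <- sprintf("q%02d", seq_len(nrow(xy)))
  free <- data.frame(compound_id = ids, v_vdw_free = 0, v_el_free = 0)
  sims <- data.frame(compound_id = ids, template_id = "T", pose_id = "I",
                     replicate_id = "r1",
                     v_vdw_bound = xy[, 1] / alpha,
                     v_el_bound = xy[, 2] / beta,
                     stringsAsFactors = FALSE)
  energy_dataset(sims, free)
}

forged_model <- function(train_ids, alpha = 0.22, beta = 0.10) {
  structure(list(alpha = alpha, beta = beta, thermo = thermo_context(),
                 training_compound_ids = train_ids),
            class = "lie_model")
}

test_that("applicability scores match an independent Mahalanobis computation", {
  set.seed(41)
  train_xy <- cbind(rnorm(10, -25, 4), rnorm(10, -5, 2))
  query_xy <- cbind(rnorm(4, -25, 8), rnorm(4, -5, 4))
  d <- coords_dataset(rbind(train_xy, query_xy), 0.22, 0.10)
  ids <- sprintf("q%02d", 1:14)
  model <- forged_model(ids[1:10])
  rep <- applicability_check(model, d, query_ids = ids[11:14])
  # sum of squared per-axis scores is the squared Mahalanobis distance
  md2 <- stats::mahalanobis(query_xy, colMeans(train_xy),
                            stats::cov(train_xy))
  expect_equal(rep$pa_score_1^2 + rep$pa_score_2^2, unname(md2),
               tolerance = 1e-10)
})

test_that("applicability flags follow the per-axis threshold", {
  # 8 points on an ellipse aligned with the axes: sample sd exactly 2 along
  # x and 1 along y (radius sqrt(7) gives per-axis variance 7 * 4 / 7 = 4),
  # so the principal axes are the coordinate axes with spreads (2, 1)
  angles <- seq(0, 2 * pi, length.out = 9)[-9]
  train_xy <- sqrt(7) * cbind(cos(angles), 0.5 * sin(angles)) - 20
  centroid <- colMeans(train_xy)
  queries <- rbind(centroid,                  # at the centroid: scores 0
                   centroid + c(5, 0))        # 2.5 sd out along one axis
  d <- coords_dataset(rbind(train_xy, queries), 0.22, 0.10)
  ids <- sprintf("q%02d", seq_len(nrow(train_xy) + 2))
  model <- forged_model(ids[seq_len(nrow(train_xy))])
  rep <- applicability_check(model, d, query_ids = utils::tail(ids, 2))
  expect_equal(c(rep$pa_score_1[1], rep$pa_score_2[1]), c(0, 0),
               tolerance = 1e-10)
  expect_equal(max(rep$pa_score_1[2], rep$pa_score_2[2]), 2.5,
               tolerance = 1e-8)
  expect_false(rep$flagged[1])
  expect_true(rep$flagged[2])
  # variance reading: displacement 5 over variance 4
  rep_var <- applicability_check(model, d, query_ids = utils::tail(ids, 2),
                                 spread = "variance")
  expect_equal(max(rep_var$pa_score_1[2], rep_var$pa_score_2[2]), 1.25,
               tolerance = 1e-8)
})

test_that("applicability flags are invariant under rigid rotation", {
  set.seed(43)
  train_xy <- cbind(rnorm(8, -25, 5), rnorm(8, -6, 1.5))
  query_xy <- cbind(rnorm(5, -25, 10), rnorm(5, -6, 4))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ids <- sprintf("q%02d", 1:13)
  d1 <- coords_dataset(rbind(train_xy, query_xy), 0.22, 0.10)
  d2 <- coords_dataset(rbind(train_xy %*% R, query_xy %*% R), 0.22, 0.10)
  m <- forged_model(ids[1:8])
  r1 <- applicability_check(m, d1, query_ids = ids[9:13])
  r2 <- applicability_check(m, d2, query_ids = ids[9:13])
  expect_equal(r1$flagged, r2$flagged)
  expect_equal(r1$pa_score_1^2 + r1$pa_score_2^2,
               r2$pa_score_1^2 + r2$pa_score_2^2, tolerance = 1e-8)
})

test_that("degenerate applicability setups fail loudly", {
  train_xy <- cbind(c(-20, -21, -22, -23), c(-5, -5, -5, -5))  # zero spread
  d <- coords_dataset(train_xy, 0.22, 0.10)
  ids <- sprintf("q%02d", 1:4)
  expect_error(applicability_check(forged_model(ids), d, query_ids = ids[1]),
               "singular")
  expect_error(applicability_check(forged_model(ids[1:2]), d,
                                   query_ids = ids[3]),
               ">= 3 training")
})
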
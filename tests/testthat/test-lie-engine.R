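thermo <- thermo_context()
kT <- KB_KJ_PER_MOL_K * 300

test_that("replicate runs merge into one simulation by (frame-weighted) mean", {
  base <- data.frame(compound_id = "c1", template_id = "T", pose_id = "I",
                     replicate_id = c("r1", "r2"),
                     v_vdw_bound = c(-100, -102), v_el_bound = c(-40, -44))
  out <- combine_replicates(base)
  expect_equal(nrow(out), 1)
  expect_equal(out$v_vdw_bound, -101)
  expect_equal(out$v_el_bound, -42)
  expect_equal(out$replicate_id, "combined")

  weighted <- base
  weighted$n_frames <- c(1000, 3000)
  expect_equal(combine_replicates(weighted)$v_vdw_bound, -101.5)

  single <- base[1, ]
  out1 <- combine_replicates(single)
  expect_equal(out1$v_vdw_bound, -100)
  expect_equal(nrow(out1), 1)
})

test_that("delta energies are exact bound-minus-free differences", {
  sims <- data.frame(compound_id = "c1", template_id = "T", pose_id = "I",
                     replicate_id = "r1", v_vdw_bound = -120, v_el_bound = -60)
  free <- data.frame(compound_id = "c1", v_vdw_free = -30, v_el_free = -50)
  d <- delta_energies(energy_dataset(sims, free), "c1")
  expect_equal(d$d_vdw, -90)
  expect_equal(d$d_el, -10)

  same <- sims; same$v_vdw_bound <- -30; same$v_el_bound <- -50
  d0 <- delta_energies(energy_dataset(same, free), "c1")
  expect_equal(c(d0$d_vdw, d0$d_el), c(0, 0))

  toy <- make_toy_dataset(replicates = 2)
  expect_equal(nrow(delta_energies(toy, "c1")), 4)  # replicates merged
  expect_error(delta_energies(toy, "nope"), "free-state|simulations")
})

test_that("single-simulation LIE free energy is the linear form", {
  expect_equal(dg_single(0.22, 0.10, -90, -10), -20.8)
  expect_equal(dg_single(0, 0, -90, -10), 0)
  expect_equal(dg_single(1, 0, c(-3, 7), c(99, -99)), c(-3, 7))
})

test_that("Boltzmann weights match analytic ratios and stay normalized", {
  expect_equal(boltzmann_weights(-42, thermo), 1)
  expect_equal(boltzmann_weights(c(-10, -10), thermo), c(0.5, 0.5))
  expect_equal(boltzmann_weights(c(0, kT * log(3)), thermo), c(0.75, 0.25))
  # extreme gap: must not overflow, lower-energy simulation takes all weight
  w <- boltzmann_weights(c(0, -5000), thermo)
  expect_false(any(is.nan(w)))
  expect_equal(w, c(0, 1))
  expect_error(boltzmann_weights(numeric(0), thermo), "non-empty")

  set.seed(3)
  for (k in 1:100) {
    w <- boltzmann_weights(rnorm(sample(1:8, 1), -30, 20), thermo)
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-12)
  }
})

test_that("weights become uniform as T grows and concentrate as T shrinks", {
  dg <- c(-31, -27, -39, -33)
  hot <- boltzmann_weights(dg, thermo_context(temperature_weighting = 1e9))
  expect_equal(hot, rep(0.25, 4), tolerance = 1e-6)
  cold <- boltzmann_weights(dg, thermo_context(temperature_weighting = 1e-3))
  expect_equal(cold[which.min(dg)], 1)
})

test_that("weights are invariant under a constant shift of all dG_i", {
  set.seed(4)
  for (k in 1:25) {
    dg <- rnorm(6, -30, 10)
    c0 <- rnorm(1, 0, 50)
    expect_equal(boltzmann_weights(dg, thermo),
                 boltzmann_weights(dg + c0, thermo))
  }
})

test_that("combined free energy agrees with a brute-force oracle", {
  set.seed(7)
  for (k in 1:120) {
    n <- sample(1:6, 1)
    deltas <- data.frame(compound_id = "c1",
                         template_id = sprintf("T%d", seq_len(n)),
                         pose_id = "I",
                         d_vdw = rnorm(n, -90, 25), d_el = rnorm(n, -25, 12))
    a <- runif(1, 0.05, 0.5); b <- runif(1, 0.02, 0.4)
    got <- dg_combined(a, b, deltas, thermo)
    ref <- oracle_combined(a, b, deltas$d_vdw, deltas$d_el, kT)
    expect_equal(got$dg_calc, ref$dg, tolerance = 1e-10)
    expect_equal(got$weights$weight, ref$weights, tolerance = 1e-10)
    # combination is a convex mixture of per-simulation values
    expect_gte(got$dg_calc, min(got$weights$dg_i) - 1e-12)
    expect_lte(got$dg_calc, max(got$weights$dg_i) + 1e-12)
  }
})

test_that("one simulation reduces the combination to the linear form", {
  deltas <- data.frame(compound_id = "c1", template_id = "T", pose_id = "I",
                       d_vdw = -90, d_el = -10)
  expect_equal(dg_combined(0.22, 0.10, deltas, thermo)$dg_calc,
               dg_single(0.22, 0.10, -90, -10))
  # identical simulations behave like one
  rep3 <- deltas[c(1, 1, 1), ]
  expect_equal(dg_combined(0.22, 0.10, rep3, thermo)$dg_calc,
               dg_single(0.22, 0.10, -90, -10))
  mixed <- deltas; mixed$compound_id <- "c2"
  expect_error(dg_combined(0.22, 0.10, rbind(deltas, mixed), thermo),
               "mixes compound ids")
})

test_that("calibration recovers the true coefficients from noiseless data", {
  g <- generate_energy_dataset(generator_config(
    n_compounds = 17, replicate_noise_sigma = 0,
    experimental_noise_sigma = 0, seed = 1))
  m <- lie_calibrate(g$dataset)
  expect_true(m$converged)
  expect_equal(m$alpha, 0.22, tolerance = 1e-6 / 0.22)
  expect_equal(m$beta, 0.10, tolerance = 1e-6 / 0.10)
  expect_lt(m$rmse_train, 1e-6)
  # prediction on held-out compounds is exact too
  for (id in c("cmp10", "cmp17")) {
    truth <- g$truth$compounds$dg_true[g$truth$compounds$compound_id == id]
    expect_equal(lie_predict(m, g$dataset, id)$dg_calc, truth,
                 tolerance = 1e-8)
  }
})

test_that("single-simulation calibration equals direct least squares", {
  d <- make_single_sim_dataset()
  m <- lie_calibrate(d)
  expect_true(m$converged)
  expect_lte(m$n_iterations, 2)  # weights are trivially 1, no iteration needed
  # independent closed-form solve of the 2-parameter regression
  dd <- do.call(rbind, lapply(d$compounds$compound_id,
                              function(id) delta_energies(d, id)))
  fit <- stats::lm(d$compounds$dg_exp ~ 0 + dd$d_vdw + dd$d_el)
  expect_equal(unname(m$alpha), unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(unname(m$beta), unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("duplicating every simulation does not move the fit", {
  g <- generate_energy_dataset(generator_config(n_compounds = 5, seed = 9))
  m1 <- lie_calibrate(g$dataset)
  dup <- g$dataset$simulations
  dup$replicate_id <- paste0(dup$replicate_id, "_dup")
  # duplicated poses under new pose ids: every Boltzmann state appears twice
  dup2 <- g$dataset$simulations
  dup2$pose_id <- paste0(dup2$pose_id, "b")
  d2 <- energy_dataset(rbind(g$dataset$simulations, dup2),
                       g$dataset$free_states, g$dataset$compounds)
  m2 <- lie_calibrate(d2)
  expect_equal(m2$alpha, m1$alpha, tolerance = 1e-8)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-8)
})

test_that("calibration fails loudly on degenerate input", {
  d <- make_single_sim_dataset(n = 4)
  expect_error(lie_calibrate(d, training_ids = "s01"), "at least 2")
  # collinear design: d_el proportional to d_vdw for every compound
  sims <- d$simulations
  free <- d$free_states
  sims$v_el_bound <- free$v_el_free + 2 * (sims$v_vdw_bound - free$v_vdw_free)
  coll <- energy_dataset(sims, free, d$compounds)
  expect_error(lie_calibrate(coll), "collinear|degenerate")
})

test_that("re-predicting a training compound reproduces the calibration state", {
  g <- generate_energy_dataset(generator_config(n_compounds = 6, seed = 13))
  m <- lie_calibrate(g$dataset)
  for (id in m$training_compound_ids) {
    p <- lie_predict(m, g$dataset, id)
    expect_equal(p$dg_calc, unname(m$dg_calc_train[id]), tolerance = 1e-6)
    expect_equal(p$weights$weight, m$final_weights[[id]]$weight,
                 tolerance = 1e-6)
  }
  expect_error(lie_predict(m, g$dataset, "ghost"), "free-state|simulations")
})

test_that("rmse and sdep share the plain quadratic form", {
  expect_equal(rmse(c(-30, -40), c(-30, -40)), 0)
  expect_equal(rmse(c(3, -3, 3, -3), c(0, 0, 0, 0)), 3)
  set.seed(21)
  calc <- rnorm(5, -35, 5); ref <- rnorm(5, -35, 5)
  expect_equal(rmse(calc, ref), sqrt(sum((calc - ref)^2) / 5))
  expect_identical(rmse, sdep)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "lengths")
})

test_that("model JSON serialization round-trips", {
  g <- generate_energy_dataset(generator_config(n_compounds = 4, seed = 2))
  m <- lie_calibrate(g$dataset)
  path <- withr::local_tempfile(fileext = ".json")
  write_lie_model(m, path)
  back <- read_lie_model(path)
  expect_equal(back$alpha, m$alpha)
  expect_equal(back$beta, m$beta)
  expect_equal(back$training_compound_ids, m$training_compound_ids)
  expect_equal(back$final_weights[["cmp01"]]$weight,
               m$final_weights[["cmp01"]]$weight)
  p1 <- lie_predict(m, g$dataset, "cmp03")
  p2 <- lie_predict(back, g$dataset, "cmp03")
  expect_equal(p2$dg_calc, p1$dg_calc)
})
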
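# Independent oracles and small fixtures shared across test files.

# Direct transliteration of the three LIE formulas, deliberately naive
# (plain exponentials, combination as sum of W_i * dG_i) so it stays
# independent of the package's shifted-log-space / weighted-sum route.
oracle_combined <- function(alpha, beta, d_vdw, d_el, kT) {
  dg_i <- alpha * d_vdw + beta * d_el
  w <- exp(-dg_i / kT)
  w <- w / sum(w)
  list(dg = sum(w * dg_i), weights = w)
}

# Brute-force no-superposition RMSD between two coordinate matrices.
oracle_rmsd <- function(a, b) {
  sqrt(sum((a - b)^2) / nrow(a))
}

# Exhaustive central-structure search: try every member as candidate.
oracle_central <- function(members, mat) {
  members <- sort(members)
  if (length(members) == 1) return(members)
  best <- members[1]; best_val <- Inf
  for (m in members) {
    val <- mean(mat[m, setdiff(members, m)])
    if (val < best_val - 1e-15) { best <- m; best_val <- val }
  }
  best
}

# Hand-buildable dataset: 2 compounds, 2 templates x 2 poses, replicates
# optional, energies chosen so nothing is degenerate.
make_toy_dataset <- function(replicates = 1) {
  grid <- expand.grid(replicate_id = sprintf("r%d", seq_len(replicates)),
                      pose_id = c("I", "II"),
                      template_id = c("CHZ170", "PPD70"),
                      compound_id = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  set.seed(42)
  sims <- data.frame(grid[, c("compound_id", "template_id", "pose_id",
                              "replicate_id")],
                     v_vdw_bound = -100 - seq_len(n) * 3 + rnorm(n, 0, 0.1),
                     v_el_bound = -40 - seq_len(n) * 2 + rnorm(n, 0, 0.1),
                     stringsAsFactors = FALSE)
  free <- data.frame(compound_id = c("c1", "c2"),
                     v_vdw_free = c(-20, -25),
                     v_el_free = c(-35, -30))
  compounds <- data.frame(compound_id = c("c1", "c2"),
                          ic50 = c(1e-6, NA), dg_exp = c(NA, -35),
                          molar_mass = c(300, 320), net_charge = c(1, 1),
                          role = c("train", "train"),
                          stringsAsFactors = FALSE)
  energy_dataset(sims, free, compounds)
}

# Single-simulation-per-compound dataset whose calibration reduces to one
# ordinary 2-parameter least-squares problem.
make_single_sim_dataset <- function(n = 6, seed = 11) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  d_vdw <- rnorm(n, -90, 15)
  d_el <- rnorm(n, -25, 10)
  free <- data.frame(compound_id = ids, v_vdw_free = rnorm(n, -60, 5),
                     v_el_free = rnorm(n, -150, 10))
  sims <- data.frame(compound_id = ids, template_id = "T01", pose_id = "I",
                     replicate_id = "r1",
                     v_vdw_bound = free$v_vdw_free + d_vdw,
                     v_el_bound = free$v_el_free + d_el,
                     stringsAsFactors = FALSE)
  compounds <- data.frame(compound_id = ids, ic50 = NA_real_,
                          dg_exp = 0.25 * d_vdw + 0.08 * d_el + rnorm(n, 0, 1),
                          molar_mass = NA_real_, net_charge = NA_real_,
                          role = "train", stringsAsFactors = FALSE)
  energy_dataset(sims, free, compounds)
}
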
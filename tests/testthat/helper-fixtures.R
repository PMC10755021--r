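# Shared fixtures and tiny independent oracles used across test files.

# deterministic random SABRE parameter draws for property-style tests
random_params <- function(n, seed = 1303) {
  withr::with_seed(seed, data.frame(
    log_kd = runif(n, -9, -5),
    efficacy = runif(n, 0.02, 1),
    gain = 10^runif(n, -1.5, 2),
    stringsAsFactors = FALSE
  ))
}

# 7 partial-to-full agonists on one amplified pathway (alpha-adrenergic-like
# design: common gain, individual efficacies, known affinities)
seven_ligand_spec <- function(noise_sigma = 0.01, seed = 1) {
  eff <- c(1, 0.8, 0.6, 0.45, 0.3, 0.2, 0.1)
  kd <- seq(-7.6, -6.4, length.out = 7)
  ligs <- lapply(seq_len(7), function(i) list(log_kd = kd[i], efficacy = eff[i]))
  names(ligs) <- paste0("L", 1:7)
  scenario_spec(ligands = ligs, pathways = c(P1 = 11.6),
                noise_sigma = noise_sigma, seed = seed)
}

# two ligands x two pathways, efficacy shared across pathways per ligand
two_by_two_spec <- function(noise_sigma = 0, seed = 1) {
  scenario_spec(
    ligands = list(A = list(log_kd = -7.2, efficacy = 0.9),
                   B = list(log_kd = -6.8, efficacy = 0.35)),
    pathways = c(P1 = 12, P2 = 0.5),
    noise_sigma = noise_sigma, seed = seed)
}

# independent oracle: invert occupancy (law of mass action) for logL
oracle_logl_from_occupancy <- function(f_occup, log_kd) {
  log_kd + log10(f_occup / (1 - f_occup))
}

expect_panel_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$ligand, b$ligand)
  expect_equal(a$pathway, b$pathway)
  expect_equal(a$log_conc, b$log_conc, tolerance = tol)
  expect_equal(a$response, b$response, tolerance = tol)
}
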
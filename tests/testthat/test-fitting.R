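test_that("fit_hill_per_curve recovers noise-free Hill parameters to 1e-6", {
  lc <- seq(-10, -4, length.out = 9)
  panel <- data.frame(ligand = "L1", pathway = "P1", log_conc = lc,
                      response = hill_response(lc, hill_params(-7, 0.8)))
  fit <- fit_hill_per_curve(panel)
  ct <- fit$curve_table
  expect_true(ct$converged)
  expect_equal(ct$e_max, 0.8, tolerance = 1e-6)
  expect_equal(ct$log_ec50, -7, tolerance = 1e-6)
  expect_equal(fit$n_params, 2L)
  # free Hill slope recovers n as well
  panel2 <- data.frame(ligand = "L1", pathway = "P1", log_conc = lc,
                       response = hill_response(lc, hill_params(-7, 0.8, hill = 2)))
  ct2 <- fit_hill_per_curve(panel2, fix_hill_at_one = FALSE)$curve_table
  expect_equal(ct2$hill, 2, tolerance = 1e-4)
})

test_that("weak curves are flagged low-information with wide uncertainty", {
  lc <- seq(-10, -4, length.out = 9)
  y <- hill_response(lc, hill_params(-6.2, 0.06))
  panel <- data.frame(ligand = "w", pathway = "P1", log_conc = lc, response = y)
  ct <- fit_hill_per_curve(panel)$curve_table
  expect_true(ct$low_information)
})

test_that("constraint resolution counts adjustable scalars correctly", {
  spec <- two_by_two_spec(noise_sigma = 0.01)
  panel <- generate_panel(spec)
  fit <- fit_sabre_global(panel, recovery_constraints(spec, "per-ligand"),
                          multistart = 2)
  expect_equal(fit$n_params, 4L)  # 2 pathway gains + 2 shared efficacies
  expect_setequal(
    fit$estimates$label,
    c("gain[P1]", "gain[P2]", "efficacy[A]", "efficacy[B]"))
})

test_that("unidentifiable single-curve constraints raise the coupling error", {
  lc <- seq(-10, -4, length.out = 9)
  panel <- data.frame(ligand = "L1", pathway = "P1", log_conc = lc,
                      response = response_simplified(lc, -7, 0.8, 10))
  expect_error(
    fit_sabre_global(panel, sabre_constraints(
      log_kd = par_free(), efficacy = par_free(), gain = par_free())),
    "efficacy\\*gain|coupling")
})

test_that("free Kd with free gain is flagged scale-indeterminate", {
  spec <- two_by_two_spec(noise_sigma = 0.01)
  panel <- generate_panel(spec)
  expect_warning(
    fit <- fit_sabre_global(panel, sabre_constraints(
      log_kd = par_shared("per-ligand"),
      efficacy = par_shared("per-ligand"),
      gain = par_shared("per-pathway")), multistart = 2),
    "scale-indeterminate")
  expect_true(fit$scale_indeterminate)
})

test_that("gamma fixed at 1 reduces the global fit to the Clark fit", {
  lc <- seq(-10, -4, length.out = 9)
  y <- response_simplified(lc, -7, 0.62, 1) +
    withr::with_seed(5, rnorm(9, 0, 0.01))
  panel <- data.frame(ligand = "L1", pathway = "P1", log_conc = lc,
                      response = y)
  sab <- fit_sabre_global(panel, sabre_constraints(
    log_kd = par_free(), efficacy = par_free(), gain = par_fixed(1)))
  hill <- fit_hill_per_curve(panel)
  est <- setNames(sab$estimates$estimate, sab$estimates$parameter)
  expect_equal(est[["efficacy"]], hill$curve_table$e_max, tolerance = 1e-4)
  expect_equal(est[["log_kd"]], hill$curve_table$log_ec50, tolerance = 1e-4)
})

test_that("fits are equivariant under rescaling concentrations and Kd together", {
  spec <- two_by_two_spec(noise_sigma = 0.015, seed = 11)
  panel <- generate_panel(spec)
  c0 <- recovery_constraints(spec, "per-ligand")
  f0 <- fit_sabre_global(panel, c0, seed = 7)
  shift <- 1.5
  panel2 <- panel
  panel2$log_conc <- panel2$log_conc + shift
  c1 <- c0
  c1$log_kd <- par_fixed(vapply(spec$ligands, `[[`, numeric(1), "log_kd") + shift)
  f1 <- fit_sabre_global(panel2, c1, seed = 7)
  expect_equal(f0$estimates$estimate, f1$estimates$estimate, tolerance = 1e-6)
})

test_that("repeated fits from different random initializations agree", {
  spec <- two_by_two_spec(noise_sigma = 0.015, seed = 3)
  panel <- generate_panel(spec)
  cons <- recovery_constraints(spec, "per-ligand")
  fits <- lapply(c(101, 202, 303), function(s) {
    fit_sabre_global(panel, cons, multistart = 4, seed = s)$estimates$estimate
  })
  expect_equal(fits[[1]], fits[[2]], tolerance = 1e-6)
  expect_equal(fits[[1]], fits[[3]], tolerance = 1e-6)
})

test_that("AICc uses the least-squares form and guards degenerate cases", {
  mk <- function(sse, n, k) {
    sabrefit:::new_sabre_fit("sabre_global",
                             data.frame(), data.frame(), sse,
                             n_params = k, n_obs = n, converged = TRUE,
                             seed = 1, fingerprint = "x")
  }
  a <- mk(2.5, 70, 14); b <- mk(2.5, 70, 8)
  ma <- model_metrics(a); mb <- model_metrics(b)
  expect_equal(ma$aicc, 70 * log(2.5 / 70) + 28 + 2 * 14 * 15 / 55,
               tolerance = 1e-12)
  # same SSE: AICc difference is exactly the parameter-count penalty
  expect_equal(ma$aicc - mb$aicc, 2 * 6 + (2 * 14 * 15 / 55 - 2 * 8 * 9 / 61),
               tolerance = 1e-12)
  expect_error(model_metrics(mk(0, 70, 8)), "SSE is zero")
  expect_error(model_metrics(mk(1, 10, 9)), "n_obs - k - 1")
})

test_that("compare_models prefers parsimony and rejects mismatched panels", {
  spec <- seven_ligand_spec(noise_sigma = 0.01, seed = 4)
  panel <- generate_panel(spec)
  hill <- fit_hill_per_curve(panel)
  sab <- fit_sabre_global(panel, recovery_constraints(spec, "per-ligand"),
                          multistart = 4)
  expect_equal(hill$n_params, 14L)
  expect_equal(sab$n_params, 8L)
  cmp <- compare_models(hill, sab)
  expect_equal(cmp$preferred, "b")  # the generating, more parsimonious model
  expect_lt(cmp$aicc_b, cmp$aicc_a)
  # identical fit compared with itself: zero deltas
  cmp0 <- compare_models(sab, sab)
  expect_equal(cmp0$delta_aicc, 0)
  expect_equal(cmp0$delta_sse, 0)
  other <- generate_panel(two_by_two_spec(noise_sigma = 0.01))
  f_other <- fit_sabre_global(other, recovery_constraints(two_by_two_spec(),
                                                          "per-ligand"),
                              multistart = 2)
  expect_error(compare_models(sab, f_other), "different observation sets")
})

test_that("nested gamma-free beats gamma-fixed-at-1 on amplified data", {
  spec <- two_by_two_spec(noise_sigma = 0.02, seed = 21)
  panel <- generate_panel(spec)
  free <- fit_sabre_global(panel, recovery_constraints(spec, "per-ligand"),
                           multistart = 4)
  kd <- vapply(spec$ligands, `[[`, numeric(1), "log_kd")
  fixed1 <- fit_sabre_global(panel, sabre_constraints(
    log_kd = par_fixed(kd), efficacy = par_shared("per-ligand"),
    gain = par_fixed(1)), multistart = 4)
  cmp <- compare_models(fixed1, free)
  expect_equal(cmp$preferred, "b")
})
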
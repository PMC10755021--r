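test_that("response_general matches hand-evaluated closed forms and limits", {
  # full agonist at L = Kd: gamma/(gamma + 1)
  p <- sabre_params(log_kd = -6.64, efficacy = 1, gain = 30.84)
  expect_equal(response_general(-6.64, p), 30.84 / 31.84, tolerance = 1e-12)
  # zero-concentration limit with no constitutive activity
  expect_equal(response_general(-Inf, p), 0)
  # saturation limit is e_max_pred
  p2 <- sabre_params(-6.6, efficacy = 0.178, gain = 30.84)
  expect_equal(response_general(Inf, p2),
               0.178 * 30.84 / (0.178 * 30.84 - 0.178 + 1), tolerance = 1e-12)
  # basal response with constitutive activity, not auto-subtracted
  p3 <- sabre_params(-7, efficacy = 0.9, gain = 4, efficacy_r0 = 0.1)
  basal <- 0.1 * 4 / (0.1 * 4 - 0.1 + 1)
  expect_equal(response_general(-Inf, p3), basal, tolerance = 1e-12)
  expect_gt(response_general(-12, p3), 0)
  # NA rejected with a clear message
  expect_error(response_general(NA_real_, p), "NA/NaN")
})

test_that("response_simplified reproduces Clark reduction and derived midpoints", {
  # gamma = 1, epsilon = 0.5 at L = Kd: half-occupancy times e_max
  expect_equal(response_simplified(-7, -7, 0.5, 1), 0.25, tolerance = 1e-12)
  # full agonist: half-maximum at Kd/gamma (Kobs = Kd/gamma)
  expect_equal(response_simplified(-7 - log10(15), -7, 1, 15), 0.5,
               tolerance = 1e-12)
  expect_error(response_simplified(-7, -7, 0.5, -1), "gain")
  expect_error(response_simplified(-7, -7, 1.5, 2), "efficacy")
})

test_that("occupancy follows the law of mass action", {
  expect_equal(occupancy(-7, -7), 0.5, tolerance = 1e-12)
  expect_equal(occupancy(-6, -7), 10 / 11, tolerance = 1e-12)
  expect_equal(occupancy(-7, -7, hill = 2), 0.5, tolerance = 1e-12)
  expect_equal(occupancy(c(-Inf, Inf), -7), c(0, 1))
})

test_that("k_obs and e_max_pred match the closed forms", {
  expect_equal(k_obs(-7, 1, 20), -7 - log10(20), tolerance = 1e-12)
  expect_equal(k_obs(-7, 0.3, 1), -7, tolerance = 1e-12)
  # printed-parameter case: kappa = 6.31 -> log EC50 about -7.40
  expect_equal(k_obs(-6.60, 0.178, 30.84),
               -6.60 - log10(0.178 * 30.84 - 0.178 + 1), tolerance = 1e-12)
  expect_equal(round(k_obs(-6.60, 0.178, 30.84), 2), -7.40)
  expect_equal(e_max_pred(1, 7.3), 1, tolerance = 1e-12)
  expect_equal(e_max_pred(0.3, 1), 0.3, tolerance = 1e-12)
  expect_equal(e_max_pred(0.823, 0.059),
               0.823 * 0.059 / (0.823 * 0.059 - 0.823 + 1), tolerance = 1e-12)
  expect_error(k_obs(-7, 0, -1), "gain")
})

test_that("kappa is consistent between midpoint-shift and parameter forms", {
  expect_equal(kappa_from_shift(-6.62, -7.72), 10^1.10, tolerance = 1e-12)
  expect_equal(kappa_from_shift(-7, -7), 1)
  expect_equal(kappa_from_params(1, 15.51), 15.51, tolerance = 1e-12)
  expect_error(kappa_from_params(1, 1e-12), NA) # tiny but positive kappa ok
  pars <- random_params(100)
  for (i in seq_len(nrow(pars))) {
    kap_p <- kappa_from_params(pars$efficacy[i], pars$gain[i])
    kap_s <- kappa_from_shift(pars$log_kd[i],
                              k_obs(pars$log_kd[i], pars$efficacy[i], pars$gain[i]))
    expect_equal(kap_p, kap_s, tolerance = 1e-10)
  }
})

test_that("response-from-occupancy transforms agree with the two-step composition", {
  expect_equal(response_from_occupancy(0, 0.7, 5), 0)
  expect_equal(response_from_occupancy(1, 1, 5), 1, tolerance = 1e-12)
  # oracle: invert occupancy for logL, then evaluate the concentration form
  f <- 0.2
  logl <- oracle_logl_from_occupancy(f, -7)
  expect_equal(response_from_occupancy(f, 1, 30.84),
               response_simplified(logl, -7, 1, 30.84), tolerance = 1e-12)
  expect_equal(round(response_from_occupancy(0.2, 1, 30.84), 3), 0.885)
  # generic form arithmetic: e_max 1, kappa 12.59, f 0.5
  expect_equal(response_from_occupancy_generic(0.5, 1, 12.59),
               12.59 * 0.5 / (11.59 * 0.5 + 1), tolerance = 1e-12)
  expect_equal(round(response_from_occupancy_generic(0.5, 1, 12.59), 3), 0.926)
  # removable kappa -> 1 singularity: analytic linear limit
  expect_equal(response_from_occupancy_generic(0.37, 0.8, 1), 0.8 * 0.37)
  expect_equal(response_from_occupancy(0.37, 0.8, 1), 0.8 * 0.37,
               tolerance = 1e-12)
  # strongly attenuated pathway: 80% occupancy, ~15% response
  kap <- uniroot(function(k) response_from_occupancy_generic(0.8, 1, k) - 0.15,
                 c(1e-4, 0.9999999), tol = 1e-12)$root
  expect_equal(response_from_occupancy_generic(0.8, 1, kap), 0.15,
               tolerance = 1e-9)
  expect_lt(kap, 0.1)
  expect_error(response_from_occupancy(1.2, 1, 5), "f_occup")
})

test_that("hill_response and operational_response evaluate their closed forms", {
  expect_equal(hill_response(-7, hill_params(-7, 0.8)), 0.4, tolerance = 1e-12)
  expect_equal(hill_response(-6, hill_params(-7, 1, hill = 3)), 1000 / 1001,
               tolerance = 1e-12)
  expect_equal(hill_response(-7.01, hill_params(-7.01, 0.942)), 0.471,
               tolerance = 1e-12)
  # operational model: tau = 1, L = KD/2 -> 1/4; apparent e_max = tau/(tau+1)
  expect_equal(operational_response(-7 + log10(0.5), operational_params(-7, 1)),
               0.25, tolerance = 1e-12)
  expect_equal(operational_response(Inf, operational_params(-7, 3)), 0.75)
  # large tau approaches occupancy-shaped curve with tiny EC50
  op <- operational_params(-7, 1e6)
  expect_equal(operational_response(-7, op), 1, tolerance = 1e-5)
})

test_that("cheng_prusoff corrects IC50 by radioligand occupancy", {
  expect_equal(cheng_prusoff(1e-6, 0, 1e-9), log10(1e-6), tolerance = 1e-12)
  expect_equal(cheng_prusoff(1e-6, 1e-9, 1e-9), log10(5e-7), tolerance = 1e-12)
  expect_equal(cheng_prusoff(1e-6, 3e-9, 1e-9), log10(2.5e-7), tolerance = 1e-12)
  expect_error(cheng_prusoff(-1e-6, 1e-9, 1e-9), "ic50")
})

test_that("reduction chain holds to machine precision on random grids", {
  pars <- random_params(100, seed = 77)
  logl <- seq(-11, -3, length.out = 13)
  for (i in seq_len(nrow(pars))) {
    p5 <- sabre_params(pars$log_kd[i], pars$efficacy[i], pars$gain[i],
                       efficacy_r0 = 0, hill = 1)
    expect_equal(response_general(logl, p5),
                 response_simplified(logl, pars$log_kd[i], pars$efficacy[i],
                                     pars$gain[i]), tolerance = 1e-14)
    # gamma = 1 reduces to the Clark curve with e_max = efficacy, EC50 = Kd
    expect_equal(response_simplified(logl, pars$log_kd[i], pars$efficacy[i], 1),
                 hill_response(logl, hill_params(pars$log_kd[i],
                                                 pars$efficacy[i])),
                 tolerance = 1e-14)
  }
})

test_that("composition identity: response(occupancy(logL)) equals the concentration form", {
  pars <- random_params(60, seed = 99)
  logl <- seq(-10, -4, length.out = 11)
  for (i in seq_len(nrow(pars))) {
    via_occ <- response_from_occupancy(occupancy(logl, pars$log_kd[i]),
                                       pars$efficacy[i], pars$gain[i])
    direct <- response_simplified(logl, pars$log_kd[i], pars$efficacy[i],
                                  pars$gain[i])
    expect_equal(via_occ, direct, tolerance = 1e-12)
  }
})

test_that("monotonicity and shift-sign semantics hold", {
  pars <- random_params(40, seed = 1234)
  logl <- seq(-11, -3, length.out = 25)
  for (i in seq_len(nrow(pars))) {
    y <- response_simplified(logl, pars$log_kd[i], pars$efficacy[i],
                             pars$gain[i])
    expect_true(all(diff(y) > 0))
    fr <- response_from_occupancy(seq(0, 1, by = 0.05), pars$efficacy[i],
                                  pars$gain[i])
    expect_true(all(diff(fr) > 0))
    kap <- kappa_from_params(pars$efficacy[i], pars$gain[i])
    if (pars$gain[i] > 1) expect_gt(kap, 1)
    if (pars$gain[i] < 1) expect_lt(kap, 1)
  }
  expect_equal(kappa_from_params(0.6, 1), 1)
})

test_that("predicted apex and midpoint match brute-force curve search", {
  pars <- random_params(25, seed = 2025)
  for (i in seq_len(nrow(pars))) {
    kd <- pars$log_kd[i]; e <- pars$efficacy[i]; g <- pars$gain[i]
    grid <- seq(kd - 6, kd + 6, by = 0.001)
    y <- response_simplified(grid, kd, e, g)
    emax_hat <- max(y)  # apex approached at the top of a wide grid
    emax_pred <- e_max_pred(e, g)
    expect_lt(abs(emax_hat - emax_pred) / emax_pred, 1e-3)
    # midpoint: linear interpolation of the crossing of e_max/2
    j <- which(y >= emax_pred / 2)[1]
    frac <- (emax_pred / 2 - y[j - 1]) / (y[j] - y[j - 1])
    ec50_hat <- 10^(grid[j - 1] + frac * 0.001)
    expect_lt(abs(ec50_hat - 10^k_obs(kd, e, g)) / 10^k_obs(kd, e, g), 1e-3)
  }
})
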
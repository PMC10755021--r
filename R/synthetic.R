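# Synthetic concentration-response panels: scenario specifications,
# built-in presets (two-pathway bias scenarios and the three two-pathway
# mu-opioid-receptor-like settings), and occupancy-threshold curves.

#' Scenario specification for synthetic panels
#'
#' Describes a ground-truth parameter panel plus a noise model.  `ligands`
#' is a named list; each element has `log_kd` and `efficacy`, where
#' `efficacy` is either a scalar (same in every pathway) or a vector named
#' by pathway.  `pathways` is a named numeric vector of gains.  The default
#' grid gives each ligand 9 points from its own log Kd - 3 to log Kd + 3,
#' covering shifts up to roughly 30-fold either way.
#'
#' @param ligands named list of `list(log_kd =, efficacy =)` entries.
#' @param pathways named numeric vector of per-pathway gains.
#' @param grid optional list `list(from =, to =, n =)` of absolute log10
#'   molar limits; `NULL` centres a 9-point grid on each ligand's Kd.
#' @param noise_sigma response-scale Gaussian standard deviation (fraction
#'   units, >= 0).
#' @param seed integer seed; identical specs generate identical panels.
#' @param hill Hill coefficient used for generation.
#' @param efficacy_r0 constitutive-activity efficacy used for generation.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(ligands, pathways, grid = NULL, noise_sigma = 0,
                          seed = 1, hill = 1, efficacy_r0 = 0) {
  if (!is.list(ligands) || is.null(names(ligands)) || any(!nzchar(names(ligands)))) {
    stop_bad_arg("ligands", "must be a named list")
  }
  if (!is.numeric(pathways) || is.null(names(pathways)) || any(!nzchar(names(pathways)))) {
    stop_bad_arg("pathways", "must be a named numeric vector of gains")
  }
  check_num(pathways, "pathways", positive = TRUE)
  for (nm in names(ligands)) {
    lg <- ligands[[nm]]
    if (!is.list(lg) || is.null(lg$log_kd) || is.null(lg$efficacy)) {
      stop_bad_arg(sprintf("ligands$%s", nm), "must be list(log_kd =, efficacy =)")
    }
    check_num(lg$log_kd, sprintf("ligands$%s$log_kd", nm), len = 1)
    check_num(lg$efficacy, sprintf("ligands$%s$efficacy", nm),
              lower = 0, upper = 1)
    if (length(lg$efficacy) > 1 &&
        !all(names(pathways) %in% names(lg$efficacy))) {
      stop_bad_arg(sprintf("ligands$%s$efficacy", nm),
                   "per-pathway efficacies must be named by pathway")
    }
  }
  if (!is.null(grid)) {
    check_num(grid$from, "grid$from", len = 1)
    check_num(grid$to, "grid$to", len = 1)
    check_num(grid$n, "grid$n", len = 1, lower = 2)
  }
  check_num(noise_sigma, "noise_sigma", len = 1, lower = 0)
  check_num(hill, "hill", len = 1, positive = TRUE)
  check_num(efficacy_r0, "efficacy_r0", len = 1, lower = 0, upper = 1)
  structure(list(ligands = ligands, pathways = pathways, grid = grid,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 hill = hill, efficacy_r0 = efficacy_r0),
            class = "scenario_spec")
}

#' Built-in scenario presets
#'
#' `"fig4"`: three hypothetical compounds (log Kd -7.0 / -6.5 / -8.0) on
#' two amplified pathways (gains 15 and 5); CpdTst1 is a balanced full
#' agonist (efficacy 1 in both pathways), CpdTst2 a biased agonist
#' (0.8 vs 0.2) and CpdTst3 a weak balanced agonist (0.25).
#' `"fig5"`: identical except pathway 2 is right-shifted (gain 0.15), so
#' weak agonists produce almost no pathway-2 response whether biased or
#' not.  `"fig1"`: an approximate reconstruction of the illustrative
#' one-ligand scenario with one strongly left-shifted (gain 30, so 20%
#' occupancy gives ~90% response) and one strongly right-shifted pathway
#' (gain 0.047, so 80% occupancy gives ~15% response).
#' `"mopr_mcpherson"`, `"mopr_hothersall"`, `"mopr_pedersen"`: two-pathway
#' (G-protein activation, left-shifted; beta-arrestin2 recruitment,
#' right-shifted) DAMGO/morphine settings using the published fitted
#' gains, efficacies and experimental log Kd values of the three
#' mu-opioid-receptor studies.
#'
#' @param name preset name.
#' @param noise_sigma,seed passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
scenario_preset <- function(name = c("fig4", "fig5", "fig1",
                                     "mopr_mcpherson", "mopr_hothersall",
                                     "mopr_pedersen"),
                            noise_sigma = 0, seed = 1) {
  name <- match.arg(name)
  cpd <- function(kd, e1, e2) list(log_kd = kd,
                                   efficacy = c(P1 = e1, P2 = e2))
  mopr <- function(kd_damgo, kd_morphine, g_gprt, g_barr, e_damgo, e_morphine) {
    scenario_spec(
      ligands = list(
        DAMGO = list(log_kd = kd_damgo,
                     efficacy = c(Gprt = e_damgo, bArr = e_damgo)),
        morphine = list(log_kd = kd_morphine,
                        efficacy = c(Gprt = e_morphine, bArr = e_morphine))),
      pathways = c(Gprt = g_gprt, bArr = g_barr),
      noise_sigma = noise_sigma, seed = seed)
  }
  switch(name,
    fig4 = scenario_spec(
      ligands = list(CpdTst1 = cpd(-7.0, 1.0, 1.0),
                     CpdTst2 = cpd(-6.5, 0.8, 0.2),
                     CpdTst3 = cpd(-8.0, 0.25, 0.25)),
      pathways = c(P1 = 15, P2 = 5),
      noise_sigma = noise_sigma, seed = seed),
    fig5 = scenario_spec(
      ligands = list(CpdTst1 = cpd(-7.0, 1.0, 1.0),
                     CpdTst2 = cpd(-6.5, 0.8, 0.2),
                     CpdTst3 = cpd(-8.0, 0.25, 0.25)),
      pathways = c(P1 = 15, P2 = 0.15),
      noise_sigma = noise_sigma, seed = seed),
    fig1 = scenario_spec(
      ligands = list(Cpd = cpd(-7.0, 1.0, 1.0)),
      pathways = c(P1 = 30, P2 = 0.047),
      noise_sigma = noise_sigma, seed = seed),
    mopr_mcpherson = mopr(-6.64, -6.60, 30.84, 0.669, 1.000, 0.178),
    mopr_hothersall = mopr(-6.62, -6.76, 9.88, 0.193, 0.948, 0.375),
    mopr_pedersen = mopr(-7.34, -7.02, 15.51, 0.059, 0.999, 0.823)
  )
}

# ground-truth sabre_params for one ligand-pathway of a spec
spec_params <- function(spec, ligand, pathway) {
  lg <- spec$ligands[[ligand]]
  eff <- if (length(lg$efficacy) > 1) lg$efficacy[[pathway]] else lg$efficacy
  sabre_params(log_kd = lg$log_kd, efficacy = eff,
               gain = spec$pathways[[pathway]],
               efficacy_r0 = spec$efficacy_r0, hill = spec$hill)
}

#' Generate a synthetic concentration-response panel
#'
#' Evaluates the full model for every ligand-pathway pair of the scenario
#' on the concentration grid, adds Gaussian noise of the specified sigma on
#' the fraction scale, and clips to the panel band \[-0.05, 1.10\].
#' Identical specs (including seed) generate identical panels.
#'
#' @param spec a [scenario_spec()] or preset name accepted by
#'   [scenario_preset()].
#' @return A `response_panel` with attribute `"spec"`.
#' @export
generate_panel <- function(spec) {
  if (is.character(spec)) spec <- scenario_preset(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  rows <- list()
  for (lig in names(spec$ligands)) {
    lg <- spec$ligands[[lig]]
    grid <- if (is.null(spec$grid)) {
      seq(lg$log_kd - 3, lg$log_kd + 3, length.out = 9)
    } else {
      seq(spec$grid$from, spec$grid$to, length.out = spec$grid$n)
    }
    for (pw in names(spec$pathways)) {
      p <- spec_params(spec, lig, pw)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = lig, pathway = pw, log_conc = grid,
        response = response_general(grid, p), stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(nrow(panel), 0, spec$noise_sigma))
    panel$response <- pmin(pmax(panel$response + noise, -0.05), 1.10)
  }
  panel <- as_response_panel(panel)
  attr(panel, "spec") <- spec
  panel
}

#' Occupancy-threshold response curve
#'
#' Models a co-occupancy requirement: if `nu` independently occupied
#' receptors within a system are needed to trigger the response, then
#' \eqn{f_{resp} \propto f_{occup}^{\nu}}.  The curve is normalized to its
#' maximum over the evaluation grid (the proportionality constant is not
#' otherwise determined).  `nu = 1` reduces to plain occupancy.  Fitted
#' with the three-parameter model (efficacy = 1, Kd fixed), a `nu = 2`
#' curve on a +/-3 log-unit grid appears as an apparent gain of about 0.4
#' and is slightly steeper than hyperbolic (best-fit Hill slope > 1).
#'
#' @param nu integer >= 1, number of receptors that must be co-occupied.
#' @param log_kd log10 Kd (molar) of the underlying binding.
#' @param grid list `list(from =, to =, n =)`; default 61 points spanning
#'   log Kd +/- 3.
#' @param noise_sigma Gaussian noise sigma on the fraction scale.
#' @param seed integer seed for the noise.
#' @return A single-curve `response_panel` (ligand `"threshold"`, pathway
#'   `sprintf("nu%d", nu)`).
#' @export
generate_threshold_panel <- function(nu, log_kd = -7, grid = NULL,
                                     noise_sigma = 0, seed = 1) {
  check_num(nu, "nu", len = 1, lower = 1)
  if (nu != round(nu)) stop_bad_arg("nu", "must be an integer >= 1")
  check_num(log_kd, "log_kd", len = 1)
  if (is.null(grid)) grid <- list(from = log_kd - 3, to = log_kd + 3, n = 61)
  lc <- seq(grid$from, grid$to, length.out = grid$n)
  f <- occupancy(lc, log_kd)^nu
  f <- f / max(f)
  if (noise_sigma > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sigma))
    f <- pmin(pmax(f, -0.05), 1.10)
  }
  panel <- as_response_panel(data.frame(
    ligand = "threshold", pathway = sprintf("nu%d", nu),
    log_conc = lc, response = f, stringsAsFactors = FALSE))
  attr(panel, "spec") <- list(nu = nu, log_kd = log_kd, grid = grid,
                              noise_sigma = noise_sigma, seed = seed)
  panel
}

#' Two-pathway mu-opioid-receptor-like panel
#'
#' Convenience wrapper: generates a DAMGO/morphine panel with one
#' left-shifted (G-protein) and one right-shifted (beta-arrestin2) pathway
#' from the published parameters of the chosen study.
#'
#' @param study one of `"mcpherson"`, `"hothersall"`, `"pedersen"`.
#' @param noise_sigma,seed passed through to the scenario.
#' @param grid optional absolute grid (see [scenario_spec()]).
#' @return A `response_panel`.
#' @export
generate_mopr_like <- function(study = c("mcpherson", "hothersall", "pedersen"),
                               noise_sigma = 0, seed = 1, grid = NULL) {
  study <- match.arg(study)
  spec <- scenario_preset(paste0("mopr_", study), noise_sigma = noise_sigma,
                          seed = seed)
  spec$grid <- grid
  generate_panel(spec)
}

#' Recovery constraints for a scenario
#'
#' Builds the constraint specification that pins every generating value of
#' a scenario except the efficacies and gains: per-ligand log Kd fixed at
#' the scenario's truth, gain shared per pathway, efficacy adjustable
#' (per-curve by default, or `"per-ligand"` to share across pathways),
#' constitutive activity and Hill slope fixed.  This is the standard
#' round-trip / parameter-recovery configuration for panels made by
#' [generate_panel()].
#'
#' @param spec a [scenario_spec()].
#' @param efficacy_group sharing group for the efficacy.
#' @return A `sabre_constraints` object.
#' @export
recovery_constraints <- function(spec, efficacy_group = "per-curve") {
  kd <- vapply(spec$ligands, `[[`, numeric(1), "log_kd")
  sabre_constraints(
    log_kd = par_fixed(kd),
    efficacy = par_shared(efficacy_group),
    gain = par_shared("per-pathway"),
    efficacy_r0 = par_fixed(spec$efficacy_r0),
    hill = par_fixed(spec$hill))
}
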
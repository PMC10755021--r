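# Global fit of the SABRE model across a multi-ligand, multi-pathway panel
# with parameter sharing driven by a constraint specification.

# natural-scale parameter matrix (curves x 5) from an optimizer vector;
# hot path: transforms applied vectorized via precomputed codes
# (1 identity, 2 log10, 3 scaled logit)
build_param_matrix <- function(t_opt, res) {
  th <- res$theta
  nat <- t_opt
  i2 <- th$tcode == 2L
  if (any(i2)) nat[i2] <- 10^t_opt[i2]
  i3 <- th$tcode == 3L
  if (any(i3)) {
    nat[i3] <- th$lower[i3] + (th$upper[i3] - th$lower[i3]) * plogis(t_opt[i3])
  }
  P <- res$fixed
  for (p in PARAM_NAMES) {
    adj <- res$index[, p] > 0L
    if (any(adj)) P[adj, p] <- nat[res$index[adj, p]]
  }
  P
}

# vector of fitted responses for every panel row; hot path of the
# optimizer, so the five-parameter form is evaluated in-line (vectorized
# over rows, no per-curve object construction)
sabre_fitted <- function(P, panel, curve_id) {
  kd <- P[curve_id, "log_kd"]; e <- P[curve_id, "efficacy"]
  g <- P[curve_id, "gain"]; e0 <- P[curve_id, "efficacy_r0"]
  n <- P[curve_id, "hill"]
  r <- exp(LN10 * n * (panel$log_conc - kd))
  eg <- e * g
  out <- (eg * r + e0 * g) / ((eg - e + 1) * r + (e0 * g - e0 + 1))
  inf <- is.infinite(r)
  if (any(inf)) out[inf] <- (eg / (eg - e + 1))[inf]
  out
}

#' Constrained global SABRE fit
#'
#' Fits the (up to) five-parameter model to all curves of a panel
#' simultaneously, with each parameter fixed, shared within groups
#' (global / per-ligand / per-pathway) or free per curve as declared in the
#' constraint specification.  The canonical design fixes per-ligand
#' experimental log Kd values and fits one gain per pathway plus one
#' efficacy per ligand.
#'
#' Optimization runs on transformed parameters (log10 gain and Hill slope,
#' scaled-logit efficacies, raw log Kd) from a deterministic Latin-hypercube
#' multistart; standard errors come from the residual Jacobian at the
#' optimum via the delta method.  If no ligand has a fixed Kd while the
#' gain is adjustable, the absolute affinity/gain scale is not identified
#' from response data alone (only efficacy-gain products and kappa shifts
#' are); the result is then flagged `scale_indeterminate` with a warning.
#'
#' @param panel a [as_response_panel()] data.frame (or coercible); each
#'   fitted curve needs at least 4 points (5 if the Hill slope is free).
#' @param constraints a [sabre_constraints()] object.
#' @param multistart number of optimizer starts (first is heuristic, rest
#'   Latin hypercube); default 8.
#' @param seed integer seed making the multistart deterministic.
#' @param weights optional per-point weights overriding a `weight` column.
#' @return A `sabre_fit` object: `estimates` (parameter, group, estimate,
#'   se), `residuals`, `sse`, `aicc`, `n_params`, `n_obs`, `converged`,
#'   `param_matrix` (resolved per-curve natural-scale parameters) and the
#'   `scale_indeterminate` flag.
#' @examples
#' spec <- scenario_preset("fig4")
#' panel <- generate_panel(spec)
#' fit <- fit_sabre_global(panel, sabre_constraints(
#'   log_kd = par_fixed(c(CpdTst1 = -7, CpdTst2 = -6.5, CpdTst3 = -8)),
#'   efficacy = par_free(),
#'   gain = par_shared("per-pathway")))
#' @export
fit_sabre_global <- function(panel, constraints = sabre_constraints(),
                             multistart = 8, seed = 42, weights = NULL) {
  panel <- as_response_panel(panel)
  res <- resolve_constraints(panel, constraints)
  curves <- res$curves
  curve_id <- panel_curve_id(panel, curves)
  hill_free <- res$index[, "hill"] > 0
  min_pts <- ifelse(hill_free, 5L, 4L)
  npts <- tabulate(curve_id, nbins = nrow(curves))
  if (any(npts < min_pts)) {
    bad <- which(npts < min_pts)[1]
    stop(sprintf("curve %s:%s has %d points; at least %d are required",
                 curves$ligand[bad], curves$pathway[bad], npts[bad],
                 min_pts[bad]), call. = FALSE)
  }
  if (res$scale_indeterminate) {
    warning(paste("no ligand has a fixed log_kd while gain is adjustable:",
                  "the fit is scale-indeterminate; only efficacy*gain",
                  "products and kappa shifts are reliable"), call. = FALSE)
  }
  w <- if (!is.null(weights)) weights else panel$weight
  sw <- if (is.null(w)) 1 else sqrt(w)

  th <- res$theta
  k <- nrow(th)
  if (k == 0) stop("constraints leave no adjustable parameter", call. = FALSE)
  if (k >= nrow(panel)) {
    stop(sprintf("%d adjustable parameters for %d observations", k,
                 nrow(panel)), call. = FALSE)
  }
  # specialize the residual closure: plain vectors only, row-level
  # parameter indices precomputed (this is the optimizer hot path)
  tlo <- th$lower; thi <- th$upper; tcode <- th$tcode
  i2 <- which(tcode == 2L); i3 <- which(tcode == 3L)
  ridx <- res$index[curve_id, , drop = FALSE]
  rfix <- res$fixed[curve_id, , drop = FALSE]
  lc <- panel$log_conc; yobs <- panel$response
  row_par <- vector("list", 5L)
  for (j in 1:5) {
    sel <- ridx[, j] > 0L
    row_par[[j]] <- list(base = rfix[, j], sel = sel, map = ridx[sel, j])
  }
  eval_fitted <- function(t_opt) {
    nat <- t_opt
    if (length(i2)) nat[i2] <- 10^t_opt[i2]
    if (length(i3)) {
      nat[i3] <- tlo[i3] + (thi[i3] - tlo[i3]) * plogis(t_opt[i3])
    }
    v <- lapply(row_par, function(rp) {
      x <- rp$base
      if (any(rp$sel)) x[rp$sel] <- nat[rp$map]
      x
    })
    kd <- v[[1]]; e <- v[[2]]; g <- v[[3]]; e0 <- v[[4]]; n <- v[[5]]
    r <- exp(LN10 * n * (lc - kd))
    eg <- e * g
    out <- (eg * r + e0 * g) / ((eg - e + 1) * r + (e0 * g - e0 + 1))
    inf <- is.infinite(r)
    if (any(inf)) out[inf] <- (eg / (eg - e + 1))[inf]
    out
  }
  resid_fn <- function(t_opt) sw * (yobs - eval_fitted(t_opt))
  # heuristic start: efficacy from each group's top observed response
  start_nat <- th$init
  for (j in seq_len(k)) {
    if (th$param[j] == "efficacy") {
      rows <- curve_id %in% which(res$index[, "efficacy"] == j)
      if (any(rows)) {
        start_nat[j] <- min(max(max(panel$response[rows]), 0.05),
                            th$upper[j] - 1e-4)
      }
    }
  }
  start_opt <- vapply(seq_len(k), function(j) {
    theta_to_opt(start_nat[j], th$param[j], th$lower[j], th$upper[j])
  }, numeric(1))
  bounds <- vapply(seq_len(k), function(j) {
    opt_bounds(th$param[j], th$lower[j], th$upper[j])
  }, numeric(2))
  best <- ls_multistart(resid_fn, start_opt, bounds[1, ], bounds[2, ],
                        multistart = multistart, seed = seed)
  t_hat <- best$par
  P <- build_param_matrix(t_hat, res)
  fitted <- sabre_fitted(P, panel, curve_id)
  r <- panel$response - fitted
  sse <- sum((sw * r)^2)
  J <- num_jacobian(resid_fn, t_hat)
  se_t <- se_from_jacobian(J, sse, nrow(panel), k)
  nat <- vapply(seq_len(k), function(j) {
    opt_to_theta(t_hat[j], th$param[j], th$lower[j], th$upper[j])
  }, numeric(1))
  se_nat <- vapply(seq_len(k), function(j) {
    se_t[j] * abs(dtheta_dopt(t_hat[j], th$param[j], th$lower[j], th$upper[j]))
  }, numeric(1))
  estimates <- data.frame(
    parameter = th$param,
    group = sub("^[a-z_0-9]+\\[(.*)\\]$", "\\1",
                ifelse(grepl("\\[", th$label), th$label, paste0(th$param, "[global]"))),
    label = th$label, estimate = nat, se = se_nat,
    lower = th$lower, upper = th$upper, stringsAsFactors = FALSE)
  residuals <- data.frame(ligand = panel$ligand, pathway = panel$pathway,
                          log_conc = panel$log_conc,
                          observed = panel$response, fitted = fitted,
                          residual = r, stringsAsFactors = FALSE)
  pm <- as.data.frame(P)
  pm <- cbind(curves, pm)
  new_sabre_fit("sabre_global", estimates, residuals, sse,
                n_params = k, n_obs = nrow(panel),
                converged = isTRUE(best$converged), seed = seed,
                fingerprint = panel_fingerprint(panel),
                extra = list(param_matrix = pm,
                             scale_indeterminate = res$scale_indeterminate,
                             objective = best$objective,
                             multistart = multistart))
}
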
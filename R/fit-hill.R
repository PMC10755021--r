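# Independent sigmoid (Hill/Clark) fits, one curve at a time -- the
# conventional per-curve EC50/e_max analysis the global model is compared
# against.

#' Independent Hill fits per curve
#'
#' Fits `e_max` and `log_ec50` (plus the Hill slope `n` unless
#' `fix_hill_at_one`) separately to every ligand-pathway curve of the
#' panel.  Each curve contributes 2 (or 3) parameters to the total count
#' used for AICc, e.g. 7 curves with fixed slope give 14 parameters.
#'
#' Curves whose responses never exceed 0.1 are flagged `low_information`
#' (the plateau is unseen, so EC50 and e_max are poorly identified and
#' their standard errors are wide); non-convergence is reported per curve
#' in the `converged` column rather than dropped.  Fitted `e_max` is
#' allowed up to 1.2 so that noisy full-agonist curves are not pinned at
#' the theoretical bound.
#'
#' @inheritParams fit_sabre_global
#' @param fix_hill_at_one logical; fix n = 1 (Clark shape) or fit it.
#' @return A `sabre_fit` object; `estimates` has one row per parameter per
#'   curve and `curve_table` one row per curve (ligand, pathway, e_max,
#'   log_ec50, hill, ses, converged, low_information).
#' @export
fit_hill_per_curve <- function(panel, fix_hill_at_one = TRUE,
                               multistart = 4, seed = 42, weights = NULL) {
  panel <- as_response_panel(panel)
  curves <- panel_curves(panel)
  curve_id <- panel_curve_id(panel, curves)
  min_pts <- if (fix_hill_at_one) 4L else 5L
  w_all <- if (!is.null(weights)) weights else panel$weight

  est_rows <- list(); curve_rows <- list()
  fitted_all <- numeric(nrow(panel))
  total_k <- 0L
  for (i in seq_len(nrow(curves))) {
    rows <- which(curve_id == i)
    lc <- panel$log_conc[rows]; y <- panel$response[rows]
    sw <- if (is.null(w_all)) 1 else sqrt(w_all[rows])
    if (length(rows) < min_pts) {
      stop(sprintf("curve %s:%s has %d points; at least %d are required",
                   curves$ligand[i], curves$pathway[i], length(rows), min_pts),
           call. = FALSE)
    }
    # parameters on optimizer scale: log_ec50 raw, e_max scaled-logit in
    # (0.001, 1.2), hill log10 in [0.3, 5]
    e_lo <- 1e-3; e_hi <- 1.2
    ec_b <- c(min(lc[is.finite(lc)]) - 3, max(lc[is.finite(lc)]) + 3)
    pars <- c("log_ec50", "e_max", if (!fix_hill_at_one) "hill")
    make_hp <- function(t) {
      list(log_ec50 = t[1],
           e_max = e_lo + (e_hi - e_lo) * plogis(t[2]),
           hill = if (fix_hill_at_one) 1 else 10^t[3])
    }
    resid_fn <- function(t) {
      hp <- make_hp(t)
      sw * (y - hp$e_max * plogis(LN10 * hp$hill * (lc - hp$log_ec50)))
    }
    emax0 <- min(max(max(y), 0.05), e_hi - 1e-3)
    ec0 <- lc[which.min(abs(y - emax0 / 2))]
    start <- c(ec0, qlogis((emax0 - e_lo) / (e_hi - e_lo)),
               if (!fix_hill_at_one) 0)
    lower <- c(ec_b[1], -LOGIT_CAP, if (!fix_hill_at_one) log10(0.3))
    upper <- c(ec_b[2], LOGIT_CAP, if (!fix_hill_at_one) log10(5))
    k <- length(start)
    total_k <- total_k + k
    fit <- tryCatch(
      ls_multistart(resid_fn, start, lower, upper,
                    multistart = multistart, seed = seed + i),
      error = function(e) NULL)
    if (is.null(fit)) {
      curve_rows[[i]] <- data.frame(
        ligand = curves$ligand[i], pathway = curves$pathway[i],
        e_max = NA_real_, se_e_max = NA_real_, log_ec50 = NA_real_,
        se_log_ec50 = NA_real_, hill = NA_real_, se_hill = NA_real_,
        sse = NA_real_, converged = FALSE,
        low_information = max(y) < 0.1, stringsAsFactors = FALSE)
      next
    }
    t_hat <- fit$par
    hp <- make_hp(t_hat)
    fitted <- hp$e_max * plogis(LN10 * hp$hill * (lc - hp$log_ec50))
    fitted_all[rows] <- fitted
    r <- y - fitted
    sse_i <- sum((sw * r)^2)
    J <- num_jacobian(resid_fn, t_hat)
    se_t <- se_from_jacobian(J, sse_i, length(rows), k)
    pl <- plogis(t_hat[2])
    se_nat <- c(se_t[1], se_t[2] * (e_hi - e_lo) * pl * (1 - pl),
                if (!fix_hill_at_one) se_t[3] * LN10 * 10^t_hat[3])
    curve_rows[[i]] <- data.frame(
      ligand = curves$ligand[i], pathway = curves$pathway[i],
      e_max = hp$e_max, se_e_max = se_nat[2],
      log_ec50 = hp$log_ec50, se_log_ec50 = se_nat[1],
      hill = hp$hill, se_hill = if (fix_hill_at_one) NA_real_ else se_nat[3],
      sse = sse_i, converged = isTRUE(fit$converged),
      low_information = max(y) < 0.1, stringsAsFactors = FALSE)
    glab <- paste(curves$ligand[i], curves$pathway[i], sep = ":")
    est_rows[[i]] <- data.frame(
      parameter = pars, group = glab,
      label = sprintf("%s[%s]", pars, glab),
      estimate = unlist(hp[pars], use.names = FALSE),
      se = se_nat[match(pars, c("log_ec50", "e_max", "hill"))],
      lower = c(ec_b[1], e_lo, if (!fix_hill_at_one) 0.3),
      upper = c(ec_b[2], e_hi, if (!fix_hill_at_one) 5),
      stringsAsFactors = FALSE)
  }
  curve_table <- do.call(rbind, curve_rows)
  estimates <- do.call(rbind, est_rows)
  r_all <- panel$response - fitted_all
  sw_all <- if (is.null(w_all)) 1 else sqrt(w_all)
  sse <- sum((sw_all * r_all)^2)
  residuals <- data.frame(ligand = panel$ligand, pathway = panel$pathway,
                          log_conc = panel$log_conc,
                          observed = panel$response, fitted = fitted_all,
                          residual = r_all, stringsAsFactors = FALSE)
  new_sabre_fit("hill_per_curve", estimates, residuals, sse,
                n_params = total_k, n_obs = nrow(panel),
                converged = all(curve_table$converged), seed = seed,
                fingerprint = panel_fingerprint(panel),
                extra = list(curve_table = curve_table,
                             fix_hill_at_one = fix_hill_at_one))
}
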
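# Pure evaluators for the SABRE model, its classical reductions, and the
# occupancy/response transforms.  Concentrations are log10 molar throughout;
# responses are fractions in [0, 1] (percent only at the I/O boundary).

LN10 <- log(10)

# Guard for log-concentration vectors: NA/NaN rejected, +/-Inf allowed
# (the hyperbolic forms have well-defined limits there).
check_logl <- function(logL) {
  if (!is.numeric(logL) || length(logL) == 0) {
    stop_bad_arg("logL", "must be a non-empty numeric vector of log10 molar concentrations")
  }
  if (anyNA(logL)) {
    stop_bad_arg("logL", "contains NA/NaN; log10 molar concentrations must be real (+/-Inf allowed as limits)")
  }
  invisible(logL)
}

#' Full five-parameter SABRE response
#'
#' Fractional response
#' \deqn{E/E_{max} = \frac{\varepsilon\gamma L^n + \varepsilon_{R0}\gamma K_d^n}
#'   {(\varepsilon\gamma - \varepsilon + 1) L^n +
#'    (\varepsilon_{R0}\gamma - \varepsilon_{R0} + 1) K_d^n}}
#' Evaluated in a normalized form (dividing through by \eqn{K_d^n}) for
#' numerical stability across wide concentration ranges.  With
#' `efficacy_r0 = 0` and `hill = 1` this reduces exactly to
#' [response_simplified()]; with `gain = 1` further to the Clark equation.
#' A nonzero `efficacy_r0` yields a nonzero basal response at L = 0; no
#' baseline subtraction is performed here (the caller owns baselines).
#'
#' @param logL numeric vector of log10 molar concentrations (+/-Inf allowed
#'   as limits; NA rejected).
#' @param p a [sabre_params()] object.
#' @return Fractional response in \[0, 1\], same length as `logL`.
#' @examples
#' p <- sabre_params(-6.64, efficacy = 1, gain = 30.84)
#' response_general(-6.64, p)  # 30.84/31.84
#' @export
response_general <- function(logL, p) {
  if (!inherits(p, "sabre_params")) p <- do.call(sabre_params, as.list(p))
  check_logl(logL)
  r <- exp(LN10 * p$hill * (logL - p$log_kd))  # (L/Kd)^n
  eg <- p$efficacy * p$gain
  num0 <- p$efficacy_r0 * p$gain
  den0 <- p$efficacy_r0 * p$gain - p$efficacy_r0 + 1
  out <- (eg * r + num0) / ((eg - p$efficacy + 1) * r + den0)
  # limits: r = Inf -> emax; r = 0 handled by the finite constant term
  inf <- is.infinite(r)
  if (any(inf)) out[inf] <- eg / (eg - p$efficacy + 1)
  out
}

#' Three-parameter SABRE response (no constitutive activity, unit Hill slope)
#'
#' \deqn{E/E_{max} = \frac{\varepsilon\gamma L}
#'   {(\varepsilon\gamma - \varepsilon + 1) L + K_d}}
#' With `gain = 1` this is the Clark equation with \eqn{e_{max} = \varepsilon}.
#'
#' @inheritParams response_general
#' @param log_kd log10 Kd (molar).
#' @param efficacy efficacy \eqn{\varepsilon} in \[0, 1\].
#' @param gain gain \eqn{\gamma > 0}.
#' @return Fractional response in \[0, 1\].
#' @export
response_simplified <- function(logL, log_kd, efficacy, gain) {
  p <- sabre_params(log_kd = log_kd, efficacy = efficacy, gain = gain,
                    efficacy_r0 = 0, hill = 1)
  response_general(logL, p)
}

#' Fractional receptor occupancy
#'
#' Law-of-mass-action occupancy \eqn{L^n/(L^n + K_d^n)}; always saturates at
#' 100 percent, equals 0.5 at L = Kd for any Hill coefficient.
#'
#' @inheritParams response_simplified
#' @param hill Hill coefficient n > 0.
#' @return Fractional occupancy in \[0, 1\].
#' @export
occupancy <- function(logL, log_kd, hill = 1) {
  check_logl(logL)
  check_num(log_kd, "log_kd", len = 1)
  check_num(hill, "hill", len = 1, positive = TRUE)
  plogis(LN10 * hill * (logL - log_kd))
}

#' Predicted log10 EC50 (Kobs) from SABRE parameters
#'
#' \deqn{K_{obs} = K_d / (\varepsilon\gamma - \varepsilon + 1)}
#' so that for a full agonist (\eqn{\varepsilon = 1}) the fold-shift is
#' exactly \eqn{\gamma}; \eqn{\gamma = 1} gives Kobs = Kd.
#'
#' @inheritParams response_simplified
#' @return log10 EC50 (molar).
#' @export
k_obs <- function(log_kd, efficacy, gain) {
  check_num(log_kd, "log_kd", len = 1)
  check_num(efficacy, "efficacy", len = 1, lower = 0, upper = 1)
  check_num(gain, "gain", len = 1, positive = TRUE)
  kap <- efficacy * gain - efficacy + 1
  if (kap <= 0) {
    stop("degenerate parameters: efficacy*gain - efficacy + 1 must be > 0",
         call. = FALSE)
  }
  log_kd - log10(kap)
}

#' Predicted maximal fractional response from SABRE parameters
#'
#' \deqn{e_{max} = \varepsilon\gamma / (\varepsilon\gamma - \varepsilon + 1)}
#' Equals \eqn{\varepsilon} when \eqn{\gamma = 1}; equals 1 for a full
#' agonist regardless of gain.
#'
#' @inheritParams response_simplified
#' @return Fractional maximal response in (0, 1\].
#' @export
e_max_pred <- function(efficacy, gain) {
  check_num(efficacy, "efficacy", len = 1, lower = 0, upper = 1)
  check_num(gain, "gain", len = 1, positive = TRUE)
  kap <- efficacy * gain - efficacy + 1
  if (kap <= 0) {
    stop("degenerate parameters: efficacy*gain - efficacy + 1 must be > 0",
         call. = FALSE)
  }
  efficacy * gain / kap
}

#' Shift parameter kappa from observed midpoints
#'
#' \deqn{\kappa = K_d / EC_{50}}, the fold shift between the response and
#' occupancy midpoints.  \eqn{\kappa > 1}: response left-shifted versus
#' occupancy (more concentration-sensitive); \eqn{\kappa < 1}: right-shifted.
#'
#' @param log_kd log10 Kd (molar).
#' @param log_ec50 log10 EC50 (molar).
#' @return kappa (dimensionless, > 0).
#' @examples
#' kappa_from_shift(-6.62, -7.72)  # 12.59: left-shifted G-protein response
#' kappa_from_shift(-6.62, -6.02)  # 0.251: right-shifted arrestin response
#' @export
kappa_from_shift <- function(log_kd, log_ec50) {
  check_num(log_kd, "log_kd")
  check_num(log_ec50, "log_ec50")
  10^(log_kd - log_ec50)
}

#' Shift parameter kappa from SABRE parameters
#'
#' \deqn{\kappa = \varepsilon\gamma - \varepsilon + 1}; reduces to
#' \eqn{\gamma} for a full agonist.
#'
#' @inheritParams response_simplified
#' @return kappa (dimensionless, > 0).
#' @export
kappa_from_params <- function(efficacy, gain) {
  check_num(efficacy, "efficacy", lower = 0, upper = 1)
  check_num(gain, "gain", positive = TRUE)
  kap <- efficacy * gain - efficacy + 1
  if (any(kap <= 0)) {
    stop("nonpositive kappa: efficacy*gain - efficacy + 1 must be > 0",
         call. = FALSE)
  }
  kap
}

#' Response as a function of occupancy, generic hyperbolic form
#'
#' Links two hyperbolic curves sharing a concentration axis:
#' \deqn{f_{resp} = e_{max}\frac{\kappa}{\kappa-1}
#'   \frac{f_{occup}}{f_{occup} + 1/(\kappa-1)}}
#' (occupancy maximum e100 fixed at 1).  The \eqn{\kappa \to 1} singularity
#' is removable; within `|kappa - 1| < 1e-9` the analytic limit
#' \eqn{e_{max} f_{occup}} (the "unity line" scaled by e_max) is returned.
#'
#' @param f_occup fractional occupancy in \[0, 1\].
#' @param e_max maximal fractional response in (0, 1\].
#' @param kappa shift parameter \eqn{\kappa > 0}.
#' @return Fractional response, same length as `f_occup`.
#' @export
response_from_occupancy_generic <- function(f_occup, e_max, kappa) {
  check_num(f_occup, "f_occup", lower = 0, upper = 1)
  check_num(e_max, "e_max", len = 1, upper = 1)
  if (e_max <= 0) stop_bad_arg("e_max", "must be > 0")
  check_num(kappa, "kappa", len = 1, positive = TRUE)
  if (abs(kappa - 1) < 1e-9) {
    return(e_max * f_occup)
  }
  # algebraically e_max*kappa/(kappa-1) * f/(f + 1/(kappa-1))
  # = e_max*kappa*f / ((kappa-1)*f + 1), stable for kappa < 1 too
  e_max * kappa * f_occup / ((kappa - 1) * f_occup + 1)
}

#' Response as a function of occupancy, SABRE parameters
#'
#' Composition of the occupancy inverse with the three-parameter response:
#' \deqn{f_{resp} = \frac{\varepsilon\gamma f_{occup}}
#'   {\varepsilon(\gamma-1) f_{occup} + 1}}
#' identical to [response_from_occupancy_generic()] with
#' \eqn{\kappa = \varepsilon\gamma-\varepsilon+1} and e_max from
#' [e_max_pred()], and identical to [response_simplified()] composed with
#' the inverse of [occupancy()].  \eqn{\gamma = 1} (the removable
#' \eqn{\kappa = 1} case) returns the linear limit
#' \eqn{\varepsilon f_{occup}}.
#'
#' @inheritParams response_from_occupancy_generic
#' @param efficacy efficacy \eqn{\varepsilon} in \[0, 1\].
#' @param gain gain \eqn{\gamma > 0}.
#' @return Fractional response.
#' @export
response_from_occupancy <- function(f_occup, efficacy, gain) {
  check_num(efficacy, "efficacy", len = 1, lower = 0, upper = 1)
  check_num(gain, "gain", len = 1, positive = TRUE)
  response_from_occupancy_generic(f_occup,
                                  e_max = e_max_pred(efficacy, gain),
                                  kappa = kappa_from_params(efficacy, gain))
}

#' Hill/Clark sigmoid response
#'
#' \deqn{E/E_{max} = e_{max} L^n / (L^n + EC_{50}^n)}; n = 1 gives the Clark
#' equation.
#'
#' @inheritParams response_general
#' @param hp a [hill_params()] object.
#' @return Fractional response.
#' @export
hill_response <- function(logL, hp) {
  if (!inherits(hp, "hill_params")) hp <- do.call(hill_params, as.list(hp))
  check_logl(logL)
  hp$e_max * plogis(LN10 * hp$hill * (logL - hp$log_ec50))
}

#' Operational (Black & Leff) model response
#'
#' \deqn{E/E_{max} = \tau L / ((\tau + 1) L + K_D)}; apparent
#' \eqn{e_{max} = \tau/(\tau+1)}, apparent \eqn{EC_{50} = K_D/(\tau+1)}.
#' Forward evaluation only (used as a comparator; not fitted).
#'
#' @inheritParams response_general
#' @param op an [operational_params()] object.
#' @return Fractional response.
#' @export
operational_response <- function(logL, op) {
  if (!inherits(op, "operational_params")) op <- do.call(operational_params, as.list(op))
  check_logl(logL)
  r <- exp(LN10 * (logL - op$log_KD))  # L/KD
  out <- op$tau * r / ((op$tau + 1) * r + 1)
  inf <- is.infinite(r)
  if (any(inf)) out[inf] <- op$tau / (op$tau + 1)
  out
}

#' Cheng-Prusoff correction of a competition IC50
#'
#' Converts a competition-binding IC50 into a Kd accounting for the
#' radioligand occupancy: \eqn{K_d = IC_{50} / (1 + [RL]/K_{d,RL})}.
#'
#' @param ic50 competition IC50 (molar, > 0).
#' @param radioligand_conc radioligand concentration (molar, >= 0; 0 means
#'   no correction).
#' @param radioligand_kd radioligand Kd (molar, > 0).
#' @return log10 Kd (molar).
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_kd) {
  check_num(ic50, "ic50", positive = TRUE)
  check_num(radioligand_conc, "radioligand_conc", lower = 0)
  check_num(radioligand_kd, "radioligand_kd", positive = TRUE)
  log10(ic50 / (1 + radioligand_conc / radioligand_kd))
}
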
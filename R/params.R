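#' SABRE parameter set for one ligand-pathway pair
#'
#' Bundles the five model symbols: `log_kd` (log10 of the equilibrium
#' dissociation constant, molar), `efficacy` (\eqn{\varepsilon}, ability of
#' the bound ligand to activate the receptor, capped at 1), `gain`
#' (\eqn{\gamma}, pathway signal amplification; \eqn{\gamma>1} amplification,
#' \eqn{\gamma<1} attenuation, \eqn{\gamma=1} neutral), `efficacy_r0`
#' (\eqn{\varepsilon_{R0}}, constitutive-activity efficacy of unoccupied
#' receptors) and `hill` (Hill coefficient n).
#'
#' @param log_kd log10 Kd (molar); finite.
#' @param efficacy efficacy \eqn{\varepsilon} in \[0, 1\].
#' @param gain gain \eqn{\gamma > 0}.
#' @param efficacy_r0 constitutive-activity efficacy in \[0, 1\]; default 0.
#' @param hill Hill coefficient n > 0; default 1.
#' @return An object of class `sabre_params`.
#' @examples
#' p <- sabre_params(log_kd = -7, efficacy = 0.5, gain = 15)
#' response_general(seq(-10, -4, by = 0.5), p)
#' @export
sabre_params <- function(log_kd, efficacy, gain, efficacy_r0 = 0, hill = 1) {
  check_num(log_kd, "log_kd", len = 1)
  check_num(efficacy, "efficacy", len = 1, lower = 0, upper = 1)
  check_num(gain, "gain", len = 1, positive = TRUE)
  check_num(efficacy_r0, "efficacy_r0", len = 1, lower = 0, upper = 1)
  check_num(hill, "hill", len = 1, positive = TRUE)
  structure(
    list(log_kd = log_kd, efficacy = efficacy, gain = gain,
         efficacy_r0 = efficacy_r0, hill = hill),
    class = "sabre_params"
  )
}

#' @export
print.sabre_params <- function(x, ...) {
  cat(sprintf(
    "SABRE parameters: log Kd = %.4g, efficacy = %.4g, gain = %.4g, efficacy_r0 = %.4g, hill = %.4g\n",
    x$log_kd, x$efficacy, x$gain, x$efficacy_r0, x$hill))
  invisible(x)
}

#' Hill (sigmoid) curve parameters
#'
#' @param log_ec50 log10 EC50 (molar); the observed half-maximal
#'   concentration (Kobs).
#' @param e_max maximal fractional response in (0, 1\] (percent only at I/O).
#' @param hill Hill coefficient n > 0.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(log_ec50, e_max, hill = 1) {
  check_num(log_ec50, "log_ec50", len = 1)
  check_num(e_max, "e_max", len = 1, upper = 1)
  if (e_max <= 0) stop_bad_arg("e_max", "must be > 0")
  check_num(hill, "hill", len = 1, positive = TRUE)
  structure(list(log_ec50 = log_ec50, e_max = e_max, hill = hill),
            class = "hill_params")
}

#' Operational (Black & Leff) model parameters
#'
#' @param log_KD log10 of the operational-model dissociation constant
#'   (molar); note this is not the experimental binding Kd.
#' @param tau transducer ratio \eqn{\tau > 0}.
#' @return An object of class `operational_params`.
#' @export
operational_params <- function(log_KD, tau) {
  check_num(log_KD, "log_KD", len = 1)
  check_num(tau, "tau", len = 1, positive = TRUE)
  structure(list(log_KD = log_KD, tau = tau), class = "operational_params")
}
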
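# Declarative constraint specification for the global fit.  Each of the five
# model parameters (log_kd, efficacy, gain, efficacy_r0, hill) is resolved to
# exactly one rule: fixed at given value(s), shared within a grouping
# (global / per-ligand / per-pathway), or free per curve.

PARAM_NAMES <- c("log_kd", "efficacy", "gain", "efficacy_r0", "hill")

# default box bounds on the natural scale, per parameter
default_bounds <- function(param) {
  switch(param,
    log_kd      = c(-14, -2),
    efficacy    = c(1e-3, 1),
    gain        = c(0.01, 1000),
    efficacy_r0 = c(0, 0.5),
    hill        = c(0.3, 5),
    stop("unknown parameter: ", param)
  )
}

default_init <- function(param) {
  switch(param,
    log_kd = -7, efficacy = 0.5, gain = 1, efficacy_r0 = 0.01, hill = 1)
}

#' Constraint rules for a single model parameter
#'
#' `par_fixed(value)` pins the parameter; `value` may be a scalar or a
#' vector named by ligand, pathway or `"ligand:pathway"` (e.g. per-ligand
#' experimental log Kd values).  `par_shared(group)` makes the parameter
#' adjustable with one value per group: `"global"`, `"per-ligand"`,
#' `"per-pathway"` or `"per-curve"`.  `par_free()` is shorthand for
#' `par_shared("per-curve")` (one independent value per ligand-pathway
#' curve).  `lower`/`upper`/`init` override the parameter's default box
#' bounds and starting value.
#'
#' @param value numeric scalar or named numeric vector.
#' @param group sharing structure; see Details.
#' @param lower,upper,init optional bounds and starting value (natural
#'   scale).
#' @return A rule object consumed by [sabre_constraints()].
#' @name constraint_rules
NULL

#' @rdname constraint_rules
#' @export
par_fixed <- function(value) {
  check_num(value, "value")
  structure(list(rule = "fixed", value = value), class = "sabre_rule")
}

#' @rdname constraint_rules
#' @export
par_shared <- function(group = c("global", "per-ligand", "per-pathway", "per-curve"),
                       lower = NULL, upper = NULL, init = NULL) {
  group <- match.arg(group)
  structure(list(rule = "shared", group = group,
                 lower = lower, upper = upper, init = init),
            class = "sabre_rule")
}

#' @rdname constraint_rules
#' @export
par_free <- function(lower = NULL, upper = NULL, init = NULL) {
  par_shared("per-curve", lower = lower, upper = upper, init = init)
}

#' Assemble a full constraint specification
#'
#' Defaults reproduce the canonical multi-ligand, multi-pathway design:
#' per-ligand binding affinity (free unless pinned to experimental values),
#' one efficacy per ligand shared across pathways, one gain per pathway,
#' no constitutive activity, unit Hill slope.
#'
#' @param log_kd,efficacy,gain,efficacy_r0,hill rule objects from
#'   [par_fixed()], [par_shared()] or [par_free()].
#' @return An object of class `sabre_constraints`.
#' @examples
#' sabre_constraints(
#'   log_kd = par_fixed(c(CpdTst1 = -7, CpdTst2 = -6.5, CpdTst3 = -8)),
#'   efficacy = par_shared("per-ligand"),
#'   gain = par_shared("per-pathway")
#' )
#' @export
sabre_constraints <- function(log_kd = par_shared("per-ligand"),
                              efficacy = par_shared("per-ligand"),
                              gain = par_shared("per-pathway"),
                              efficacy_r0 = par_fixed(0),
                              hill = par_fixed(1)) {
  rules <- list(log_kd = log_kd, efficacy = efficacy, gain = gain,
                efficacy_r0 = efficacy_r0, hill = hill)
  for (p in PARAM_NAMES) {
    if (!inherits(rules[[p]], "sabre_rule")) {
      stop_bad_arg(p, "must be a rule built with par_fixed()/par_shared()/par_free()")
    }
  }
  structure(rules, class = "sabre_constraints")
}

# look up a (possibly named) fixed value for one curve
lookup_fixed <- function(value, param, ligand, pathway) {
  if (is.null(names(value))) {
    if (length(value) != 1) {
      stop(sprintf("fixed values for `%s` must be scalar or named", param),
           call. = FALSE)
    }
    return(unname(value))
  }
  for (key in c(paste(ligand, pathway, sep = ":"), ligand, pathway)) {
    if (key %in% names(value)) return(unname(value[[key]]))
  }
  stop(sprintf("no fixed `%s` value for curve %s:%s (names tried: '%s:%s', '%s', '%s')",
               param, ligand, pathway, ligand, pathway, ligand, pathway),
       call. = FALSE)
}

# Resolve a constraint spec against a panel.  Returns:
#   theta  - data.frame of adjustable scalars (label, param, lower, upper, init)
#   index  - curves x 5 integer matrix (0 = fixed, else row of theta)
#   fixed  - curves x 5 numeric matrix of fixed values (NA where adjustable)
#   curves - the (ligand, pathway) table
resolve_constraints <- function(panel, constraints) {
  stopifnot(inherits(constraints, "sabre_constraints"))
  curves <- panel_curves(panel)
  nc <- nrow(curves)
  index <- matrix(0L, nc, length(PARAM_NAMES),
                  dimnames = list(NULL, PARAM_NAMES))
  fixed <- matrix(NA_real_, nc, length(PARAM_NAMES),
                  dimnames = list(NULL, PARAM_NAMES))
  theta <- data.frame(label = character(), param = character(),
                      lower = numeric(), upper = numeric(), init = numeric(),
                      tcode = integer(), stringsAsFactors = FALSE)
  for (p in PARAM_NAMES) {
    rule <- constraints[[p]]
    if (rule$rule == "fixed") {
      for (i in seq_len(nc)) {
        fixed[i, p] <- lookup_fixed(rule$value, p,
                                    curves$ligand[i], curves$pathway[i])
      }
      next
    }
    b <- default_bounds(p)
    lo <- if (is.null(rule$lower)) b[1] else rule$lower
    hi <- if (is.null(rule$upper)) b[2] else rule$upper
    ini <- if (is.null(rule$init)) min(max(default_init(p), lo), hi) else rule$init
    for (i in seq_len(nc)) {
      glab <- switch(rule$group,
        "global"      = "",
        "per-ligand"  = curves$ligand[i],
        "per-pathway" = curves$pathway[i],
        "per-curve"   = paste(curves$ligand[i], curves$pathway[i], sep = ":"))
      label <- if (nzchar(glab)) sprintf("%s[%s]", p, glab) else p
      j <- match(label, theta$label)
      if (is.na(j)) {
        theta <- rbind(theta, data.frame(
          label = label, param = p, lower = lo, upper = hi, init = ini,
          tcode = transform_code(p), stringsAsFactors = FALSE))
        j <- nrow(theta)
      }
      index[i, p] <- j
    }
  }
  # identifiability guards ------------------------------------------------
  for (i in seq_len(nc)) {
    trio <- index[i, c("log_kd", "efficacy", "gain")]
    if (all(trio > 0)) {
      # all three adjustable on this curve; fatal if none of the three is
      # informed by any other curve (pure efficacy*gain/Kd coupling)
      alone <- vapply(trio, function(j) sum(index == j) == 1, logical(1))
      if (all(alone)) {
        stop(sprintf(
          paste0("unidentifiable constraints for curve %s:%s: log_kd, ",
                 "efficacy and gain are all free on a single curve, but a ",
                 "single sigmoid only determines EC50 and e_max, which ",
                 "couple efficacy and gain (kappa = efficacy*gain - ",
                 "efficacy + 1); fix or share at least one of them"),
          curves$ligand[i], curves$pathway[i]), call. = FALSE)
      }
    }
  }
  scale_indeterminate <-
    constraints$log_kd$rule != "fixed" && constraints$gain$rule != "fixed"
  list(theta = theta, index = index, fixed = fixed, curves = curves,
       scale_indeterminate = scale_indeterminate)
}

# ---- parameter transforms (natural <-> optimizer scale) ------------------
# gain, hill: log10; efficacy, efficacy_r0: scaled logit; log_kd: identity.
# Logit arguments are clamped so bounds themselves map to +/-LOGIT_CAP.
LOGIT_CAP <- 16

theta_to_opt <- function(value, param, lower, upper) {
  switch(param,
    gain = , hill = log10(value),
    efficacy = , efficacy_r0 = {
      z <- (value - lower) / (upper - lower)
      z <- pmin(pmax(z, plogis(-LOGIT_CAP)), plogis(LOGIT_CAP))
      qlogis(z)
    },
    value)
}

opt_to_theta <- function(t, param, lower, upper) {
  switch(param,
    gain = , hill = 10^t,
    efficacy = , efficacy_r0 = lower + (upper - lower) * plogis(t),
    t)
}

opt_bounds <- function(param, lower, upper) {
  switch(param,
    gain = , hill = c(log10(lower), log10(upper)),
    efficacy = , efficacy_r0 = c(-LOGIT_CAP, LOGIT_CAP),
    c(lower, upper))
}

# derivative d(natural)/d(opt), for delta-method standard errors
dtheta_dopt <- function(t, param, lower, upper) {
  switch(param,
    gain = , hill = LN10 * 10^t,
    efficacy = , efficacy_r0 = (upper - lower) * plogis(t) * (1 - plogis(t)),
    1)
}

# integer transform code used by the optimizer hot path:
# 1 identity, 2 log10, 3 scaled logit
transform_code <- function(param) {
  switch(param, gain = , hill = 2L, efficacy = , efficacy_r0 = 3L, 1L)
}
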
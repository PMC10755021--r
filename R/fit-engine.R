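# Shared least-squares machinery: box-constrained quasi-Newton (PORT /
# nlminb) on transformed parameters, deterministic Latin-hypercube
# multistart, and Jacobian-based standard errors mapped back to the natural
# scale by the delta method.

FIT_CONTROL <- list(rel.tol = 1e-12, x.tol = 1.5e-10,
                    eval.max = 10000, iter.max = 5000)

# Latin hypercube of m points in [0,1]^k (deterministic under the caller's
# seed), mapped into [lower, upper] boxes on the optimizer scale.
lhs_starts <- function(m, lower, upper) {
  k <- length(lower)
  u <- matrix(0, m, k)
  for (j in seq_len(k)) u[, j] <- (sample.int(m) - runif(m)) / m
  lo <- pmax(lower, -25); hi <- pmin(upper, 25)
  u * matrix(hi - lo, m, k, byrow = TRUE) + matrix(lo, m, k, byrow = TRUE)
}

# resid_fn(theta_opt) -> numeric residual vector.
# Returns the best local optimum over `multistart` starts (first start is
# the caller-provided heuristic start).
ls_multistart <- function(resid_fn, start_opt, lower, upper,
                          multistart = 8, seed = 42) {
  obj <- function(t) {
    r <- resid_fn(t)
    if (any(!is.finite(r))) return(1e12)
    sum(r * r)
  }
  starts <- with_seed(seed, {
    s <- matrix(start_opt, nrow = 1)
    if (multistart > 1) {
      s <- rbind(s, lhs_starts(multistart - 1, lower, upper))
    }
    s
  })
  conv_ok <- function(fit) {
    fit$convergence == 0 ||
      grepl("relative convergence|X-convergence|absolute function convergence",
            fit$message %||% "")
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(starts[i, ], obj, lower = lower, upper = upper,
             control = FIT_CONTROL),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  converged <- conv_ok(best)
  # polish from the winner (restart clears the PORT memory)
  polish <- tryCatch(
    nlminb(best$par, obj, lower = lower, upper = upper, control = FIT_CONTROL),
    error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= best$objective) {
    converged <- converged || conv_ok(polish)
    best <- polish
  }
  best$converged <- converged
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central-difference Jacobian of the residual vector
num_jacobian <- function(resid_fn, theta) {
  r0 <- resid_fn(theta)
  k <- length(theta)
  J <- matrix(NA_real_, length(r0), k)
  for (j in seq_len(k)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  J
}

# standard errors on the optimizer scale; pseudo-inverse fallback for
# rank-deficient J'J (e.g. parameters at bounds)
se_from_jacobian <- function(J, sse, n_obs, n_par) {
  dof <- n_obs - n_par
  if (dof <= 0) return(rep(NA_real_, n_par))
  sigma2 <- sse / dof
  JtJ <- crossprod(J)
  cov_t <- tryCatch(sigma2 * chol2inv(chol(JtJ)), error = function(e) {
    s <- svd(JtJ)
    pos <- s$d > max(s$d) * 1e-12
    d_inv <- ifelse(pos, 1 / s$d, 0)
    sigma2 * s$v %*% (d_inv * t(s$u))
  })
  sqrt(pmax(diag(cov_t), 0))
}

#' Fit quality metrics
#'
#' Returns the sum of squared errors and the corrected Akaike Information
#' Criterion in the least-squares (Gaussian) form,
#' \deqn{AICc = n \ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)}
#' where k counts only the mean-model parameters (not the residual
#' variance), matching common curve-fitting software.
#'
#' @param result a `sabre_fit` object from [fit_sabre_global()] or
#'   [fit_hill_per_curve()].
#' @return Named list with `sse` and `aicc`.
#' @export
model_metrics <- function(result) {
  stopifnot(inherits(result, "sabre_fit"))
  list(sse = result$sse,
       aicc = aicc_ls(result$sse, result$n_obs, result$n_params))
}

aicc_ls <- function(sse, n_obs, k) {
  if (sse <= 0) {
    stop("AICc undefined: SSE is zero (degenerate perfect fit)", call. = FALSE)
  }
  if (n_obs - k - 1 <= 0) {
    stop(sprintf(
      "AICc undefined: correction term requires n_obs - k - 1 > 0 (n_obs = %d, k = %d)",
      n_obs, k), call. = FALSE)
  }
  n_obs * log(sse / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Compare two fits of the same panel
#'
#' @param a,b `sabre_fit` objects fitted to the same observations on the
#'   same response scale.
#' @return List with per-model SSE/AICc, `delta_sse` and `delta_aicc`
#'   (b minus a), Akaike weights, and the preferred model (lower AICc).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "sabre_fit"), inherits(b, "sabre_fit"))
  if (a$n_obs != b$n_obs || !identical(a$fingerprint, b$fingerprint)) {
    stop("cannot compare fits of different observation sets", call. = FALSE)
  }
  aicc_a <- aicc_ls(a$sse, a$n_obs, a$n_params)
  aicc_b <- aicc_ls(b$sse, b$n_obs, b$n_params)
  d <- c(aicc_a, aicc_b) - min(aicc_a, aicc_b)
  w <- exp(-0.5 * d) / sum(exp(-0.5 * d))
  list(model_a = a$model, model_b = b$model,
       sse_a = a$sse, sse_b = b$sse, delta_sse = b$sse - a$sse,
       aicc_a = aicc_a, aicc_b = aicc_b, delta_aicc = aicc_b - aicc_a,
       akaike_weights = setNames(w, c("a", "b")),
       preferred = if (aicc_b < aicc_a) "b" else if (aicc_a < aicc_b) "a" else "tie")
}

new_sabre_fit <- function(model, estimates, residuals, sse, n_params, n_obs,
                          converged, seed, fingerprint, extra = list()) {
  aicc <- tryCatch(aicc_ls(sse, n_obs, n_params), error = function(e) NA_real_)
  structure(c(list(model = model, estimates = estimates,
                   residuals = residuals, sse = sse, aicc = aicc,
                   n_params = n_params, n_obs = n_obs,
                   converged = converged, seed = seed,
                   fingerprint = fingerprint), extra),
            class = "sabre_fit")
}

#' @export
print.sabre_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d observations, %d adjustable parameters\n",
              x$model, x$n_obs, x$n_params))
  cat(sprintf("SSE = %.6g, AICc = %s, converged = %s\n", x$sse,
              if (is.na(x$aicc)) "NA" else sprintf("%.4g", x$aicc),
              x$converged))
  if (isTRUE(x$scale_indeterminate)) {
    cat("note: scale-indeterminate (no fixed Kd with free gain);",
        "only efficacy*gain products and kappa shifts are reliable\n")
  }
  print(x$estimates, digits = 4, row.names = FALSE)
  invisible(x)
}
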
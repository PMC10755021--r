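# File I/O: tidy panel CSV dialect (percent responses on disk, fractions in
# memory) and the plain-text constraint configuration format.

PANEL_HEADER <- "# sabrefit panel v1: ligand,pathway,log_conc_M,response_pct[,weight]"

#' Read / write tidy concentration-response panels
#'
#' The on-disk dialect is a long-format CSV with one row per observation
#' and columns `ligand`, `pathway`, `log_conc_M` (log10 molar) and
#' `response_pct` (percent of assay Emax), plus an optional `weight`
#' column; lines starting with `#` are comments.  In memory the response is
#' a fraction.  `conc_units` of `"M"` or `"nM"` converts a linear
#' concentration column at the boundary; the default `"log10M"` takes the
#' column as already logarithmic.  Written files round-trip losslessly at
#' 12 significant digits.
#'
#' @param path file path.
#' @param conc_units `"log10M"` (default), `"M"` or `"nM"`.
#' @return `read_panel`: a `response_panel`; `write_panel`: `path`,
#'   invisibly.
#' @export
read_panel <- function(path, conc_units = c("log10M", "M", "nM")) {
  conc_units <- match.arg(conc_units)
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path),
                               call. = FALSE)
  df <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  need <- c("ligand", "pathway", "log_conc_M", "response_pct")
  if (conc_units != "log10M") need[3] <- "conc"
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s (expected schema: %s)",
                 path, paste(missing_cols, collapse = ", "),
                 paste(need, collapse = ",")), call. = FALSE)
  }
  if (!is.numeric(df$response_pct)) {
    stop(sprintf("%s: column response_pct is not numeric", path), call. = FALSE)
  }
  log_conc <- switch(conc_units,
    log10M = df$log_conc_M,
    M = log10(df$conc),
    nM = log10(df$conc * 1e-9))
  out <- data.frame(ligand = df$ligand, pathway = df$pathway,
                    log_conc = log_conc,
                    response = df$response_pct / 100,
                    stringsAsFactors = FALSE)
  if (!is.null(df$weight)) out$weight <- df$weight
  as_response_panel(out)
}

#' @rdname read_panel
#' @param panel a `response_panel` (or coercible data.frame).
#' @param overwrite logical; refuse to clobber an existing file unless TRUE.
#' @export
write_panel <- function(panel, path, overwrite = FALSE) {
  panel <- as_response_panel(panel)
  if (file.exists(path) && !overwrite) {
    stop(sprintf("%s exists; pass overwrite = TRUE to replace it", path),
         call. = FALSE)
  }
  df <- data.frame(ligand = panel$ligand, pathway = panel$pathway,
                   log_conc_M = format(panel$log_conc, digits = 12,
                                       trim = TRUE, scientific = FALSE),
                   response_pct = format(panel$response * 100, digits = 12,
                                         trim = TRUE, scientific = FALSE),
                   stringsAsFactors = FALSE)
  if (!is.null(panel$weight)) {
    df$weight <- format(panel$weight, digits = 12, trim = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(PANEL_HEADER, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a constraint configuration file
#'
#' Plain-text, one parameter per line, `parameter: rule`:
#' \preformatted{
#' # sabrefit constraints v1
#' log_kd: fixed CpdTst1=-7.0 CpdTst2=-6.5 CpdTst3=-8.0
#' efficacy: shared per-ligand
#' gain: shared per-pathway
#' efficacy_r0: fixed 0
#' hill: fixed 1
#' }
#' Rules: `fixed <value>` or `fixed name=value ...`; `shared
#' global|per-ligand|per-pathway|per-curve`; `free`.  Omitted parameters
#' take the [sabre_constraints()] defaults.
#'
#' @param path file path.
#' @return A `sabre_constraints` object.
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("constraints file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    m <- regexec("^([a-z_0-9]+)\\s*:\\s*(.+)$", ln)[[1]]
    if (m[1] == -1) {
      stop(sprintf("%s line %d: expected 'parameter: rule', got '%s'",
                   path, i, lines[i]), call. = FALSE)
    }
    key <- regmatches(ln, regexec("^([a-z_0-9]+)\\s*:\\s*(.+)$", ln))[[1]]
    param <- key[2]
    if (!param %in% PARAM_NAMES) {
      stop(sprintf("%s line %d: unknown parameter '%s' (expected one of %s)",
                   path, i, param, paste(PARAM_NAMES, collapse = ", ")),
           call. = FALSE)
    }
    rules[[param]] <- parse_rule(key[3], path, i)
  }
  do.call(sabre_constraints, rules)
}

parse_rule <- function(text, path = "<string>", line = NA) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  err <- function(msg) stop(sprintf("%s line %s: %s", path, line, msg),
                            call. = FALSE)
  if (!length(toks)) err("empty rule")
  kind <- toks[1]
  if (kind == "fixed") {
    vals <- toks[-1]
    if (!length(vals)) err("'fixed' needs a value")
    if (all(grepl("=", vals))) {
      parts <- strsplit(vals, "=", fixed = TRUE)
      v <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])),
                  numeric(1))
      names(v) <- vapply(parts, `[[`, character(1), 1)
    } else {
      v <- suppressWarnings(as.numeric(vals))
      if (length(v) != 1) err("'fixed' takes one value or name=value pairs")
    }
    if (anyNA(v)) err("non-numeric fixed value")
    par_fixed(v)
  } else if (kind == "shared") {
    if (length(toks) < 2) err("'shared' needs a group key")
    par_shared(toks[2])
  } else if (kind == "free") {
    par_free()
  } else {
    err(sprintf("unknown rule '%s' (expected fixed/shared/free)", kind))
  }
}

# write fit artifacts: parameters.csv, residuals.csv, metrics.json
write_fit_artifacts <- function(fit, dir, overwrite = FALSE) {
  paths <- file.path(dir, c("parameters.csv", "residuals.csv", "metrics.json"))
  if (!overwrite && any(file.exists(paths))) {
    stop(sprintf("fit artifacts already exist in %s; pass overwrite", dir),
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(fit$estimates, paths[1], row.names = FALSE)
  write.csv(fit$residuals, paths[2], row.names = FALSE)
  meta <- list(model = fit$model, sse = fit$sse, aicc = fit$aicc,
               n_params = fit$n_params, n_obs = fit$n_obs,
               converged = fit$converged, seed = fit$seed,
               scale_indeterminate = isTRUE(fit$scale_indeterminate),
               fingerprint = fit$fingerprint,
               package_version = as.character(utils::packageVersion("sabrefit")))
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(fit$param_matrix)) {
    write.csv(fit$param_matrix, file.path(dir, "param_matrix.csv"),
              row.names = FALSE)
  }
  if (!is.null(fit$curve_table)) {
    write.csv(fit$curve_table, file.path(dir, "curve_table.csv"),
              row.names = FALSE)
  }
  invisible(paths)
}
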
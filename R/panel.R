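# Tidy concentration-response panels: one row per observation, columns
# ligand / pathway / log_conc / response (fraction scale).  This mirrors the
# on-disk CSV dialect (where response is in percent) and is the common
# currency of the fitting, bias and synthetic modules.

#' Construct / validate a tidy concentration-response panel
#'
#' A panel is a data.frame with columns `ligand`, `pathway`, `log_conc`
#' (log10 molar) and `response` (fraction of the assay Emax), plus an
#' optional `weight` column.  Responses may slightly over/undershoot the
#' \[0, 1\] range from noise; the accepted band is \[-0.05, 1.10\].
#'
#' @param x a data.frame with the columns above.
#' @return The validated panel, classed `response_panel`.
#' @export
as_response_panel <- function(x) {
  if (!is.data.frame(x)) stop_bad_arg("x", "must be a data.frame")
  need <- c("ligand", "pathway", "log_conc", "response")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop(sprintf("panel is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x$ligand <- as.character(x$ligand)
  x$pathway <- as.character(x$pathway)
  check_num(x$log_conc, "log_conc")
  check_num(x$response, "response", lower = -0.05, upper = 1.10)
  if (!is.null(x$weight)) check_num(x$weight, "weight", lower = 0)
  class(x) <- unique(c("response_panel", class(x)))
  x
}

# unique (ligand, pathway) combinations, in order of first appearance
panel_curves <- function(panel) {
  key <- paste(panel$ligand, panel$pathway, sep = "\r")
  idx <- !duplicated(key)
  data.frame(ligand = panel$ligand[idx], pathway = panel$pathway[idx],
             stringsAsFactors = FALSE)
}

# integer curve id per panel row, matching panel_curves() row order
panel_curve_id <- function(panel, curves = panel_curves(panel)) {
  match(paste(panel$ligand, panel$pathway, sep = "\r"),
        paste(curves$ligand, curves$pathway, sep = "\r"))
}

# order-insensitive fingerprint of the observation set, used by
# compare_models() to reject comparisons across different data
panel_fingerprint <- function(panel) {
  o <- order(panel$ligand, panel$pathway, panel$log_conc, panel$response)
  paste(nrow(panel),
        format(sum(panel$response), digits = 15),
        format(sum(panel$log_conc[is.finite(panel$log_conc)]), digits = 15),
        paste(range(round(panel$response[o], 10))[1:2], collapse = ","),
        sep = "|")
}
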
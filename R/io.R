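## Stable file contracts: long-format UTF-8 CSV tables with full floating
## point precision, YAML configuration, JSON fit summaries.

fmt_num <- function(x) {
  if (is.double(x)) vapply(x, function(v) sprintf("%.17g", v), "") else x
}

write_table_exact <- function(df, path) {
  out <- df
  for (nm in names(out)) out[[nm]] <- fmt_num(out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' Writes `detections.csv` (species, cell, plot, y, area in m^2),
#' `cells.csv` (cell, A in km^2, x1, x2, ecoregion), `aux.csv` (species,
#' cell, z, source), the latent truth as sidecar CSVs (`truth_z.csv`,
#' `truth_d.csv` in long format), and the configuration as `config.yaml`.
#' Numeric columns are written with 17 significant digits so a write-read
#' round trip preserves doubles exactly.
#'
#' @param data A `"macroabund_data"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_exact(data$detections, file.path(dir, "detections.csv"))
  write_table_exact(data$cells, file.path(dir, "cells.csv"))
  write_table_exact(data$aux, file.path(dir, "aux.csv"))
  if (!is.null(data$truth)) {
    I <- nrow(data$truth$z); J <- ncol(data$truth$z)
    long <- data.frame(species = rep(seq_len(I), J),
                       cell = rep(seq_len(J), each = I),
                       z = as.integer(data$truth$z),
                       d = as.numeric(data$truth$d),
                       psi = as.numeric(data$truth$psi),
                       N = as.numeric(data$truth$N))
    write_table_exact(long, file.path(dir, "truth.csv"))
  }
  if (!is.null(data$config)) {
    cfg <- data$config
    cfg$true_params <- unclass(cfg$true_params)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A list with `detections`, `cells`, `aux` (and `truth` when
#'   present), usable by [fit_abundance()].
#' @export
read_dataset <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  out <- list(detections = rd("detections.csv"), cells = rd("cells.csv"),
              aux = rd("aux.csv"))
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) out$truth_long <- rd("truth.csv")
  out
}

#' Serialize a fitted model
#'
#' Writes `params.json` (estimates, SEs, convergence) and CSV tables of the
#' predicted random effects and per-(species, cell) predictions.
#'
#' @param fit A `"macroabund_fit"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(model = fit$model,
                            params = unclass(fit$params),
                            loglik = fit$loglik,
                            convergence = fit$convergence,
                            grad_norm = fit$grad_norm,
                            se = fit$se),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  eff <- data.frame(species = fit$species, e1 = fit$effects$e1,
                    u1 = fit$effects$u1)
  write_table_exact(eff, file.path(dir, "effects_species.csv"))
  effc <- data.frame(cell = fit$cells$cell, e2 = fit$effects$e2,
                     u2 = fit$effects$u2)
  write_table_exact(effc, file.path(dir, "effects_cells.csv"))
  I <- nrow(fit$d_hat); J <- ncol(fit$d_hat)
  pred <- data.frame(species = rep(fit$species, J),
                     cell = rep(fit$cells$cell, each = I),
                     d_hat = as.numeric(fit$d_hat),
                     psi_hat = if (is.null(fit$psi_hat)) NA
                               else as.numeric(fit$psi_hat))
  write_table_exact(pred, file.path(dir, "predictions.csv"))
  invisible(dir)
}
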
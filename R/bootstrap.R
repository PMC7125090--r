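## Parametric bootstrap standard errors for the derived estimators.

#' Parametric bootstrap of the derived ecological estimators
#'
#' For each replicate, new random effects, presence states and detections
#' are simulated from the fitted parameters (auxiliary occurrence data held
#' fixed, and the presence state pinned wherever it is known), the model is
#' refitted starting from the original estimates, and the derived quantities
#' are recomputed. Standard errors are the standard deviations over the
#' successful replicates.
#'
#' @param fit A converged integrated-model fit.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed (the replicate stream is deterministic given it).
#' @param se Compute fixed-effect SEs in the refits (off by default: the
#'   bootstrap only needs point estimates)?
#' @return Object of class `"macroabund_boot"`: per-quantity standard errors
#'   (`richness`, `abundance`, `aoo`, `total_abundance`, `entropy`), the
#'   replicate draws, and the failure count. A warning is issued when fewer
#'   than 80 percent of refits succeed.
#' @export
parametric_bootstrap <- function(fit, B = 100, seed = 1, se = FALSE) {
  stopifnot(inherits(fit, "macroabund_fit"), B >= 1)
  if (fit$model != "integrated")
    stop("the bootstrap of the derived estimators needs an integrated fit")
  sims <- simulate(fit, nsim = B, seed = seed)
  start <- list(mu = fit$params$mu, beta = fit$params$beta,
                eta = fit$params$eta, gamma = fit$params$gamma,
                log_sigma = log(pmax(fit$params$sigma, 1e-4)),
                log_tau = log(pmax(fit$params$tau, 1e-4)),
                rho_t = atanh(fit$params$rho))
  rich <- ab <- ao <- tot <- ent <- vector("list", B)
  fails <- 0L
  for (b in seq_len(B)) {
    rb <- tryCatch({
      fb <- fit_abundance(sims[[b]], model = "integrated",
                          covariates = fit$covariates, start = start,
                          se = se)
      list(rich = estimate_richness(fb),
           ab = estimate_abundance(fb),
           ao = estimate_aoo(fb),
           ent = cell_estimates(fb)$entropy)
    }, error = function(e) NULL)
    if (is.null(rb)) { fails <- fails + 1L; next }
    rich[[b]] <- rb$rich; ab[[b]] <- rb$ab; ao[[b]] <- rb$ao
    tot[[b]] <- sum(rb$ab); ent[[b]] <- rb$ent
  }
  ok <- !vapply(rich, is.null, TRUE)
  if (sum(ok) < 0.8 * B)
    warning(sprintf("only %d of %d bootstrap refits succeeded; SEs use the successful ones",
                    sum(ok), B))
  if (!any(ok)) stop("all bootstrap refits failed")
  sdcol <- function(lst) apply(do.call(rbind, lst[ok]), 2, sd)
  out <- list(B = B, n_ok = sum(ok), n_fail = fails, seed = seed,
              se = list(richness = sdcol(rich),
                        abundance = sdcol(ab),
                        aoo = sdcol(ao),
                        total_abundance = sd(unlist(tot[ok])),
                        entropy = sdcol(ent)),
              replicates = list(total_abundance = unlist(tot[ok])))
  class(out) <- "macroabund_boot"
  out
}

#' @export
print.macroabund_boot <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %d/%d replicates succeeded (seed %d)\n",
              x$n_ok, x$B, x$seed))
  cat(sprintf("  SE(total abundance) = %.4g\n", x$se$total_abundance))
  cat(sprintf("  median SE(richness per cell) = %.4g\n",
              median(x$se$richness)))
  invisible(x)
}
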
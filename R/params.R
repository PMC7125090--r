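#' Model parameters of the occupancy-abundance model
#'
#' Container for the fixed effects and variance components of the integrated
#' hierarchical model. Densities are per km^2 of habitat; plot areas enter the
#' observation model in m^2 and are converted internally.
#'
#' @param mu Intercept of the log conditional density (log individuals per
#'   km^2 habitat).
#' @param beta Length-3 numeric: coefficients of the two standardized cell
#'   covariates and their interaction on log density.
#' @param eta Intercept of the occupancy logit.
#' @param gamma Length-3 numeric: covariate coefficients on the occupancy
#'   logit.
#' @param sigma Length-3 non-negative numeric: standard deviations of the
#'   species, cell, and species-by-cell random effects on log density.
#' @param tau Length-2 non-negative numeric: standard deviations of the
#'   species and cell random effects on the occupancy logit.
#' @param rho Correlation in (-1, 1) between the cell-level density and
#'   occupancy random effects.
#' @return An object of class `"macroabund_params"` (a validated list).
#' @examples
#' model_params(mu = 8, sigma = c(1.5, 0.5, 0.5))
#' @export
model_params <- function(mu = 8, beta = c(0.5, -0.3, 0.1),
                         eta = 0, gamma = c(1, -0.5, 0.2),
                         sigma = c(1.5, 0.5, 0.5), tau = c(1.5, 1),
                         rho = 0.5) {
  p <- list(mu = as.numeric(mu), beta = as.numeric(beta),
            eta = as.numeric(eta), gamma = as.numeric(gamma),
            sigma = as.numeric(sigma), tau = as.numeric(tau),
            rho = as.numeric(rho))
  validate_params(p)
  class(p) <- "macroabund_params"
  p
}

validate_params <- function(p) {
  stopifnot(length(p$mu) == 1, length(p$eta) == 1,
            length(p$beta) == 3, length(p$gamma) == 3,
            length(p$sigma) == 3, length(p$tau) == 2, length(p$rho) == 1)
  vals <- unlist(p)
  if (any(!is.finite(vals)))
    stop("model parameters must all be finite")
  if (any(p$sigma < 0) || any(p$tau < 0))
    stop("random-effect standard deviations must be >= 0")
  if (abs(p$rho) >= 1)
    stop("rho must lie strictly inside (-1, 1)")
  invisible(p)
}

#' @export
print.macroabund_params <- function(x, ...) {
  cat("Occupancy-abundance model parameters\n")
  cat(sprintf("  density:   mu = %.4g, beta = (%s)\n", x$mu,
              paste(signif(x$beta, 4), collapse = ", ")))
  cat(sprintf("  occupancy: eta = %.4g, gamma = (%s)\n", x$eta,
              paste(signif(x$gamma, 4), collapse = ", ")))
  cat(sprintf("  sigma = (%s), tau = (%s), rho = %.3f\n",
              paste(signif(x$sigma, 4), collapse = ", "),
              paste(signif(x$tau, 4), collapse = ", "), x$rho))
  invisible(x)
}
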
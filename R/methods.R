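## S3 methods for fitted occupancy-abundance models.

#' @export
print.macroabund_fit <- function(x, ...) {
  cat(sprintf("Hierarchical occupancy-abundance model (%s)\n", x$model))
  cat(sprintf("  %d species x %d cells, %d plot records (%d detections)\n",
              length(x$species), nrow(x$cells), nrow(x$detections),
              sum(x$detections$y)))
  cat(sprintf("  marginal logLik = %.3f (%s, |grad| = %.2g)\n",
              x$loglik, x$convergence, x$grad_norm))
  print(x$params)
  invisible(x)
}

#' @export
coef.macroabund_fit <- function(object, ...) {
  p <- object$params
  cf <- c(mu = p$mu, beta1 = p$beta[1], beta2 = p$beta[2], beta3 = p$beta[3])
  if (object$model == "integrated")
    cf <- c(cf, eta = p$eta, gamma1 = p$gamma[1], gamma2 = p$gamma[2],
            gamma3 = p$gamma[3])
  c(cf, sigma1 = p$sigma[1], sigma2 = p$sigma[2], sigma3 = p$sigma[3],
    if (object$model == "integrated")
      c(tau1 = p$tau[1], tau2 = p$tau[2], rho = p$rho))
}

#' @export
logLik.macroabund_fit <- function(object, ...) {
  df <- length(object$opt_par)
  structure(object$loglik, df = df, class = "logLik")
}

#' @export
vcov.macroabund_fit <- function(object, ...) {
  if (is.null(object$se)) stop("fit was run with se = FALSE")
  ## delta-method SEs only; full covariance not retained
  diag(object$se$se^2, nrow = nrow(object$se))
}

#' @export
summary.macroabund_fit <- function(object, ...) {
  out <- list(model = object$model, loglik = object$loglik,
              convergence = object$convergence, se = object$se,
              params = object$params,
              n_species = length(object$species), n_cells = nrow(object$cells),
              n_plots = nrow(object$detections))
  class(out) <- "summary.macroabund_fit"
  out
}

#' @export
print.summary.macroabund_fit <- function(x, ...) {
  cat(sprintf("Hierarchical occupancy-abundance model (%s)\n", x$model))
  cat(sprintf("  marginal logLik = %.3f (%s)\n", x$loglik, x$convergence))
  if (!is.null(x$se)) {
    tab <- x$se
    tab$z <- tab$estimate / tab$se
    print(format(tab, digits = 4), row.names = FALSE)
  } else print(x$params)
  invisible(x)
}

#' Predictions from a fitted occupancy-abundance model
#'
#' @param object A `"macroabund_fit"`.
#' @param newdata Data frame with columns `species`, `cell` and (for
#'   `type = "detection"`) `area` in m^2. Defaults to the training plots.
#' @param type `"detection"` returns the unconditional probability of
#'   detecting the species in the plot, combining the detection probability
#'   given presence with the (known or estimated) occupancy state;
#'   `"density"` the conditional density per km^2; `"occupancy"` the model
#'   occurrence probability.
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.macroabund_fit <- function(object, newdata = NULL,
                                   type = c("detection", "density", "occupancy"),
                                   ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$detections
  si <- match(newdata$species, object$species)
  ci <- match(newdata$cell, object$cells$cell)
  if (any(is.na(si))) stop("newdata contains species unknown to the fit")
  if (any(is.na(ci))) stop("newdata contains cells unknown to the fit")
  idx <- cbind(si, ci)
  d <- object$d_hat[idx]
  if (type == "density") return(d)
  if (object$model == "integrated") {
    psi <- object$psi_hat[idx]
    w <- ifelse(object$m[idx] == 1, object$z_known[idx], psi)
  } else {
    psi <- rep(1, nrow(newdata))
    w <- psi
  }
  if (type == "occupancy") return(psi)
  if (is.null(newdata$area)) stop("type = 'detection' needs plot areas")
  w * detection_prob(d, newdata$area * AREA_M2_TO_KM2)
}

#' @export
fitted.macroabund_fit <- function(object, ...) {
  predict(object, type = "detection")
}

#' @export
residuals.macroabund_fit <- function(object, type = c("pearson", "response"),
                                     ...) {
  type <- match.arg(type)
  p <- fitted(object)
  r <- object$detections$y - p
  if (type == "pearson") r <- r / sqrt(pmax(p * (1 - p), 1e-12))
  r
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new random effects, latent presence states and detections from the
#' fitted parameters. The auxiliary occurrence data are held fixed: where the
#' presence state is known (through auxiliary sources or a detection-derived
#' presence) the simulated state is pinned to the known value, mirroring the
#' parametric bootstrap for hierarchical models with partially observed
#' occupancy.
#'
#' @param object A `"macroabund_fit"`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` datasets (same shape as the training data, with
#'   `truth` attached).
#' @export
simulate.macroabund_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  I <- length(object$species); J <- nrow(object$cells)
  det <- object$detections
  idx <- cbind(det$si, det$ci)
  out <- vector("list", nsim)
  for (b in seq_len(nsim)) {
    e1 <- rnorm(I, 0, p$sigma[1]); u1 <- rnorm(I, 0, p$tau[1])
    z1 <- rnorm(J); z2 <- rnorm(J)
    e2 <- p$sigma[2] * z1
    u2 <- p$tau[2] * (p$rho * z1 + sqrt(1 - p$rho^2) * z2)
    e3 <- matrix(rnorm(I * J, 0, p$sigma[3]), I, J)
    eff <- list(e1 = e1, u1 = u1, e2 = e2, u2 = u2, e3 = e3)
    lp <- linear_predictors(p, eff, object$cells)
    d <- exp(lp$log_d)
    if (object$model == "integrated") {
      psi <- plogis(lp$logit_psi)
      z <- matrix(rbinom(I * J, 1, psi), I, J)
      z[object$m == 1] <- object$z_known[object$m == 1]
    } else {
      psi <- matrix(1, I, J)
      z <- matrix(1L, I, J)
    }
    pr <- z[idx] * detection_prob(d[idx], det$area * AREA_M2_TO_KM2)
    nd <- det[, c("species", "cell", "plot", "y", "area")]
    nd$y <- rbinom(nrow(nd), 1, pr)
    out[[b]] <- list(detections = nd, cells = object$cells, aux = object$aux,
                     truth = list(z = z, d = d, psi = psi, effects = eff,
                                  N = d * matrix(object$cells$A, I, J,
                                                 byrow = TRUE) * z))
  }
  out
}

#' Calibration plot of a fitted model
#'
#' Bins the fitted plot-level detection probabilities into deciles and plots
#' the observed detection frequency per bin against the mean prediction.
#'
#' @param x A `"macroabund_fit"`.
#' @param y Unused.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.macroabund_fit <- function(x, y, ...) {
  p <- fitted(x)
  br <- unique(quantile(p, 0:10 / 10))
  bin <- cut(p, br, include.lowest = TRUE)
  obs <- tapply(x$detections$y, bin, mean)
  pred <- tapply(p, bin, mean)
  graphics::plot(pred, obs, xlab = "mean predicted detection probability",
                 ylab = "observed detection frequency",
                 xlim = 0:1, ylim = 0:1, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
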
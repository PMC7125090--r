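## Fitting the neutral metacommunity models to SADs, composite-likelihood
## AIC comparison, and conversion of fitted parameters into speciation rates
## and average species lifetimes.

new_neutral_fit <- function(model, sad, theta = NA, beta = NA, meanlog = NA,
                            sdlog = NA, cloglik = NA, k, convergence = "converged",
                            boundary = FALSE) {
  J <- sad$J_M
  nu <- mu <- tau <- L <- NA_real_
  if (model %in% c("PMS", "RFS", "PS") && is.finite(theta)) {
    if (model == "PS") {
      pr <- ps_rates(theta, J, beta = beta)
      nu <- pr$nu; mu <- pr$mu; tau <- pr$tau
      L <- species_lifetime("PS", nu, tau_ps = tau, mu_ps = mu)
    } else {
      nu <- speciation_rate(model, theta, J)
      L <- species_lifetime(model, nu)
    }
  }
  out <- list(model = model, theta = theta, beta = beta,
              meanlog = meanlog, sdlog = sdlog,
              nu = nu, mu_ps = mu, tau_ps = tau, L = L,
              cloglik = cloglik, k = as.integer(k), aic = -2 * cloglik + 2 * k,
              J_M = J, S = sad$S,
              convergence = convergence, boundary = boundary)
  class(out) <- "neutral_fit"
  out
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Neutral metacommunity fit [%s]: J_M = %.4g, S = %d\n",
              x$model, x$J_M, x$S))
  if (x$model == "PLN") {
    cat(sprintf("  meanlog = %.4g, sdlog = %.4g\n", x$meanlog, x$sdlog))
  } else {
    cat(sprintf("  theta = %.6g", x$theta))
    if (is.finite(x$beta)) cat(sprintf(", beta = %.6g", x$beta))
    cat(sprintf("\n  nu = %.4g per individual per generation, L = %.4g generations\n",
                x$nu, x$L))
  }
  cat(sprintf("  composite logLik = %.4f, k = %d, AIC = %.2f (%s%s)\n",
              x$cloglik, x$k, x$aic, x$convergence,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' Fit the point-mutation speciation model by maximum likelihood
#'
#' Maximizes the Ewens sampling formula over the fundamental biodiversity
#' number theta (one-dimensional bracketed optimization on the log scale,
#' relative tolerance 1e-6). The maximizer satisfies the expected-richness
#' score equation `S = sum_i theta / (theta + i - 1)`. The reported AIC uses
#' the composite likelihood of the expected SAD so that models fitted by
#' different procedures remain comparable.
#'
#' @param sad A [metacommunity_sad()] or abundance vector.
#' @return A `"neutral_fit"` object.
#' @export
fit_pms <- function(sad) {
  sad <- as_sad(sad)
  if (sad$S == 1) {
    th <- 1e-10
    return(new_neutral_fit("PMS", sad, theta = th,
                           cloglik = pms_cloglik(sad, th), k = 1,
                           convergence = "theta at lower boundary",
                           boundary = TRUE))
  }
  f <- function(lt) ewens_loglik(sad, exp(lt))
  opt <- optimize(f, c(log(1e-8), log(sad$J_M)), maximum = TRUE, tol = 1e-8)
  th <- exp(opt$maximum)
  new_neutral_fit("PMS", sad, theta = th, cloglik = pms_cloglik(sad, th), k = 1)
}

pms_cloglik <- function(sad, theta) {
  es <- pm_expected_sad(theta, sad$J_M, sad$n)
  composite_loglik(sad, es, ewens_expected_richness(theta, sad$J_M))
}

#' Fit the random-fission speciation model
#'
#' Maximizes the random-fission equilibrium probability
#' ([rf_equilibrium_logprob()]) over theta. For large metacommunities the
#' estimate is close to the observed species count. AIC uses the composite
#' likelihood of [rf_expected_sad()].
#'
#' @inheritParams fit_pms
#' @return A `"neutral_fit"` object.
#' @export
fit_rfs <- function(sad) {
  sad <- as_sad(sad)
  f <- function(lt) rf_equilibrium_logprob(sad, exp(lt))
  lo <- log(max(sad$S / 30, 1e-4))
  hi <- log(min(30 * sad$S + 10, sad$J_M))
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  th <- exp(opt$maximum)
  conv <- "converged"
  if (min(abs(opt$maximum - c(lo, hi))) < 1e-4) conv <- "theta at search boundary"
  es <- rf_expected_sad(th, sad$J_M, sad$n)
  w <- rf_count_weights(th, sad$J_M)
  etot <- sum(exp(w$logw) * w$S)
  cl <- composite_loglik(sad, es, etot)
  new_neutral_fit("RFS", sad, theta = th, cloglik = cl, k = 1,
                  convergence = conv, boundary = conv != "converged")
}

#' Fit the protracted speciation model by least squares on Preston octaves
#'
#' Minimizes the sum of squared differences between observed and expected
#' species counts per octave over `(theta, beta)` with multiple starting
#' values (octaves weighted equally). The composite likelihood of the fitted
#' expected SAD is then evaluated for AIC comparison, treating the
#' least-squares solution as attaining the maximum.
#'
#' @inheritParams fit_pms
#' @param octaves Optional vector of observed octave counts overriding those
#'   of `sad` (used in calibration studies fitting synthetic expected
#'   octaves; the composite likelihood is then not evaluated).
#' @return A `"neutral_fit"` object; `boundary` is flagged when the
#'   protraction scale collapses towards the point-mutation limit.
#' @export
fit_ps <- function(sad, octaves = NULL) {
  sad <- as_sad(sad)
  J <- sad$J_M
  synthetic_obs <- !is.null(octaves)
  obs <- if (synthetic_obs) octaves else sad$octaves
  noct <- length(obs)
  ssq <- function(p) {
    th <- exp(p[1]); tau <- exp(p[2])
    if (!is.finite(th) || !is.finite(tau)) return(1e12)
    beta <- (J - 1) / (1 + tau)
    eo <- tryCatch(ps_expected_octaves(th, beta, J, octaves = noct),
                   error = function(e) NULL)
    if (is.null(eo) || any(!is.finite(eo))) return(1e12)
    sum((eo - obs)^2)
  }
  th0 <- fit_pms(sad)$theta
  q <- unname(quantile(sad$n, 0.1))
  ## the protraction scale roughly marks the lower edge of the octave support
  jlo <- which(obs > 0.05 * max(obs))[1]
  starts <- expand.grid(lt = log(c(th0, 2 * th0, sad$S)),
                        ltau = log(pmax(c(q / 4, q, 2^(jlo - 1)), 1e-3)))
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    o <- optim(c(starts$lt[r], starts$ltau[r]), ssq,
               control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- exp(best$par[1]); tau <- exp(best$par[2])
  beta <- (J - 1) / (1 + tau)
  cl <- NA_real_
  if (!synthetic_obs) {
    es <- ps_expected_sad(th, beta, J, sad$n)
    pp <- ps_pars(th, beta, J)
    etot <- th * (log1p(-pp$x2) - log1p(-pp$x1))
    cl <- composite_loglik(sad, es, etot)
  }
  new_neutral_fit("PS", sad, theta = th, beta = beta, cloglik = cl, k = 2,
                  convergence = if (best$convergence == 0) "converged" else "optim did not converge",
                  boundary = tau < 1e-3)
}

#' Fit the Poisson-lognormal baseline
#'
#' Maximum composite-likelihood fit of a zero-truncated Poisson-lognormal
#' abundance distribution (two free parameters).
#'
#' @inheritParams fit_pms
#' @return A `"neutral_fit"` object.
#' @export
fit_pln <- function(sad) {
  sad <- as_sad(sad)
  ln <- log(sad$n)
  s0 <- max(sd(ln), 0.1)
  nll <- function(p) {
    v <- tryCatch(-pln_loglik(sad, p[1], exp(p[2])), error = function(e) 1e12)
    if (!is.finite(v)) 1e12 else v
  }
  o <- optim(c(mean(ln), log(s0)), nll, control = list(maxit = 2000, reltol = 1e-12))
  meanlog <- o$par[1]; sdlog <- exp(o$par[2])
  degenerate <- sdlog < 1e-3
  new_neutral_fit("PLN", sad, meanlog = meanlog, sdlog = sdlog,
                  cloglik = -o$value, k = 2,
                  convergence = if (degenerate) "degenerate (sdlog ~ 0)"
                                else if (o$convergence == 0) "converged"
                                else "optim did not converge",
                  boundary = degenerate)
}

#' Fit and compare the neutral metacommunity models
#'
#' Fits the requested models to a metacommunity SAD and compares them by
#' composite-likelihood AIC and Akaike weights.
#'
#' @param sad SAD or abundance vector.
#' @param models Subset of `c("pms", "rfs", "ps", "pln")`.
#' @return Object of class `"neutral_fit_set"`: list of fits plus a
#'   comparison table.
#' @export
fit_neutral <- function(sad, models = c("pms", "rfs", "ps", "pln")) {
  sad <- as_sad(sad)
  models <- match.arg(models, several.ok = TRUE)
  fits <- lapply(models, function(m)
    switch(m, pms = fit_pms(sad), rfs = fit_rfs(sad),
           ps = fit_ps(sad), pln = fit_pln(sad)))
  names(fits) <- toupper(models)
  aics <- vapply(fits, function(f) f$aic, 0)
  tab <- data.frame(model = names(fits),
                    theta = vapply(fits, function(f) f$theta, 0),
                    beta = vapply(fits, function(f) f$beta, 0),
                    nu = vapply(fits, function(f) f$nu, 0),
                    L = vapply(fits, function(f) f$L, 0),
                    cloglik = vapply(fits, function(f) f$cloglik, 0),
                    k = vapply(fits, function(f) f$k, 0L),
                    AIC = aics,
                    weight = akaike_weights(aics),
                    row.names = NULL)
  out <- list(fits = fits, table = tab, sad = sad)
  class(out) <- "neutral_fit_set"
  out
}

#' @export
print.neutral_fit_set <- function(x, digits = 4, ...) {
  cat(sprintf("Neutral model comparison: S = %d, J_M = %.4g\n", x$sad$S, x$sad$J_M))
  tab <- x$table
  tab$weight <- round(tab$weight, 3)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
AIC.neutral_fit <- function(object, ..., k = 2) {
  -2 * object$cloglik + k * object$k
}

#' @export
logLik.neutral_fit <- function(object, ...) {
  structure(object$cloglik, df = object$k, class = "logLik")
}

#' Plot observed octaves against fitted expected SADs
#'
#' @param x A `"neutral_fit_set"`.
#' @param y Unused.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.neutral_fit_set <- function(x, y, ...) {
  obs <- x$sad$octaves
  noct <- length(obs)
  mid <- graphics::barplot(obs, names.arg = seq_len(noct),
                           xlab = "abundance octave", ylab = "species", ...)
  cols <- seq_along(x$fits) + 1
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    eo <- switch(f$model,
      PMS = expected_octaves(function(n) pm_expected_sad(f$theta, f$J_M, n), f$J_M, noct),
      RFS = expected_octaves(function(n) rf_expected_sad(f$theta, f$J_M, n), f$J_M, noct),
      PS = ps_expected_octaves(f$theta, f$beta, f$J_M, noct),
      PLN = {
        etot <- -expm1(pln_log_p0(f$meanlog, f$sdlog))
        x$sad$S * expected_octaves(function(n) exp(pln_log_pmf(n, f$meanlog, f$sdlog)),
                                   f$J_M, noct) / etot
      })
    graphics::lines(mid, eo[seq_len(noct)], col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(x$fits), col = cols, lwd = 2, bty = "n")
  invisible(x)
}

## ---- conversions -------------------------------------------------------

#' Speciation rate implied by a fitted fundamental biodiversity number
#'
#' Inverts the model-specific relation between theta, the metacommunity size
#' and the per-individual per-generation speciation rate nu: point mutation
#' `theta = nu/(1-nu) (J_M - 1)`; random fission `theta = sqrt(nu) J_M`;
#' protracted `theta = mu/(1-mu) (J_M - 1)` with `mu = (1 + tau) nu` and
#' `tau = (J_M - 1)/beta - 1`.
#'
#' @param model One of `"PMS"`, `"RFS"`, `"PS"` (case-insensitive).
#' @param theta Fitted fundamental biodiversity number (> 0).
#' @param J_M Metacommunity size (> 1).
#' @param beta Protracted-model second parameter (required for `"PS"`).
#' @return Speciation rate nu in (0, 1).
#' @examples
#' speciation_rate("PMS", theta = 52.3, J_M = 1.65e10)
#' @export
speciation_rate <- function(model, theta, J_M, beta = NULL) {
  model <- toupper(model)
  stopifnot(theta > 0, J_M > 1)
  nu <- switch(model,
    PMS = theta / (J_M - 1 + theta),
    RFS = (theta / J_M)^2,
    PS = {
      if (is.null(beta)) stop("PS requires beta")
      ps_rates(theta, J_M, beta = beta)$nu
    },
    stop("unknown model: ", model))
  if (nu <= 0 || nu >= 1)
    stop(sprintf("implied speciation rate %g lies outside (0, 1)", nu))
  nu
}

#' Intermediate rates of the protracted speciation model
#'
#' Computes the effective established-species speciation rate
#' `mu = theta/(J_M - 1 + theta)` and the protraction scale tau, from either
#' `beta` (`tau = (J_M - 1)/beta - 1`) or a known speciation rate `nu`
#' (`tau = mu/nu - 1`, from `mu = (1 + tau) nu`).
#'
#' @inheritParams speciation_rate
#' @param nu Speciation rate, as an alternative to `beta`.
#' @return List with `mu`, `tau`, `nu` and `beta`.
#' @export
ps_rates <- function(theta, J_M, beta = NULL, nu = NULL) {
  stopifnot(theta > 0, J_M > 1)
  mu <- theta / (J_M - 1 + theta)
  if (!is.null(beta)) {
    stopifnot(beta > 0)
    tau <- (J_M - 1) / beta - 1
    if (tau < 0) stop("beta must not exceed J_M - 1")
    nu <- mu / (1 + tau)
  } else if (!is.null(nu)) {
    stopifnot(nu > 0, nu < 1)
    tau <- mu / nu - 1
    if (tau < 0) stop("nu must not exceed mu = theta/(J_M - 1 + theta)")
    beta <- (J_M - 1) / (1 + tau)
  } else stop("supply beta or nu")
  list(mu = mu, tau = tau, nu = nu, beta = beta)
}

#' Average species lifetime in generations
#'
#' Applies the model-specific lifetime approximation derived from the ratio
#' of the equilibrium species count to the rate of production of new species:
#' point mutation `L = -log(nu)`; random fission `L = nu^(-1/2)`; protracted
#' `L = -tau * log(tau * mu)` (natural logarithms).
#'
#' @inheritParams speciation_rate
#' @param nu Speciation rate in (0, 1).
#' @param tau_ps,mu_ps Protracted-model intermediates (see [ps_rates()]),
#'   required for `"PS"`; their product must lie in (0, 1).
#' @return Average species lifetime in generations.
#' @examples
#' species_lifetime("PMS", 3.18e-9)  # about 19.6 generations
#' @export
species_lifetime <- function(model, nu, tau_ps = NULL, mu_ps = NULL) {
  model <- toupper(model)
  stopifnot(nu > 0, nu < 1)
  switch(model,
    PMS = -log(nu),
    RFS = nu^(-0.5),
    PS = {
      if (is.null(tau_ps) || is.null(mu_ps)) stop("PS requires tau_ps and mu_ps")
      tm <- tau_ps * mu_ps
      if (tm <= 0 || tm >= 1) stop("tau * mu must lie in (0, 1) for the protracted lifetime")
      -tau_ps * log(tm)
    },
    stop("unknown model: ", model))
}
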
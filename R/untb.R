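## Neutral-theory metacommunity machinery: species abundance distributions,
## Preston octaves, the Ewens sampling formula, and expected SADs under the
## point-mutation, random-fission and protracted speciation models plus a
## Poisson-lognormal baseline.

#' Metacommunity species abundance distribution
#'
#' Validates and wraps a vector of per-species abundances (individuals; may
#' be continuous when the abundances are model estimates).
#'
#' @param n Vector of positive abundances.
#' @return Object of class `"metacommunity_sad"` with elements `n` (sorted
#'   descending), `J_M` (total individuals), `S` (species count) and
#'   `octaves` (Preston octave counts).
#' @export
metacommunity_sad <- function(n) {
  n <- as.numeric(n)
  if (length(n) < 1 || any(!is.finite(n)) || any(n <= 0))
    stop("abundances must be positive and finite")
  n <- sort(n, decreasing = TRUE)
  out <- list(n = n, J_M = sum(n), S = length(n), octaves = preston_octaves(n))
  class(out) <- "metacommunity_sad"
  out
}

#' @export
print.metacommunity_sad <- function(x, ...) {
  cat(sprintf("Metacommunity SAD: S = %d species, J_M = %.6g individuals\n",
              x$S, x$J_M))
  cat("  octaves:", paste(x$octaves, collapse = " "), "\n")
  invisible(x)
}

as_sad <- function(x) {
  if (inherits(x, "metacommunity_sad")) x else metacommunity_sad(x)
}

#' Preston abundance octaves
#'
#' Octave `j` contains the species whose abundance `n` satisfies
#' `2^(j-1) <= n < 2^j` (half-open boundaries, so an abundance of exactly 2
#' falls in octave 2). Continuous abundances are binned by the same
#' boundaries without rounding.
#'
#' @param n Vector of positive abundances.
#' @return Integer vector of octave counts, octave 1 upward.
#' @examples
#' preston_octaves(c(1, 2, 3, 4, 7, 8))  # 1 2 2 1
#' @export
preston_octaves <- function(n) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("abundances must be positive")
  oc <- pmax(floor(log2(n)), 0) + 1      # n in [2^(j-1), 2^j) -> j; n < 1 impossible
  tabulate(oc, nbins = max(oc))
}

#' Log-likelihood of the Ewens sampling formula
#'
#' Probability of the unordered species abundance configuration under the
#' point-mutation neutral model, computed entirely in log space through
#' log-gamma so it remains finite at metacommunity sizes of 1e10 and beyond.
#'
#' @param sad A [metacommunity_sad()] or abundance vector.
#' @param theta Fundamental biodiversity number (> 0).
#' @return Scalar log-probability.
#' @examples
#' exp(ewens_loglik(c(1, 1), theta = 2))  # theta / (1 + theta) = 2/3
#' @export
ewens_loglik <- function(sad, theta) {
  sad <- as_sad(sad)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  n <- sad$n
  J <- sad$J_M
  mult <- table(n)
  ll <- lgamma(J + 1) - sum(log(n)) - sum(lfactorial(mult)) +
    sad$S * log(theta) - (lgamma(theta + J) - lgamma(theta))
  if (!is.finite(ll)) stop("Ewens log-likelihood over/underflowed (non-finite)")
  ll
}

#' Expected species richness of the Ewens / point-mutation model
#'
#' `E(S) = sum_{i=1..J_M} theta / (theta + i - 1)`, evaluated in closed form
#' via digamma functions.
#'
#' @inheritParams ewens_loglik
#' @param J_M Metacommunity size.
#' @export
ewens_expected_richness <- function(theta, J_M) {
  theta * (digamma(theta + J_M) - digamma(theta))
}

#' Expected species abundance distribution of the point-mutation model
#'
#' Exact Ewens expectation of the number of species with abundance `n`,
#' `E(S_n) = (theta/n) J! Gamma(theta + J - n) / ((J - n)! Gamma(theta + J))`,
#' evaluated through log-gamma; continuous `n` interpolates the expression.
#'
#' @inheritParams ewens_expected_richness
#' @param n Abundance (vectorized), `0 < n <= J_M`.
#' @return Expected number of species at each abundance.
#' @export
pm_expected_sad <- function(theta, J_M, n) {
  stopifnot(theta > 0, J_M >= 1)
  out <- numeric(length(n))
  ok <- n > 0 & n <= J_M
  le <- log(theta) - log(n[ok]) +
    lgamma(J_M + 1) - lgamma(J_M - n[ok] + 1) +
    lgamma(theta + J_M - n[ok]) - lgamma(theta + J_M)
  if (any(!is.finite(le))) stop("point-mutation expected SAD overflowed")
  out[ok] <- exp(le)
  out
}

## ---- random fission ---------------------------------------------------

## Log weights of the species count S under the random-fission equilibrium:
## t(S) = log C(J-1, S-1) + S log(theta^2/J) - log S!  (ordered compositions
## are uniform given S). Returns an adaptive window of S values with their
## log weights and the log normalizing constant.
rf_count_weights <- function(theta, J_M) {
  lr <- 2 * log(theta) - log(J_M)
  tfun <- function(S) lchoose(J_M - 1, S - 1) + S * lr - lfactorial(S)
  ## walk to the peak from a cheap initial guess, then expand
  S0 <- min(max(1, round(theta)), J_M)
  step <- function(S) tfun(S + 1) - tfun(S)
  while (S0 < J_M && step(S0) > 0) S0 <- min(J_M, S0 + max(1, ceiling(S0 * 0.2)))
  while (S0 > 1 && step(max(1, S0 - 1)) < 0) S0 <- max(1, S0 - max(1, ceiling(S0 * 0.2)))
  tpeak <- tfun(S0)
  lo <- S0
  while (lo > 1 && tfun(max(1, lo - 1)) > tpeak - 45) lo <- max(1, lo - max(1, ceiling((S0 - lo + 1) * 0.5)))
  hi <- S0
  while (hi < J_M && tfun(min(J_M, hi + 1)) > tpeak - 45) hi <- min(J_M, hi + max(1, ceiling((hi - S0 + 1) * 0.5)))
  S <- seq(lo, hi)
  lt <- tfun(S)
  m <- max(lt)
  logZ <- m + log(sum(exp(lt - m)))
  list(S = S, logw = lt - logZ, logZ = logZ)
}

#' Equilibrium log-probability of a SAD under random-fission speciation
#'
#' The random-fission metacommunity at equilibrium is even ("broken-stick"
#' like): conditional on the species count S, every ordered composition of
#' `J_M` individuals into S positive abundances is equally likely, and S
#' itself is weighted by `(theta^2 / J_M)^S / S!`. The probability of an
#' unordered abundance configuration follows by multiplying with the number
#' of distinct orderings. All terms are evaluated in log space, so the
#' function is stable at metacommunity sizes of 1e9 and beyond. The
#' maximum-likelihood theta is close to the observed species count for large
#' `J_M`, reflecting that S concentrates at theta under this law.
#'
#' @param sad A [metacommunity_sad()] or abundance vector (integer
#'   abundances; continuous estimates are accepted and treated as a
#'   configuration with distinct parts).
#' @param theta Fundamental biodiversity number (> 0); under random fission
#'   `theta = sqrt(nu) * J_M`.
#' @return Scalar log-probability.
#' @export
rf_equilibrium_logprob <- function(sad, theta) {
  sad <- as_sad(sad)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  J <- sad$J_M
  mult <- table(sad$n)
  w <- rf_count_weights(theta, J)
  lp <- sad$S * (2 * log(theta) - log(J)) - sum(lfactorial(mult)) - w$logZ
  if (!is.finite(lp)) stop("random-fission log-probability non-finite; diagnostics: ",
                           sprintf("S = %d, J_M = %.3g, theta = %.3g", sad$S, J, theta))
  lp
}

#' Expected species abundance distribution of the random-fission model
#'
#' Mixes the uniform-composition abundance marginal over the equilibrium
#' distribution of the species count:
#' `E(S_n) = sum_S P(S) S C(J_M-1-n, S-2) / C(J_M-1, S-1)` (with the single
#' species at `n = J_M` when S = 1), evaluated via log-gamma so continuous
#' abundances and very large `J_M` are handled.
#'
#' @inheritParams pm_expected_sad
#' @export
rf_expected_sad <- function(theta, J_M, n) {
  stopifnot(theta > 0, J_M >= 1)
  w <- rf_count_weights(theta, J_M)
  S <- w$S
  pw <- exp(w$logw)
  out <- numeric(length(n))
  Sg <- S[S >= 2]
  pg <- pw[S >= 2]
  for (k in seq_along(n)) {
    nn <- n[k]
    if (nn <= 0 || nn > J_M) next
    ok <- (J_M - 1 - nn) >= (Sg - 2)
    v <- numeric(length(Sg))
    v[ok] <- Sg[ok] * exp(lchoose(J_M - 1 - nn, Sg[ok] - 2) -
                          lchoose(J_M - 1, Sg[ok] - 1))
    tot <- sum(pg * v)
    if (1 %in% S && abs(nn - J_M) < 0.5) tot <- tot + pw[match(1, S)]
    out[k] <- tot
  }
  out
}

## ---- protracted speciation --------------------------------------------

## internal: intermediate rates of the protracted model
ps_pars <- function(theta, beta, J_M) {
  stopifnot(theta > 0, beta > 0, J_M > 1)
  mu <- theta / (J_M - 1 + theta)
  tau <- (J_M - 1) / beta - 1
  if (tau < 0) stop("beta must not exceed J_M - 1 (protraction time would be negative)")
  list(mu = mu, tau = tau, x1 = 1 - mu, x2 = tau / (1 + tau))
}

#' Expected SAD of the protracted speciation model (difference logseries)
#'
#' The protracted model behaves like the point-mutation logseries at large
#' abundance but predicts fewer rare species: its expected SAD is the
#' difference of two geometric-decay series,
#' `E(S_n) = (theta/n) * ((1 - mu)^n - (tau/(1+tau))^n)`, where
#' `mu = theta / (J_M - 1 + theta)` is the effective speciation rate of
#' established species and `tau = (J_M - 1)/beta - 1` the protraction
#' (speciation duration) scale set by the second fitted parameter `beta`.
#' As `beta` approaches `J_M - 1` (`tau -> 0`) the logseries is recovered.
#'
#' @inheritParams pm_expected_sad
#' @param beta Second parameter of the protracted model, `0 < beta <= J_M-1`.
#' @return `ps_expected_sad`: expected species count at abundances `n`;
#'   `ps_expected_octaves`: expected species per Preston octave.
#' @export
ps_expected_sad <- function(theta, beta, J_M, n) {
  pp <- ps_pars(theta, beta, J_M)
  out <- numeric(length(n))
  ok <- n > 0 & n <= J_M
  nn <- n[ok]
  out[ok] <- theta / nn * (exp(nn * log(pp$x1)) - exp(nn * log(pp$x2)))
  pmax(out, 0)
}

#' @rdname ps_expected_sad
#' @param octaves Number of octaves to return; defaults to the octave of
#'   `J_M`.
#' @export
ps_expected_octaves <- function(theta, beta, J_M, octaves = NULL) {
  expected_octaves(function(n) ps_expected_sad(theta, beta, J_M, n),
                   J_M, octaves)
}

#' Aggregate an expected SAD to Preston octaves
#'
#' Sums `E(S_n)` over the integer abundances of each octave; octaves too wide
#' to enumerate are integrated numerically, treating the expectation as a
#' smooth function of continuous abundance (the same half-open boundaries are
#' used).
#'
#' @param es_fun Function mapping abundance to expected species count.
#' @param J_M Metacommunity size (upper support bound).
#' @param octaves Number of octaves; defaults to the octave containing `J_M`.
#' @return Numeric vector of expected species per octave.
#' @export
expected_octaves <- function(es_fun, J_M, octaves = NULL) {
  if (is.null(octaves)) octaves <- floor(log2(J_M)) + 1
  out <- numeric(octaves)
  for (j in seq_len(octaves)) {
    lo <- 2^(j - 1)
    hi <- min(2^j - 1, J_M)
    if (hi < lo) break
    if (hi - lo < 4096) {
      out[j] <- sum(es_fun(seq(lo, hi)))
    } else {
      out[j] <- integrate(es_fun, lo, hi + 1, rel.tol = 1e-8,
                          stop.on.error = FALSE)$value
    }
  }
  out
}

## ---- Poisson-lognormal -------------------------------------------------

## log pmf of the Poisson-lognormal mixture at abundance n (continuous n
## extends the Poisson pmf through the gamma function); for n > 50 the
## mixture is numerically indistinguishable from the lognormal density.
pln_log_pmf <- function(n, meanlog, sdlog) {
  vapply(n, function(nn) {
    if (nn > 50)
      return(dnorm(log(nn), meanlog, sdlog, log = TRUE) - log(nn))
    f <- function(x) exp(nn * x - exp(x) - lgamma(nn + 1) +
                           dnorm(x, meanlog, sdlog, log = TRUE))
    v <- integrate(f, meanlog - 8 * sdlog - 1, max(meanlog + 8 * sdlog, log(nn + 1) + 6),
                   rel.tol = 1e-9, stop.on.error = FALSE)$value
    log(v)
  }, 0)
}

pln_log_p0 <- function(meanlog, sdlog) {
  f <- function(x) exp(-exp(x) + dnorm(x, meanlog, sdlog, log = TRUE))
  v <- integrate(f, meanlog - 10 * sdlog - 2, meanlog + 10 * sdlog + 2,
                 rel.tol = 1e-10, stop.on.error = FALSE)$value
  log(v)
}

#' Zero-truncated Poisson-lognormal log density of a SAD
#'
#' Composite log-likelihood of the abundances under a zero-truncated
#' Poisson-lognormal distribution (each species an independent draw).
#'
#' @param sad SAD or abundance vector.
#' @param meanlog,sdlog Parameters of the mixing lognormal.
#' @export
pln_loglik <- function(sad, meanlog, sdlog) {
  sad <- as_sad(sad)
  if (sdlog <= 0) stop("sdlog must be > 0")
  lp0 <- pln_log_p0(meanlog, sdlog)
  sum(pln_log_pmf(sad$n, meanlog, sdlog)) - sad$S * log1p(-exp(lp0))
}

## ---- composite likelihood and model weights ----------------------------

#' Composite log-likelihood of a SAD given an expected SAD
#'
#' Treats each species' abundance as an independent draw from the normalized
#' expected SAD: `sum_s log(E(S_{n_s}) / sum_n E(S_n))`.
#'
#' @param sad SAD or abundance vector.
#' @param expected Expected species count evaluated at each observed
#'   abundance (same order as `sort(n, decreasing = TRUE)`), strictly
#'   positive.
#' @param expected_total Sum of the expected SAD over its whole support
#'   (the expected species richness).
#' @return Scalar composite log-likelihood.
#' @export
composite_loglik <- function(sad, expected, expected_total) {
  sad <- as_sad(sad)
  stopifnot(length(expected) == sad$S, expected_total > 0)
  if (any(expected <= 0))
    stop("expected SAD has zero mass at an observed abundance")
  sum(log(expected)) - sad$S * log(expected_total)
}

#' Akaike weights from a vector of AIC values
#'
#' `w_m = exp(-(AIC_m - min AIC)/2)`, normalized to sum to one.
#'
#' @param aics Numeric vector of AIC values.
#' @return Vector of weights summing to 1 (names preserved).
#' @examples
#' akaike_weights(c(11671.48, 11391.19, 11150.39, 11148.78))
#' @export
akaike_weights <- function(aics) {
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}
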
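## Elementary probability building blocks of the observation model.

#' Detection probability in a plot under the Poisson point process assumption
#'
#' Individuals of a species are assumed to follow a homogeneous Poisson point
#' process with density `d` within the habitat, so the count in a plot of area
#' `a` is Poisson with mean `d * a` and the probability of detecting at least
#' one individual is `1 - exp(-d * a)`. Units of `d` and `a` must be
#' consistent (e.g. individuals per m^2 with a in m^2).
#'
#' @param d Individual density (>= 0).
#' @param a Plot area (>= 0).
#' @return Detection probability in `[0, 1)`; vectorized.
#' @examples
#' detection_prob(0.01, 100)  # 1 - exp(-1)
#' @export
detection_prob <- function(d, a) {
  if (any(d < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
    stop("detection_prob: d and a must be non-negative")
  -expm1(-d * a)
}

#' Zero-inflated detection probability
#'
#' Detection probability conditional on the cell-level presence state `z`:
#' zero when the species is absent from the cell, and [detection_prob()]
#' when present.
#'
#' @param z Presence state, 0 or 1 (vectorized).
#' @inheritParams detection_prob
#' @return Detection probability.
#' @export
zi_detection_prob <- function(z, d, a) {
  if (any(!(z %in% c(0, 1))))
    stop("zi_detection_prob: z must be 0 or 1")
  z * detection_prob(d, a)
}

#' Log-likelihood contribution of one species-cell pair
#'
#' Computes the contribution of the detection history of one (species, cell)
#' pair given its conditional density and occurrence probability. When the
#' presence state is known (`m = 1`) the Bernoulli occupancy term and, for
#' presence, the plot-level detection terms enter directly; when unknown, the
#' discrete latent state is marginalised exactly over its two values.
#'
#' @param y Integer vector of plot-level detections (0/1); may be empty.
#' @param a Plot areas, same length as `y`, in units consistent with `d`.
#' @param d Conditional density of the species in the cell.
#' @param psi Occurrence probability in (0, 1).
#' @param m 1 if the presence state is known, else 0.
#' @param z Known presence state (used when `m = 1`).
#' @return Scalar log-likelihood contribution.
#' @examples
#' # unknown state, two empty plots
#' species_cell_loglik(c(0, 0), c(50, 100), d = 0.01, psi = 0.4)
#' @export
species_cell_loglik <- function(y, a, d, psi, m = 0, z = NA) {
  stopifnot(length(y) == length(a), psi > 0, psi < 1, d >= 0)
  if (any(!(y %in% c(0, 1)))) stop("y must be 0/1")
  dm <- d * a
  ldet <- sum(ifelse(y == 1, log(-expm1(-dm)), -dm))  # given presence
  if (m == 1) {
    if (!(z %in% c(0, 1))) stop("m = 1 requires a known z in {0, 1}")
    if (z == 0) {
      if (any(y == 1))
        stop("data contradiction: detection recorded for a pair with known absence")
      return(log1p(-psi))
    }
    return(ldet + log(psi))
  }
  if (any(y == 1))
    stop("a detection implies a known presence (m must be 1)")
  # z = 0 branch has detection likelihood 1 because all y are 0
  logspace_add(log(psi) + ldet, log1p(-psi))
}

logspace_add <- function(lx, ly) {
  m <- pmax(lx, ly)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(-abs(lx - ly))))
}

#' Linear predictors of density and occupancy for all species-cell pairs
#'
#' Evaluates the log conditional density and the occupancy logit for every
#' (species, cell) combination from fixed effects and (predicted or true)
#' random effects:
#' `log d_ij = mu + beta1 x1 + beta2 x2 + beta3 x1 x2 + e1_i + e2_j + e3_ij`
#' and `logit psi_ij = eta + gamma1 x1 + gamma2 x2 + gamma3 x1 x2 + u1_i +
#' u2_j`.
#'
#' @param params A [model_params()] object.
#' @param effects List with components `e1`, `u1` (length I), `e2`, `u2`
#'   (length J), and optionally `e3` (an I x J matrix; missing entries count
#'   as 0, their prior mean).
#' @param cells Cell table with columns `x1` and `x2` (standardized
#'   covariates), one row per cell in the same order as `e2`.
#' @return List with matrices `log_d` and `logit_psi` (I x J).
#' @export
linear_predictors <- function(params, effects, cells) {
  validate_params(params)
  I <- length(effects$e1)
  J <- nrow(cells)
  stopifnot(length(effects$e2) == J)
  if (any(is.na(cells$x1)) || any(is.na(cells$x2)))
    stop("missing covariates for a modelled cell")
  xb <- params$beta[1] * cells$x1 + params$beta[2] * cells$x2 +
    params$beta[3] * cells$x1 * cells$x2
  xg <- params$gamma[1] * cells$x1 + params$gamma[2] * cells$x2 +
    params$gamma[3] * cells$x1 * cells$x2
  e3 <- effects$e3
  if (is.null(e3)) e3 <- matrix(0, I, J)
  log_d <- params$mu + outer(effects$e1, effects$e2 + xb, "+") + e3
  logit_psi <- params$eta + outer(effects$u1, effects$u2 + xg, "+")
  list(log_d = log_d, logit_psi = logit_psi)
}

# plot areas are recorded in m^2, densities per km^2 habitat
AREA_M2_TO_KM2 <- 1e-6
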
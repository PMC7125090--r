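## Synthetic-data generator: landscapes, survey designs, detection data and
## auxiliary occurrence data with exactly the generative structure the
## hierarchical model assumes.

#' Configuration for the synthetic-data generator
#'
#' @param I Number of species (positive integer).
#' @param J Number of grid cells (positive integer).
#' @param plots_per_cell Either a single non-negative integer (same number of
#'   plots in every cell), an integer vector of length `J`, or a law such as
#'   `list(law = "poisson", mean = 10)`.
#' @param plot_area_law Law for plot areas in m^2. Default is log-uniform on
#'   `[10, 1000]` m^2, mimicking vegetation-survey releves whose typical size
#'   is about 100 m^2.
#' @param habitat_area_law Law for the habitat (e.g. natural forest) area
#'   `A_j` in km^2 within each cell. Default uniform on `[5, 95]` km^2,
#'   i.e. partial habitat cover of a 10 km x 10 km cell.
#' @param true_params A [model_params()] object: the generating parameters.
#' @param aux_presence_coverage Probability in `[0, 1]` that a truly occupied
#'   (species, cell) is registered as a known presence by an auxiliary source.
#' @param aux_absence_coverage Probability in `[0, 1]` that a truly unoccupied
#'   (species, cell) is registered as a known absence.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration including the seed.
#' @return An object of class `"macroabund_config"`.
#' @export
sim_config <- function(I, J, plots_per_cell = 10,
                       plot_area_law = list(law = "loguniform", min = 10, max = 1000),
                       habitat_area_law = list(law = "uniform", min = 5, max = 95),
                       true_params = model_params(),
                       aux_presence_coverage = 0.5,
                       aux_absence_coverage = 0.3,
                       seed = 1) {
  stopifnot(I >= 1, J >= 1, is.finite(I), is.finite(J))
  for (p in c(aux_presence_coverage, aux_absence_coverage))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("aux coverage probabilities must lie in [0, 1]")
  validate_params(true_params)
  check_law(plot_area_law, positive = TRUE)
  check_law(habitat_area_law, positive = TRUE)
  cfg <- list(I = as.integer(I), J = as.integer(J),
              plots_per_cell = plots_per_cell,
              plot_area_law = plot_area_law,
              habitat_area_law = habitat_area_law,
              true_params = true_params,
              aux_presence_coverage = aux_presence_coverage,
              aux_absence_coverage = aux_absence_coverage,
              seed = as.integer(seed))
  class(cfg) <- "macroabund_config"
  cfg
}

check_law <- function(law, positive = FALSE) {
  if (!is.list(law) || is.null(law$law))
    stop("a law must be a list with a 'law' name")
  if (!law$law %in% c("constant", "uniform", "loguniform", "poisson"))
    stop("unknown law name: ", law$law)
  vals <- unlist(law[setdiff(names(law), "law")])
  if (any(!is.finite(vals))) stop("non-finite law parameters")
  if (positive && law$law %in% c("uniform", "loguniform") &&
      (law$min <= 0 || law$max < law$min))
    stop("law range must satisfy 0 < min <= max")
  if (positive && law$law == "constant" && law$value <= 0)
    stop("constant law value must be > 0")
  invisible(law)
}

draw_law <- function(n, law) {
  switch(law$law,
         constant = rep(law$value, n),
         uniform = runif(n, law$min, law$max),
         loguniform = exp(runif(n, log(law$min), log(law$max))),
         poisson = rpois(n, law$mean))
}

#' Simulate a complete survey dataset from the hierarchical model
#'
#' Draws a landscape (habitat areas, standardized covariates), correlated
#' Gaussian random effects, latent presence states, replicated
#' detection-nondetection observations, and partially observed auxiliary
#' occurrence records, exactly as the integrated occupancy-abundance model
#' assumes. The full latent truth is retained for calibration studies.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `"macroabund_data"`: a list with `detections`
#'   (species, cell, plot, y, area in m^2), `cells` (cell, A in km^2, x1, x2,
#'   ecoregion), `aux` (species, cell, z, source), `truth` (matrices `z`, `d`,
#'   `psi`, `N = d * A * z`, and the random effects), and `config`.
#' @examples
#' d <- simulate_dataset(sim_config(I = 5, J = 4, plots_per_cell = 3, seed = 1))
#' head(d$detections)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "macroabund_config"))
  set.seed(config$seed)
  I <- config$I; J <- config$J
  pars <- config$true_params

  ## survey design
  K <- config$plots_per_cell
  if (is.list(K)) K <- draw_law(J, K)
  if (length(K) == 1) K <- rep(K, J)
  stopifnot(length(K) == J, all(K >= 0))
  if (all(K == 0)) stop("at least one cell must contain a plot")
  K <- as.integer(K)

  ## landscape: habitat areas and standardized covariates
  A <- draw_law(J, config$habitat_area_law)
  x1 <- rnorm(J); x2 <- rnorm(J)
  x1 <- as.numeric(scale(x1)); x2 <- as.numeric(scale(x2))
  cells <- data.frame(cell = seq_len(J), A = A, x1 = x1, x2 = x2,
                      ecoregion = "R1", stringsAsFactors = FALSE)

  ## random effects; (e2, u2) bivariate normal with correlation rho
  e1 <- rnorm(I, 0, pars$sigma[1])
  u1 <- rnorm(I, 0, pars$tau[1])
  z1 <- rnorm(J); z2 <- rnorm(J)
  e2 <- pars$sigma[2] * z1
  u2 <- pars$tau[2] * (pars$rho * z1 + sqrt(1 - pars$rho^2) * z2)
  e3 <- matrix(rnorm(I * J, 0, pars$sigma[3]), I, J)
  effects <- list(e1 = e1, u1 = u1, e2 = e2, u2 = u2, e3 = e3)

  lp <- linear_predictors(pars, effects, cells)
  d <- exp(lp$log_d)          # individuals per km^2, conditional on presence
  psi <- plogis(lp$logit_psi)
  z <- matrix(rbinom(I * J, 1, psi), I, J)

  ## detection-nondetection observations
  cell_rep <- rep.int(seq_len(J), K)
  nplot <- length(cell_rep)
  area <- draw_law(nplot, config$plot_area_law)
  plot_id <- paste0("c", cell_rep, "p", sequence(K))
  sp <- rep(seq_len(I), times = nplot)
  pc <- rep(cell_rep, each = I)
  pa <- rep(area, each = I)
  pid <- rep(plot_id, each = I)
  pdet <- z[cbind(sp, pc)] * detection_prob(d[cbind(sp, pc)], pa * AREA_M2_TO_KM2)
  y <- rbinom(length(pdet), 1, pdet)
  detections <- data.frame(species = sp, cell = pc, plot = pid,
                           y = y, area = pa, stringsAsFactors = FALSE)

  ## auxiliary occurrence records never contradict the truth
  reg_p <- z == 1 & matrix(runif(I * J), I, J) < config$aux_presence_coverage
  reg_a <- z == 0 & matrix(runif(I * J), I, J) < config$aux_absence_coverage
  wp <- which(reg_p, arr.ind = TRUE)
  wa <- which(reg_a, arr.ind = TRUE)
  aux <- data.frame(species = c(wp[, 1], wa[, 1]),
                    cell = c(wp[, 2], wa[, 2]),
                    z = c(rep(1L, nrow(wp)), rep(0L, nrow(wa))),
                    source = c(rep("presence-source", nrow(wp)),
                               rep("absence-source", nrow(wa))),
                    stringsAsFactors = FALSE)
  aux <- aux[order(aux$species, aux$cell), , drop = FALSE]
  rownames(aux) <- NULL

  truth <- list(z = z, d = d, psi = psi,
                N = d * matrix(A, I, J, byrow = TRUE) * z,
                effects = effects)
  out <- list(detections = detections, cells = cells, aux = aux,
              truth = truth, config = config)
  class(out) <- "macroabund_data"
  out
}

#' @export
print.macroabund_data <- function(x, ...) {
  cat(sprintf("Synthetic occupancy-abundance dataset: %d species x %d cells, %d plots\n",
              x$config$I, x$config$J, length(unique(x$detections$plot))))
  cat(sprintf("  detections: %d of %d records positive\n",
              sum(x$detections$y), nrow(x$detections)))
  cat(sprintf("  auxiliary records: %d presences, %d absences\n",
              sum(x$aux$z == 1), sum(x$aux$z == 0)))
  invisible(x)
}

#' Simulate a metacommunity species abundance distribution
#'
#' `point_mutation` draws an exact sample from the stationary species
#' abundance distribution of the point-mutation neutral model via the
#' sequential urn construction: the i-th individual founds a new species with
#' probability `theta / (theta + i - 1)`, otherwise it copies a uniformly
#' chosen earlier individual. `poisson_lognormal` draws per-species abundances
#' from a zero-truncated Poisson-lognormal distribution.
#'
#' @param mode `"point_mutation"` or `"poisson_lognormal"`.
#' @param params For `point_mutation`, `list(theta = ...)` with `theta > 0`;
#'   for `poisson_lognormal`, `list(meanlog = ..., sdlog = ..., S = ...)`.
#' @param J_M Metacommunity size (number of individuals) for
#'   `point_mutation`; ignored for `poisson_lognormal`.
#' @param seed Integer seed.
#' @return A [metacommunity_sad()] object (abundances sorted descending).
#' @examples
#' simulate_neutral_sad("point_mutation", list(theta = 5), J_M = 200, seed = 1)
#' @export
simulate_neutral_sad <- function(mode = c("point_mutation", "poisson_lognormal"),
                                 params, J_M = NULL, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "point_mutation") {
    theta <- params$theta
    if (is.null(theta) || !is.finite(theta) || theta <= 0)
      stop("point_mutation requires theta > 0")
    if (is.null(J_M) || J_M < 1) stop("J_M must be a positive integer")
    J_M <- as.integer(J_M)
    founder <- runif(J_M) < theta / (theta + seq_len(J_M) - 1)
    pick <- runif(J_M)
    sp <- integer(J_M)
    nsp <- 0L
    for (i in seq_len(J_M)) {
      if (founder[i]) {
        nsp <- nsp + 1L
        sp[i] <- nsp
      } else {
        sp[i] <- sp[floor(pick[i] * (i - 1)) + 1L]
      }
    }
    n <- tabulate(sp)
  } else {
    S <- params$S
    if (is.null(S) || S < 1) stop("poisson_lognormal requires a species count S")
    stopifnot(is.finite(params$meanlog), is.finite(params$sdlog), params$sdlog >= 0)
    n <- integer(S)
    todo <- seq_len(S)
    while (length(todo)) {  # zero-truncation by redraw
      lam <- rlnorm(length(todo), params$meanlog, params$sdlog)
      n[todo] <- rpois(length(todo), lam)
      todo <- todo[n[todo] == 0]
    }
  }
  metacommunity_sad(sort(n, decreasing = TRUE))
}
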
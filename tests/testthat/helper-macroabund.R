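## Shared fixtures and independent oracles for the test suite.

## small integrated-model dataset with a reasonable amount of signal
small_data <- function(seed = 1, I = 10, J = 15, K = 8) {
  simulate_dataset(sim_config(I = I, J = J, plots_per_cell = K,
                              aux_presence_coverage = 0.6,
                              aux_absence_coverage = 0.5, seed = seed))
}

## hand-built fit-like object for the derived-quantity estimators
fake_fit <- function(d_hat, psi_hat, m, z, A) {
  I <- nrow(d_hat); J <- ncol(d_hat)
  structure(list(model = "integrated", d_hat = d_hat, psi_hat = psi_hat,
                 m = m, z_known = z,
                 cells = data.frame(cell = seq_len(J), A = A),
                 species = seq_len(I)),
            class = "macroabund_fit")
}

## exact per-pair marginal likelihood by brute-force 1-D integration
## (independent of the package's Laplace and Gauss-Hermite paths)
integrate_marginal <- function(params, data) {
  pd <- macroabund:::prepare_model_data(data, "integrated", TRUE)
  eff0 <- list(e1 = numeric(pd$I), u1 = numeric(pd$I),
               e2 = numeric(pd$J), u2 = numeric(pd$J))
  lp <- linear_predictors(params, eff0, pd$cells)
  s3 <- params$sigma[3]
  tot <- 0
  for (q in seq_len(nrow(pd$pairs))) {
    i <- pd$pairs[q, 1]; j <- pd$pairs[q, 2]
    rows <- which(pd$det$si == i & pd$det$ci == j)
    y <- pd$det$y[rows]; a <- pd$det$area[rows] * 1e-6
    psi <- stats::plogis(lp$logit_psi[i, j])
    ll <- function(e) species_cell_loglik(y, a, exp(lp$log_d[i, j] + e), psi,
                                          m = pd$m[i, j], z = pd$z[i, j])
    if (!length(rows)) { tot <- tot + ll(0); next }
    g <- function(e) vapply(e, function(ee) exp(ll(ee) + dnorm(ee, 0, s3, log = TRUE)), 0)
    tot <- tot + log(stats::integrate(g, -12, 12, rel.tol = 1e-12)$value)
  }
  tot
}

## all integer partitions of n (decreasing parts)
enum_partitions <- function(n, max = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq(min(n, max), 1)) {
    for (p in enum_partitions(n - k, k)) out <- c(out, list(c(k, p)))
  }
  out
}

table3 <- list(
  J_M = c(central = 1.65e10, northern = 4.18e9, southern = 3.26e8,
          oceanic = 6.39e6),
  S = c(central = 1024, northern = 328, southern = 508, oceanic = 141),
  pms = list(theta = c(52.3, 16.9, 31.4, 10.6),
             nu = c(3.18e-9, 4.06e-9, 9.62e-8, 1.65e-6),
             L = c(19.6, 19.3, 16.2, 13.3)),
  rfs = list(theta = c(1023.8, 327.8, 507.8, 140.8),
             nu = c(3.87e-15, 6.16e-15, 2.42e-12, 4.85e-10),
             L = c(1.61e7, 1.27e7, 6.43e5, 4.54e4)),
  ps = list(theta = c(113.5, 61.8, 76.6, 31.7),
            nu = c(2.72e-13, 2.78e-14, 3.03e-11, 1.74e-9),
            L = c(2.19e5, 2.58e6, 4.89e4, 1.21e4)))

table2_aic <- list(
  central = c(PMS = 34706.21, RFS = 36034.85, PS = 33635.67, PLN = 33652.16),
  northern = c(PMS = 11671.48, RFS = 11391.19, PS = 11150.39, PLN = 11148.78),
  southern = c(PMS = 14511.53, RFS = 14544.38, PS = 13922.75, PLN = 14009.33),
  oceanic = c(PMS = 3388.36, RFS = 3298.71, PS = 3214.74, PLN = 3226.23))

table2_weights <- list(
  central = c(0, 0, 1, 0),
  northern = c(0, 0, 0.309, 0.691),
  southern = c(0, 0, 1, 0),
  oceanic = c(0, 0, 0.997, 0.003))
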
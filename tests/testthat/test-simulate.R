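test_that("simulated datasets are deterministic and respect the latent truth", {
  cfg <- sim_config(I = 6, J = 8, plots_per_cell = 4, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)

  ## detections impossible where the species is absent
  idx <- cbind(d1$detections$species, d1$detections$cell)
  expect_true(all(d1$detections$y[d1$truth$z[idx] == 0] == 0))

  ## auxiliary records never contradict the truth
  ai <- cbind(d1$aux$species, d1$aux$cell)
  expect_true(all(d1$aux$z == d1$truth$z[ai]))

  ## per-cell abundance is density x habitat area x presence
  expect_equal(d1$truth$N,
               d1$truth$d * matrix(d1$cells$A, 6, 8, byrow = TRUE) * d1$truth$z)

  ## covariates standardized over cells
  expect_equal(mean(d1$cells$x1), 0, tolerance = 1e-10)
  expect_equal(var(d1$cells$x2), 1, tolerance = 1e-10)
})

test_that("full auxiliary coverage reveals every presence state", {
  d <- simulate_dataset(sim_config(I = 5, J = 6, plots_per_cell = 2,
                                   aux_presence_coverage = 1,
                                   aux_absence_coverage = 1, seed = 2))
  expect_equal(nrow(d$aux), 30)  # every (species, cell) registered
  ai <- cbind(d$aux$species, d$aux$cell)
  expect_true(all(d$aux$z == d$truth$z[ai]))
})

test_that("switching off the random effects leaves only the fixed parts", {
  p <- model_params(mu = 6, beta = c(0.4, 0.2, -0.1), eta = 0.7,
                    gamma = c(0.3, 0, 0), sigma = c(0, 0, 0), tau = c(0, 0),
                    rho = 0)
  d <- simulate_dataset(sim_config(I = 4, J = 5, plots_per_cell = 2,
                                   true_params = p, seed = 4))
  x1 <- d$cells$x1; x2 <- d$cells$x2
  for (j in 1:5) {
    expect_equal(d$truth$d[, j],
                 rep(exp(6 + 0.4 * x1[j] + 0.2 * x2[j] - 0.1 * x1[j] * x2[j]), 4),
                 tolerance = 1e-12)
    expect_equal(d$truth$psi[, j],
                 rep(plogis(0.7 + 0.3 * x1[j]), 4), tolerance = 1e-12)
  }
})

test_that("empirical detection frequencies match the Poisson link", {
  d <- simulate_dataset(sim_config(I = 200, J = 100, plots_per_cell = 20,
                                   plot_area_law = list(law = "constant", value = 100),
                                   seed = 11))
  det <- d$detections
  idx <- cbind(det$species, det$cell)
  present <- d$truth$z[idx] == 1
  p_theory <- detection_prob(d$truth$d[idx], 100 * 1e-6)
  ## pooled standardized discrepancy over occupied pairs
  obs <- sum(det$y[present])
  expec <- sum(p_theory[present])
  vv <- sum(p_theory[present] * (1 - p_theory[present]))
  expect_lt(abs(obs - expec) / sqrt(vv), 4)
  ## per-pair: detection frequencies over 20 replicate plots track p
  agg_obs <- tapply(det$y[present], paste(det$species[present], det$cell[present]), mean)
  agg_p <- tapply(p_theory[present], paste(det$species[present], det$cell[present]), mean)
  expect_gt(cor(agg_obs, agg_p), 0.9)
})

test_that("simulated random effects have the configured moments", {
  p <- model_params(sigma = c(1.5, 0.5, 0.5), tau = c(1.5, 1), rho = 0.5)
  d <- simulate_dataset(sim_config(I = 100, J = 100, plots_per_cell = 1,
                                   true_params = p, seed = 13))
  eff <- d$truth$effects
  expect_equal(sd(eff$e3), 0.5, tolerance = 0.03)     # 10,000 draws
  expect_equal(sd(eff$e1), 1.5, tolerance = 0.45)     # 100 draws
  expect_equal(sd(eff$u2), 1.0, tolerance = 0.3)
  expect_equal(cor(eff$e2, eff$u2), 0.5, tolerance = 0.25)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(I = 3, J = 3, aux_presence_coverage = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(I = 3, J = 3,
                          plot_area_law = list(law = "lognormal", min = 1, max = 2)),
               "unknown law")
  expect_error(sim_config(I = 3, J = 3,
                          plot_area_law = list(law = "uniform", min = -1, max = 2)),
               "min")
  expect_error(sim_config(I = 3, J = 3,
                          true_params = model_params(mu = Inf)), "finite")
  expect_error(simulate_dataset(sim_config(I = 2, J = 2, plots_per_cell = 0,
                                           seed = 1)),
               "at least one cell")
})
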
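test_that("degenerate marginal likelihood equals the direct sum over pairs", {
  d <- small_data(seed = 1, I = 8, J = 10, K = 5)
  p0 <- model_params(mu = 8, beta = c(0.5, -0.3, 0.1), eta = 0,
                     gamma = c(1, -0.5, 0.2), sigma = c(0, 0, 0),
                     tau = c(0, 0), rho = 0)
  ml <- marginal_loglik(p0, d)
  ## direct fixed-effects-only computation through species_cell_loglik
  pd <- macroabund:::prepare_model_data(d, "integrated", TRUE)
  eff0 <- list(e1 = numeric(pd$I), u1 = numeric(pd$I),
               e2 = numeric(pd$J), u2 = numeric(pd$J))
  lp <- linear_predictors(p0, eff0, pd$cells)
  tot <- 0
  for (q in seq_len(nrow(pd$pairs))) {
    i <- pd$pairs[q, 1]; j <- pd$pairs[q, 2]
    rows <- which(pd$det$si == i & pd$det$ci == j)
    tot <- tot + species_cell_loglik(pd$det$y[rows], pd$det$area[rows] * 1e-6,
                                     exp(lp$log_d[i, j]),
                                     plogis(lp$logit_psi[i, j]),
                                     m = pd$m[i, j], z = pd$z[i, j])
  }
  expect_equal(ml, tot, tolerance = 1e-8)
})

test_that("marginal likelihood is deterministic and finite", {
  d <- small_data(seed = 2, I = 6, J = 8, K = 4)
  p <- model_params()
  expect_identical(marginal_loglik(p, d), marginal_loglik(p, d))
  expect_true(is.finite(marginal_loglik(p, d)))
})

test_that("quadrature path matches brute-force integration", {
  p <- model_params(sigma = c(0, 0, 0.5), tau = c(0, 0), rho = 0)
  for (seed in 1:3) {
    d <- simulate_dataset(sim_config(I = 2, J = 2, plots_per_cell = 2,
                                     true_params = p,
                                     plot_area_law = list(law = "constant", value = 100),
                                     seed = seed))
    ag <- marginal_loglik(p, d, method = "aghq")
    oracle <- integrate_marginal(p, d)
    expect_equal(ag, oracle, tolerance = 1e-7)
    ## the Laplace approximation tracks the exact value to its documented
    ## accuracy on binary data (a few parts in 1e3 of the log-likelihood)
    la <- marginal_loglik(p, d)
    expect_equal(la, oracle, tolerance = 1e-2)
  }
  expect_error(marginal_loglik(model_params(), small_data(3, 4, 5, 2),
                               method = "aghq"), "quadrature path")
})

test_that("baseline fit agrees with an independent cloglog-offset GLMM", {
  skip_if_not_installed("glmmTMB")
  cfg <- sim_config(I = 12, J = 15, plots_per_cell = 8,
                    true_params = model_params(mu = 8, beta = c(0, 0, 0),
                                               eta = 20, gamma = c(0, 0, 0),
                                               sigma = c(1, 0.6, 0.4),
                                               tau = c(0.01, 0.01), rho = 0),
                    aux_presence_coverage = 0, aux_absence_coverage = 0,
                    seed = 11)
  d <- simulate_dataset(cfg)
  f <- fit_abundance(d, model = "baseline", covariates = FALSE)
  det <- d$detections
  det$offs <- log(det$area * 1e-6)
  det$pair <- interaction(det$species, det$cell)
  g <- glmmTMB::glmmTMB(y ~ 1 + (1 | species) + (1 | cell) + (1 | pair),
                        data = det, family = binomial(link = "cloglog"),
                        offset = det$offs)
  expect_equal(unname(coef(f)["mu"]), unname(glmmTMB::fixef(g)$cond), tolerance = 1e-2)
  sds <- sqrt(unlist(glmmTMB::VarCorr(g)$cond))
  expect_equal(unname(coef(f)[c("sigma1", "sigma2", "sigma3")]),
               unname(sds[c("species", "cell", "pair")]), tolerance = 1e-2)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
})

test_that("fitting errors on unusable data and warns on constant covariates", {
  d <- small_data(seed = 1, I = 5, J = 6, K = 3)
  empty <- d; empty$detections <- d$detections[0, ]
  expect_error(fit_abundance(empty), "empty detection table")
  zeroes <- d; zeroes$detections$y <- 0
  expect_error(fit_abundance(zeroes), "all detections are zero")
  flat <- d; flat$cells$x1 <- 0
  expect_warning(fit_abundance(flat, se = FALSE), "constant")
})

test_that("the fitted object supports the standard model interface", {
  d <- small_data(seed = 4)
  f <- fit_abundance(d)
  expect_s3_class(f, "macroabund_fit")
  cf <- coef(f)
  expect_true(all(c("mu", "eta", "sigma1", "tau2", "rho") %in% names(cf)))
  expect_s3_class(summary(f), "summary.macroabund_fit")
  expect_equal(as.numeric(logLik(f)), f$loglik)
  ## predictions are probabilities aligned with the data
  p <- fitted(f)
  expect_length(p, nrow(d$detections))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auc_rank(p, d$detections$y), 0.7)  # in-sample discrimination
  r <- residuals(f)
  expect_length(r, nrow(d$detections))
  ## density predictions positive, occupancy in (0, 1)
  nd <- data.frame(species = c(1, 2), cell = c(1, 2), area = c(100, 100))
  expect_true(all(predict(f, nd, type = "density") > 0))
  po <- predict(f, nd, type = "occupancy")
  expect_true(all(po > 0 & po < 1))
  expect_error(predict(f, data.frame(species = 999, cell = 1, area = 1)),
               "unknown")
  ## simulation from the fit pins known presence states
  s <- simulate(f, nsim = 1, seed = 9)[[1]]
  known <- f$m == 1
  expect_equal(s$truth$z[known], f$z_known[known])
  expect_identical(simulate(f, 1, seed = 9)[[1]]$detections$y,
                   s$detections$y)
})

test_that("fixed effects are recovered on moderately sized data", {
  cfg <- sim_config(I = 15, J = 25, plots_per_cell = 8,
                    aux_presence_coverage = 0.6, aux_absence_coverage = 0.5,
                    seed = 17)
  d <- simulate_dataset(cfg)
  f <- fit_abundance(d)
  tp <- cfg$true_params
  se <- f$se
  est <- setNames(se$estimate, se$parameter)
  ses <- setNames(se$se, se$parameter)
  truth <- c(mu = tp$mu, beta = tp$beta, eta = tp$eta, gamma = tp$gamma)
  nm_est <- c("mu", rep("beta", 3), "eta", rep("gamma", 3))
  est_f <- est[names(est) %in% nm_est]
  se_f <- ses[names(ses) %in% nm_est]
  ## point estimates land near the truth at this size
  expect_lt(max(abs(est_f - truth) / pmax(2 * se_f, 0.2)), 3)
})
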
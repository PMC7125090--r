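test_that("Preston octaves use half-open powers of two", {
  expect_equal(preston_octaves(c(1, 1)), 2L)
  expect_equal(preston_octaves(c(2, 3)), c(0L, 2L))
  expect_equal(preston_octaves(c(1, 2, 3, 4, 7, 8)), c(1L, 2L, 2L, 1L))
  ## continuous abundances binned by the same boundaries
  expect_equal(preston_octaves(c(1.5, 2.0, 3.99, 4.0)), c(1L, 2L, 1L))
  expect_error(preston_octaves(c(1, 0)), "positive")
  ## binning conserves the species count
  set.seed(1)
  n <- rlnorm(200, 4, 2)
  expect_equal(sum(preston_octaves(n)), 200)
})

test_that("the Ewens sampling formula is a probability distribution", {
  ## J_M = 2 by hand
  th <- 1.7
  expect_equal(exp(ewens_loglik(c(2), th)), 1 / (1 + th), tolerance = 1e-12)
  expect_equal(exp(ewens_loglik(c(1, 1), th)), th / (1 + th), tolerance = 1e-12)
  ## brute-force enumeration of all partitions
  for (J in c(4, 8)) for (th in c(0.5, 1, 7)) {
    tot <- sum(vapply(enum_partitions(J),
                      function(p) exp(ewens_loglik(p, th)), 0))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  ## single dominant species, vanishing speciation: probability -> 1
  expect_gt(ewens_loglik(c(1000), 1e-12), -1e-8)
  ## stability at metacommunity sizes of 1e10
  expect_true(is.finite(ewens_loglik(c(rep(1e7, 500), rep(1e4, 400)) *
                                       2.05, 50)))
})

test_that("point-mutation MLE satisfies the expected-richness score equation", {
  for (seed in 1:3) {
    s <- simulate_neutral_sad("point_mutation", list(theta = 20), J_M = 1e5,
                              seed = seed)
    f <- fit_pms(s)
    expect_equal(ewens_expected_richness(f$theta, s$J_M), s$S,
                 tolerance = 1e-4)
    ## recovery within 3 SE (observed information of the Ewens likelihood)
    h <- 1e-3
    ll <- function(t) ewens_loglik(s, t)
    info <- -(ll(f$theta + h) - 2 * ll(f$theta) + ll(f$theta - h)) / h^2
    expect_lt(abs(f$theta - 20), 3 / sqrt(info))
  }
  ## single species: boundary reported
  f1 <- fit_pms(metacommunity_sad(50))
  expect_true(f1$boundary)
  expect_lt(f1$theta, 1e-6)
})

test_that("the expected Ewens SAD matches its richness identity and the urn", {
  for (th in c(1, 5)) for (J in c(20, 200)) {
    expect_equal(sum(pm_expected_sad(th, J, seq_len(J))),
                 ewens_expected_richness(th, J), tolerance = 1e-6)
  }
  expect_equal(pm_expected_sad(3, 1, 1), 1, tolerance = 1e-12)

  ## Monte-Carlo octaves of the urn at theta = 5, J_M = 1000
  B <- 300
  octs <- matrix(0, B, 10)
  for (b in seq_len(B)) {
    s <- simulate_neutral_sad("point_mutation", list(theta = 5), J_M = 1000,
                              seed = 1000 + b)
    oc <- s$octaves
    octs[b, seq_along(oc)] <- oc
  }
  eo <- expected_octaves(function(n) pm_expected_sad(5, 1000, n), 1000, 10)
  for (j in 1:8) {
    mc_se <- sd(octs[, j]) / sqrt(B)
    expect_lt(abs(mean(octs[, j]) - eo[j]), 3 * mc_se + 1e-8)
  }
})

test_that("the random-fission equilibrium is normalized and theta tracks S", {
  ## brute force over all partitions at small J_M
  for (J in c(6, 8)) for (th in c(1, 3)) {
    tot <- sum(vapply(enum_partitions(J),
                      function(p) exp(rf_equilibrium_logprob(p, th)), 0))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  ## stable in log space at J_M = 1e9 and theta-hat close to S
  set.seed(5)
  n <- sort(rlnorm(300, 10, 2), decreasing = TRUE)
  n <- n / sum(n) * 1e9
  s <- metacommunity_sad(n)
  expect_true(is.finite(rf_equilibrium_logprob(s, 300)))
  f <- fit_rfs(s)
  expect_lt(abs(f$theta - s$S), 1)
  expect_true(is.finite(f$nu) && f$nu > 0 && f$nu < 1)
})

test_that("random-fission expected SAD integrates to the expected richness", {
  th <- 12; J <- 5000
  es <- rf_expected_sad(th, J, seq_len(J))
  w <- macroabund:::rf_count_weights(th, J)
  expect_equal(sum(es), sum(exp(w$logw) * w$S), tolerance = 1e-6)
})

test_that("protracted octaves approach the point-mutation limit for large beta", {
  th <- 40; J <- 1e6
  ## the limit is the logseries regime n << J_M, so compare octaves up to
  ## 2^12; beyond that the exact Ewens expectation carries finite-size
  ## corrections the limiting form does not
  eo_ps <- ps_expected_octaves(th, beta = (J - 1) / (1 + 1e-8), J, octaves = 12)
  eo_pm <- expected_octaves(function(n) pm_expected_sad(th, J, n), J, 12)
  expect_lt(max(abs(eo_ps / eo_pm - 1)), 0.005)
})

test_that("protracted least squares recovers parameters from its own octaves", {
  J <- 1e6
  eo <- ps_expected_octaves(50, beta = 1000, J)
  ## a nominal SAD supplies J_M; the fitted octaves are overridden
  f <- fit_ps(metacommunity_sad(rep(J / 100, 100)), octaves = eo)
  expect_equal(f$theta, 50, tolerance = 0.01)
  expect_equal(f$beta, 1000, tolerance = 0.01)
})

test_that("protracted expected SAD is finite and eventually decreasing", {
  es <- ps_expected_sad(30, 500, 1e6, 10^seq(0, 5.9, by = 0.1))
  expect_true(all(is.finite(es)))
  tail_part <- es[10^seq(0, 5.9, by = 0.1) > 1e3]
  expect_true(all(diff(tail_part) <= 0))
  expect_error(ps_expected_sad(30, 2e6, 1e6, 10), "beta")
})

test_that("Poisson-lognormal fit recovers simulated parameters", {
  s <- simulate_neutral_sad("poisson_lognormal",
                            list(meanlog = 3, sdlog = 1.5, S = 500), seed = 21)
  f <- fit_pln(s)
  expect_equal(f$meanlog, 3, tolerance = 0.25)   # ~3 SE at S = 500
  expect_equal(f$sdlog, 1.5, tolerance = 0.2)
  ## optimality: perturbations lower the composite likelihood
  base <- pln_loglik(s, f$meanlog, f$sdlog)
  expect_gt(base, pln_loglik(s, f$meanlog + 0.1, f$sdlog))
  expect_gt(base, pln_loglik(s, f$meanlog, f$sdlog * 1.1))
})

test_that("composite likelihood and information weights behave", {
  ## equal AICs share the weight equally
  expect_equal(akaike_weights(c(3, 3, 3)), rep(1 / 3, 3))
  w <- akaike_weights(c(0, 20))
  expect_equal(w, c(1, exp(-10)) / (1 + exp(-10)), tolerance = 1e-12)
  ## zero expected mass at an observed abundance is an error
  expect_error(composite_loglik(c(5, 2), c(0.5, 0), 10), "zero mass|zero")
  ## scaling every expected SAD leaves AIC differences unchanged
  s <- metacommunity_sad(c(40, 20, 10, 5, 2, 1))
  es <- pm_expected_sad(2, s$J_M, s$n)
  tot <- ewens_expected_richness(2, s$J_M)
  cl1 <- composite_loglik(s, es, tot)
  cl2 <- composite_loglik(s, 7 * es, 7 * tot)
  expect_equal(cl1, cl2, tolerance = 1e-10)
})

test_that("model comparison table carries weights that sum to one", {
  s <- simulate_neutral_sad("point_mutation", list(theta = 10), J_M = 5000,
                            seed = 31)
  fs <- fit_neutral(s, models = c("pms", "rfs", "pln"))
  expect_equal(sum(fs$table$weight), 1, tolerance = 1e-10)
  expect_equal(fs$table$AIC, -2 * fs$table$cloglik + 2 * fs$table$k)
})

test_that("speciation-rate conversions follow the model-specific relations", {
  expect_equal(speciation_rate("PMS", 52.3, 1.65e10), 3.18e-9, tolerance = 0.01)
  expect_error(speciation_rate("RFS", 100, 100), "outside")
  ## protracted round trip nu -> theta/beta -> nu
  set.seed(2)
  for (r in 1:20) {
    J <- 10^runif(1, 5, 10)
    th <- 10^runif(1, 0.5, 2.5)
    beta <- 10^runif(1, 1, log10(J) - 1)
    nu <- speciation_rate("PS", th, J, beta = beta)
    back <- ps_rates(th, J, nu = nu)
    expect_equal(back$beta, beta, tolerance = 1e-10)
  }
})

test_that("species lifetimes follow the model-specific approximations", {
  expect_equal(species_lifetime("PMS", exp(-10)), 10, tolerance = 1e-12)
  expect_equal(species_lifetime("PMS", 3.18e-9), 19.6, tolerance = 0.01)
  expect_equal(species_lifetime("RFS", 3.87e-15), 1.61e7, tolerance = 0.01)
  pr <- ps_rates(113.5, 1.65e10, nu = 2.72e-13)
  expect_equal(species_lifetime("PS", pr$nu, tau_ps = pr$tau, mu_ps = pr$mu),
               2.19e5, tolerance = 0.01)
  ## monotone decreasing in nu
  nus <- 10^seq(-12, -2, by = 0.5)
  expect_true(all(diff(vapply(nus, function(v) species_lifetime("PMS", v), 0)) < 0))
  expect_true(all(diff(vapply(nus, function(v) species_lifetime("RFS", v), 0)) < 0))
  expect_error(species_lifetime("PS", 0.5, tau_ps = 10, mu_ps = 0.5), "\\(0, 1\\)")
})
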
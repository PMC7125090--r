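test_that("richness estimator combines known states and probabilities", {
  ## fully observed cell: known presences count exactly
  f <- fake_fit(d_hat = matrix(1, 3, 1), psi_hat = matrix(0.5, 3, 1),
                m = matrix(1, 3, 1), z = matrix(c(1, 1, 0), 3, 1), A = 10)
  expect_equal(unname(estimate_richness(f)), 2)
  ## all unknown: probabilities sum
  f <- fake_fit(matrix(1, 10, 1), matrix(0.5, 10, 1),
                matrix(0, 10, 1), matrix(NA, 10, 1), A = 10)
  expect_equal(unname(estimate_richness(f)), 5)
  ## mixed fixture: 1 + 0 + 0.2 + 0.9
  f <- fake_fit(matrix(1, 4, 1), matrix(c(0.3, 0.6, 0.2, 0.9), 4, 1),
                matrix(c(1, 1, 0, 0), 4, 1), matrix(c(1, 0, NA, NA), 4, 1),
                A = 10)
  expect_equal(unname(estimate_richness(f)), 2.1)
  expect_error(estimate_richness(f, cells = 99), "unknown cell")
})

test_that("abundance estimator weights density by area and occupancy", {
  f <- fake_fit(matrix(100, 1, 1), matrix(0.4, 1, 1),
                matrix(1, 1, 1), matrix(1, 1, 1), A = 50)
  expect_equal(unname(estimate_abundance(f)), 5000)
  ## known absence zeroes the contribution regardless of density
  f <- fake_fit(matrix(1e6, 1, 1), matrix(0.9, 1, 1),
                matrix(1, 1, 1), matrix(0, 1, 1), A = 50)
  expect_equal(unname(estimate_abundance(f)), 0)
  ## three-cell fixture against a hand-written sum
  d_hat <- matrix(c(10, 20, 5, 40, 2, 8), 2, 3)
  psi <- matrix(c(0.2, 0.9, 0.5, 0.1, 0.8, 0.3), 2, 3)
  m <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3)
  z <- matrix(c(1, NA, NA, 0, NA, NA), 2, 3)
  A <- c(10, 20, 5)
  f <- fake_fit(d_hat, psi, m, z, A)
  w <- ifelse(m == 1, z, psi)
  byhand <- as.numeric((d_hat * w) %*% A)
  expect_equal(unname(estimate_abundance(f)), byhand)
  ## aggregation identity: sum over singleton subsets equals the total
  parts <- sapply(1:3, function(j) estimate_abundance(f, cells = j))
  expect_equal(rowSums(parts), estimate_abundance(f), tolerance = 1e-12)
  expect_error(estimate_abundance(f, cells = integer(0)), "empty")
})

test_that("area of occupancy is an occupancy-weighted habitat sum", {
  f <- fake_fit(matrix(1, 2, 3), matrix(0.5, 2, 3),
                matrix(1, 2, 3), matrix(1, 2, 3), A = c(40, 50, 30))
  expect_equal(unname(estimate_aoo(f)), c(120, 120))
  ## zero occupancy estimate gives zero area
  f <- fake_fit(matrix(1, 1, 2), matrix(0, 1, 2),
                matrix(0, 1, 2), matrix(NA, 1, 2), A = c(10, 20))
  expect_equal(unname(estimate_aoo(f)), 0)
  ## bounded by the total habitat area, equality iff weight one everywhere
  set.seed(8)
  psi <- matrix(runif(12), 3, 4)
  f <- fake_fit(matrix(1, 3, 4), psi, matrix(0, 3, 4),
                matrix(NA, 3, 4), A = runif(4, 5, 50))
  expect_true(all(estimate_aoo(f) <= sum(f$cells$A) + 1e-12))
  expect_true(all(estimate_aoo(f) < sum(f$cells$A)))
})

test_that("Shannon entropy uses natural logs and ignores zero classes", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(5, 0, 0)), 0)
  expect_equal(shannon_entropy(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannon_entropy(c(0, 0)), "> 0")
  ## bounded by log of the number of positive classes
  set.seed(2)
  N <- rexp(30)
  expect_lte(shannon_entropy(N), log(30))
})

test_that("validation metrics follow their definitions", {
  obs <- c(2, 5, 9, 1)
  expect_equal(unname(validation_metrics(obs, obs)), c(0, 0, 1))
  vm <- validation_metrics(2 * obs, obs)
  expect_equal(unname(vm["bias"]), mean(obs))
  expect_equal(unname(vm["corr"]), 1, tolerance = 1e-12)
  expect_equal(unname(vm["rmse"]), sqrt(mean(obs^2)))
  expect_error(validation_metrics(1, 2), "at least two")
})

test_that("red-list summary flags small-range unlisted native species", {
  ab <- c(a = 1e6, b = 2e4, c = 3e3, d = 1e2)
  ao <- c(a = 500, b = 12, c = 1, d = 800)
  cat_ <- c("NC", "NC", "VU", "CR")
  out <- redlist_summary(ab, ao, cat_)
  expect_equal(out$flagged, "b")                    # NC with 12 km^2 < 20
  expect_equal(out$table$n[out$table$category == "NC"], 2L)
  ## introduced species are excluded before flagging
  out2 <- redlist_summary(ab, ao, cat_, introduced = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out2$flagged, character(0))
  expect_error(redlist_summary(ab, ao, c("NC", "NC", "XX", "CR")), "category")
})
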
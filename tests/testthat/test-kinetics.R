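test_that("pure dissolution with no hydrolysis follows the closed form", {
  p <- cascade_params(M0 = 50, k_d = 0.1, k1 = 0, k2 = 0, f0 = 0)
  grid <- seq(0, 100, by = 1)
  tr <- simulate_cascade(p, grid)
  expect_equal(tr$A, 50 * (1 - exp(-0.1 * grid)), tolerance = 1e-12)
  expect_equal(tr$B, rep(0, length(grid)))
  expect_equal(tr$C, rep(0, length(grid)))
})

test_that("fully dissolved cascade matches the Bateman solution and an RK4 oracle", {
  A0 <- 100
  p <- cascade_params(M0 = A0, k_d = 0.08, k1 = 0.02, k2 = 0.01, f0 = 1)
  grid <- seq(0, 240, by = 5)
  tr <- simulate_cascade(p, grid, method = "closed")
  expect_equal(tr$A[grid == 50], A0 * exp(-1), tolerance = 1e-12)
  bateman_B <- A0 * 0.02 / (0.01 - 0.02) * (exp(-0.02 * grid) - exp(-0.01 * grid))
  expect_equal(tr$B, bateman_B, tolerance = 1e-12)
  oracle <- cascade_rk4(p, grid, step = 0.01)
  expect_lt(max(abs(tr$B - oracle$B) / pmax(oracle$B, 1e-8)), 1e-6)
  expect_lt(max(abs(tr$C - oracle$C) / pmax(oracle$C, 1e-8)), 1e-6)
})

test_that("mass is conserved at every grid point", {
  set.seed(7)
  grid <- seq(0, 240, by = 2)
  for (i in 1:10) {
    p <- cascade_params(M0 = runif(1, 10, 1000), k_d = runif(1, 0.01, 0.2),
                        k1 = runif(1, 0.001, 0.05), k2 = runif(1, 0.001, 0.05),
                        f0 = runif(1))
    tr <- simulate_cascade(p, grid)
    total <- tr$M + tr$A + tr$B + tr$C
    expect_lt(max(abs(total - p$M0)) / p$M0, 1e-9)
    trn <- simulate_cascade(p, grid, method = "numeric")
    totn <- trn$M + trn$A + trn$B + trn$C
    expect_lt(max(abs(totn - p$M0)) / p$M0, 1e-6)
  }
})

test_that("closed form and numeric integrator agree on random parameter draws", {
  set.seed(11)
  grid <- seq(0, 240, by = 4)
  for (i in 1:20) {
    repeat {
      k1 <- runif(1, 0.002, 0.06); k2 <- runif(1, 0.002, 0.06)
      kd <- runif(1, 0.02, 0.3)
      if (abs(k1 - k2) / max(k1, k2) > 0.05 &&
          abs(k1 - kd) / kd > 0.05 && abs(k2 - kd) / kd > 0.05) break
    }
    p <- cascade_params(M0 = 100, k_d = kd, k1 = k1, k2 = k2,
                        f0 = runif(1, 0, 0.9))
    a <- simulate_cascade(p, grid, method = "closed")
    b <- simulate_cascade(p, grid, method = "numeric")
    for (col in c("M", "A", "B", "C")) {
      expect_lt(max(abs(a[[col]] - b[[col]])) / p$M0, 1e-6)
    }
  }
})

test_that("the k1 == k2 degenerate case uses its own closed form and is correct", {
  p <- cascade_params(M0 = 80, k_d = 0.3, k1 = 0.02, k2 = 0.02, f0 = 1)
  grid <- seq(0, 200, by = 2)
  tr <- simulate_cascade(p, grid)
  expect_equal(tr$B, 80 * 0.02 * grid * exp(-0.02 * grid), tolerance = 1e-10)
  oracle <- cascade_rk4(p, grid, step = 0.01)
  expect_lt(max(abs(tr$B - oracle$B)) / 80, 1e-6)
  # ties with undissolved material left fall back to the integrator
  p2 <- cascade_params(M0 = 80, k_d = 0.3, k1 = 0.02, k2 = 0.02, f0 = 0.2)
  tr2 <- simulate_cascade(p2, grid)
  oracle2 <- cascade_rk4(p2, grid, step = 0.01)
  expect_lt(max(abs(tr2$B - oracle2$B)) / 80, 1e-6)
  expect_error(simulate_cascade(p2, grid, method = "closed"),
               class = "decoctr_parameter_error")
})

test_that("invalid cascade parameters are rejected", {
  expect_error(cascade_params(100, -0.1, 0.01, 0.01),
               class = "decoctr_parameter_error")
  expect_error(cascade_params(100, 0.1, 0.01, 0.01, f0 = 1.2),
               class = "decoctr_parameter_error")
  expect_error(cascade_params(100, 0.1, 0.01, 0.01, inhibition = 0),
               class = "decoctr_parameter_error")
  expect_error(simulate_cascade(cascade_params(1, 0.1, 0.01, 0.02),
                                c(3, 2, 1)),
               class = "decoctr_parameter_error")
})

test_that("hydrolysis inhibition on k2 never decreases the monoester", {
  grid <- seq(0, 240, by = 2)
  base <- simulate_cascade(cascade_params(100, 0.08, 0.02, 0.01,
                                          inhibition = 1), grid)
  prev <- base$B
  for (inh in c(1.5, 2, 4, 8)) {
    tr <- simulate_cascade(cascade_params(100, 0.08, 0.02, 0.01,
                                          inhibition = inh), grid)
    expect_true(all(tr$B - prev >= -1e-9))
    prev <- tr$B
  }
})

test_that("hydrolysis rates are recoverable from a noiseless monoester trace", {
  p <- cascade_params(M0 = 200, k_d = 0.08, k1 = 0.025, k2 = 0.008,
                      f0 = 0.15)
  grid <- seq(0, 240, by = 0.5)
  tr <- simulate_cascade(p, grid)
  est <- recover_cascade_rates(
    tibble::tibble(time_min = grid, value = tr$B), p)
  expect_lt(abs(est[["k1"]] - 0.025) / 0.025, 1e-3)
  expect_lt(abs(est[["k2"]] - 0.008) / 0.008, 1e-3)
})

test_that("biphasic intermediate rises then falls with one interior maximum", {
  grid <- seq(0, 240, by = 0.5)
  tr <- simulate_biphasic_intermediate(0.02, 0.01, 1000, grid)
  pk <- which.max(tr$value)
  expect_gt(pk, 1)
  expect_lt(pk, length(grid))
  d <- diff(tr$value)
  expect_true(all(d[seq_len(pk - 1)] > -1e-9))
  expect_true(all(d[pk:length(d)] < 1e-9))
  # no consumption: monotone non-decreasing
  tr0 <- simulate_biphasic_intermediate(0.02, 0, 1000, grid)
  expect_true(all(diff(tr0$value) >= -1e-9))
  # empty source pool: identically zero
  trz <- simulate_biphasic_intermediate(0.02, 0.01, 0, grid)
  expect_equal(trz$value, rep(0, length(grid)))
  # a multi-stage release cascade delays the peak
  trd <- simulate_biphasic_intermediate(0.05, 0.02, 1000, grid,
                                        release_rate = rep(0.05, 6))
  expect_gt(grid[which.max(trd$value)], grid[which.max(tr$value)] - 100)
  expect_gt(which.max(trd$value), 1)
})

test_that("conversion pair conserves material and respects zero conversion", {
  grid <- seq(0, 240, by = 1)
  pre <- cascade_params(M0 = 500, k_d = 0.08, k1 = 0, k2 = 0, f0 = 1)
  tr <- simulate_conversion_pair(pre, 0.01, grid, product0 = 100)
  expect_true(all(diff(tr$product) >= -1e-9))
  expect_equal(tr$precursor + tr$product, rep(600, length(grid)),
               tolerance = 1e-9)
  tr0 <- simulate_conversion_pair(pre, 0, grid, product0 = 100)
  expect_equal(tr0$product, rep(100, length(grid)))
})

test_that("stable compounds plateau after dissolution", {
  grid <- seq(0, 240, by = 1)
  const <- simulate_stable(100, 0, grid, f0 = 1)
  expect_equal(const$value, rep(100, length(grid)))
  tr <- simulate_stable(100, 0.12, grid, f0 = 0.1)
  expect_true(all(diff(tr$value) >= 0))
  # k_d = 0.12/min reaches 1 - exp(-6) = 99.75% of the plateau by 50 min
  expect_gt(tr$value[grid == 50] / 100, 0.99)
  expect_equal(tr$value[grid == 240], 100, tolerance = 1e-6)
})
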
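test_that("a single Gaussian is recovered essentially exactly", {
  x <- seq(0, 240, by = 0.5)
  eic <- tibble::tibble(time_min = x,
                        value = 100 * exp(-((x - 120) / 40)^2))
  fit <- fit_gaussian_sum(eic, n = 1)
  expect_gt(fit$r2, 1 - 1e-9)
  est <- fit$params
  expect_lt(abs(est[["a1"]] - 100) / 100, 1e-6)
  expect_lt(abs(est[["b1"]] - 120) / 120, 1e-6)
  expect_lt(abs(est[["c1"]] - 40) / 40, 1e-6)
})

test_that("a two-Gaussian sum is recovered to 1e-4 relative", {
  x <- seq(0, 240, by = 0.5)
  y <- 100 * exp(-((x - 60) / 30)^2) + 50 * exp(-((x - 180) / 40)^2)
  fit <- fit_gaussian_sum(tibble::tibble(time_min = x, value = y), n = 2)
  expect_gt(fit$r2, 1 - 1e-9)
  p <- fit$params
  ord <- order(p[c("b1", "b2")])
  a <- p[c("a1", "a2")][ord]; b <- p[c("b1", "b2")][ord]
  cc <- abs(p[c("c1", "c2")][ord])
  expect_lt(max(abs(a - c(100, 50)) / c(100, 50)), 1e-4)
  expect_lt(max(abs(b - c(60, 180)) / c(60, 180)), 1e-4)
  expect_lt(max(abs(cc - c(30, 40)) / c(30, 40)), 1e-4)
})

test_that("flat signals are flagged degenerate rather than fitted", {
  x <- seq(0, 100, by = 1)
  fit <- fit_gaussian_sum(tibble::tibble(time_min = x, value = rep(0, 101)), 1)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$r2))
  ff <- fit_fourier(tibble::tibble(time_min = x, value = rep(3.5, 101)), 2)
  expect_true(ff$degenerate)
  expect_equal(ff$params[["a0"]], 3.5)
  expect_true(all(abs(ff$params[c("a1", "b1", "a2", "b2")]) < 1e-8))
})

test_that("a pure cosine is recovered by the Fourier fit", {
  x <- seq(0, 240, by = 0.5)
  w_true <- 2 * pi / 240
  y <- 3 + 2 * cos(w_true * x)
  fit <- fit_fourier(tibble::tibble(time_min = x, value = y), n = 1)
  expect_gt(fit$r2, 1 - 1e-9)
  expect_lt(abs(fit$params[["a0"]] - 3), 1e-6)
  expect_lt(abs(fit$params[["a1"]] - 2) / 2, 1e-5)
  expect_lt(abs(fit$params[["w"]] - w_true) / w_true, 1e-5)
})

test_that("a rising aminoalcohol-style curve is well described by FOURIER2", {
  grid <- seq(0, 240, by = 0.2)
  sc <- build_zwd_scenario("CO", grid = grid)
  v <- sc$trace[[which(sc$id == "mesaconine")]]$value
  fit <- fit_fourier(tibble::tibble(time_min = grid, value = v), n = 2)
  expect_gt(fit$r2, 0.99)
})

test_that("model selection prefers fit quality, then parsimony, order-free", {
  x <- seq(0, 240, by = 1)
  y <- 80 * exp(-((x - 100) / 50)^2)
  eic <- tibble::tibble(time_min = x, value = y)
  g1 <- fit_gaussian_sum(eic, 1)
  f1 <- fit_fourier(eic, 1)
  f2 <- fit_fourier(eic, 2)
  expect_identical(select_model(list(g1, f1, f2))$model, "GAUSSN")
  expect_identical(select_model(list(f2, f1, g1))$model, "GAUSSN")
  # exact ties fall to the smaller parameter count
  const <- tibble::tibble(time_min = x, value = rep(5, length(x)))
  fits <- list(fit_fourier(const, 2), fit_gaussian_sum(const, 1),
               fit_fourier(const, 1))
  sel <- select_model(fits)
  expect_equal(sel$n_params, min(vapply(fits, function(f) f$n_params, 1)))
  expect_identical(select_model(rev(fits))$n_params, sel$n_params)
  expect_error(select_model(list(NULL, NULL)), class = "decoctr_fit_error")
})

test_that("percent change reproduces the worked arithmetic and its inverse law", {
  expect_equal(round(percent_change(7.36e3, 3.48e3), 1), -52.7)
  expect_equal(round(percent_change(3.32e3, 2.26e4), 1), 580.7)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 5), class = "decoctr_undefined_error")
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.1, 100); b <- runif(1, 0.1, 100)
    p_ab <- percent_change(a, b); p_ba <- percent_change(b, a)
    expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1, tolerance = 1e-12)
  }
})

test_that("kinetic summaries classify trends and plateaus", {
  x <- seq(0, 240, by = 0.5)
  rising <- tibble::tibble(time_min = x, value = 10 + x)
  s <- summarize_kinetics(rising)
  expect_identical(s$trend, "RISING")
  expect_equal(s$peak_time, 240)
  const <- tibble::tibble(time_min = x, value = rep(8, length(x)))
  s2 <- summarize_kinetics(const)
  expect_identical(s2$trend, "STABLE")
  expect_equal(c(s2$plateau_start, s2$plateau_end), c(0, 240))
  # the calibrated tannin intermediate is biphasic with a late peak
  sc <- build_zwd_scenario("SINGLE", grid = test_grid())
  pgg <- sc$trace[[which(sc$id == "pentagalloylglucose")]]
  s3 <- summarize_kinetics(pgg)
  expect_identical(s3$trend, "BIPHASIC")
  expect_gt(s3$peak_time, 160)
  expect_lt(s3$peak_time, 200)
  expect_gte(s3$peak_value, max(s3$initial, s3$final))
})

test_that("system comparison produces the reported ratio conventions", {
  x <- seq(0, 240, by = 1)
  curve <- tibble::tibble(time_min = x, value = 10 + x / 10)
  s <- summarize_kinetics(curve)
  cmp <- compare_modes(s, s)
  expect_equal(cmp$peak_ratio, 1)
  expect_equal(cmp$rate_ratio, 1)
  expect_true(cmp$trend_concordant)
  zero <- summarize_kinetics(
    tibble::tibble(time_min = x, value = rep(0, length(x))))
  expect_true(is.na(compare_modes(zero, s)$peak_ratio))
})

test_that("fit objects expose tidy, glance and prediction interfaces", {
  x <- seq(0, 240, by = 1)
  eic <- tibble::tibble(time_min = x, value = 50 * exp(-((x - 90) / 60)^2))
  fit <- fit_gaussian_sum(eic, 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_identical(gl$model, "GAUSSN")
  expect_equal(predict(fit, 90), 50, tolerance = 1e-4)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
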
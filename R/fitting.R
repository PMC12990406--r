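fit_value_column <- function(eic) {
  for (nm in c("smoothed", "value", "intensity", "raw")) {
    if (nm %in% names(eic)) return(nm)
  }
  abort("No intensity column found (expected one of smoothed/value/intensity/raw).",
        class = "decoctr_parameter_error")
}

gauss_sum_eval <- function(pars, x, n) {
  a <- pars[seq_len(n)]
  b <- pars[n + seq_len(n)]
  cc <- pars[2 * n + seq_len(n)]
  y <- 0
  for (i in seq_len(n)) y <- y + a[i] * exp(-((x - b[i]) / cc[i])^2)
  unname(y)
}

fourier_eval <- function(pars, x, n) {
  a0 <- pars[1]; w <- pars[2]
  y <- rep(a0, length(x))
  for (i in seq_len(n)) {
    y <- y + pars[2 * i + 1] * cos(i * w * x) + pars[2 * i + 2] * sin(i * w * x)
  }
  unname(y)
}

new_kinetic_fit <- function(model, n, params, x, y, fitted, converged,
                            degenerate = FALSE) {
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  npar <- length(params)
  nobs <- length(y)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  adj <- if (!is.na(r2) && nobs > npar + 1) {
    1 - (1 - r2) * (nobs - 1) / (nobs - npar - 1)
  } else r2
  structure(list(model = model, n = n, params = params,
                 r2 = r2, adj_r2 = adj, rmse = sqrt(sse / nobs),
                 sse = sse, nobs = nobs, n_params = npar,
                 converged = converged, degenerate = degenerate,
                 curve = tibble(time_min = x, value = y, fitted = fitted)),
            class = "kinetic_fit")
}

#' Fit a Gaussian-sum kinetic model
#'
#' Nonlinear least squares of
#' \deqn{y = \sum_{i=1}^{n} a_i \exp\{-((x - b_i)/c_i)^2\}}
#' to an intensity time series, the peak-shaped curve family used to
#' describe decoction kinetics.  Initialisation is data driven (local maxima
#' seed the centres `b_i`, half-range widths seed `c_i`) and the optimiser is
#' restarted from a fixed set of perturbed starts, so the fit is
#' deterministic.
#'
#' @param eic Tibble with `time_min` and an intensity column (`smoothed`,
#'   `value`, `intensity` or `raw`; the first present is used).
#' @param n Number of Gaussian components (1--4); needs `>= 3n + 1` points.
#' @param restarts Number of perturbed restarts of the base initialisation.
#'
#' @return A `kinetic_fit` object (see [tidy()], [glance()],
#'   [predict.kinetic_fit()], [autoplot.kinetic_fit()]).
#' @export
fit_gaussian_sum <- function(eic, n = 2L, restarts = 5L) {
  if (!n %in% 1:4) {
    abort("Gaussian-sum order `n` must be in 1..4.",
          class = "decoctr_parameter_error")
  }
  col <- fit_value_column(eic)
  x <- eic$time_min; y <- eic[[col]]
  if (length(x) < 3 * n + 1) {
    abort("Need at least 3n + 1 points to fit a Gaussian sum.",
          class = "decoctr_parameter_error")
  }
  if (sd(y) == 0) {
    # flat signal: a Gaussian sum degenerates; report amplitude ~ level
    pars <- c(rep(y[1] / n, n), seq(min(x), max(x), length.out = n + 2)[2:(n + 1)],
              rep(diff(range(x)) * 10, n))
    names(pars) <- c(paste0("a", 1:n), paste0("b", 1:n), paste0("c", 1:n))
    return(new_kinetic_fit("GAUSSN", n, pars, x, y,
                           gauss_sum_eval(pars, x, n),
                           converged = TRUE, degenerate = TRUE))
  }
  span <- diff(range(x))
  peaks <- local_maxima(x, y, n)
  base <- c(y[peaks], x[peaks], rep(span / (2 * n), n))
  lower <- c(rep(-Inf, 2 * n), rep(span * 1e-4, n))
  starts <- list(base)
  for (r in seq_len(restarts)) {
    with_seed(1000 + r, {
      jit <- base
      jit[seq_len(n)] <- jit[seq_len(n)] * runif(n, 0.6, 1.4)
      jit[n + seq_len(n)] <- jit[n + seq_len(n)] + runif(n, -0.15, 0.15) * span
      jit[2 * n + seq_len(n)] <- jit[2 * n + seq_len(n)] * runif(n, 0.4, 2.5)
      starts[[r + 1]] <- jit
    })
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st,
                         fn = function(p) y - gauss_sum_eval(p, x, n),
                         lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance <= 1e-18 * sum(y^2)) break
  }
  if (is.null(best)) {
    abort("Gaussian-sum fit failed to converge from all starts.",
          class = "decoctr_fit_error")
  }
  pars <- best$par
  names(pars) <- c(paste0("a", 1:n), paste0("b", 1:n), paste0("c", 1:n))
  new_kinetic_fit("GAUSSN", n, pars, x, y, gauss_sum_eval(pars, x, n),
                  converged = best$info %in% 1:4)
}

local_maxima <- function(x, y, n) {
  ys <- boxcar_smooth(y, points = min(9L, 2L * (length(y) %/% 4L) + 1L))
  idx <- which(diff(sign(diff(ys))) < 0) + 1L
  idx <- idx[order(ys[idx], decreasing = TRUE)]
  if (length(idx) < n) {
    extra <- round(seq(1, length(x), length.out = n + 2))[2:(n + 1)]
    idx <- unique(c(idx, extra, which.max(ys)))
  }
  head(idx, n)
}

#' Fit a Fourier-series kinetic model
#'
#' Least squares of
#' \deqn{y = a_0 + \sum_{i=1}^{n} a_i \cos(i w x) + b_i \sin(i w x)}
#' with a single fundamental frequency `w > 0`.  Given `w` the coefficients
#' are linear and solved exactly; `w` itself is profiled over a deterministic
#' candidate grid (anchored at one period per acquisition window and at the
#' dominant discrete-Fourier frequency of the detrended signal) and refined
#' by a bounded 1-D optimisation.
#'
#' @inheritParams fit_gaussian_sum
#' @param n Number of harmonics (1--3); needs `>= 2n + 3` points.
#'
#' @return A `kinetic_fit` object.
#' @export
fit_fourier <- function(eic, n = 2L) {
  if (!n %in% 1:3) {
    abort("Fourier order `n` must be in 1..3.",
          class = "decoctr_parameter_error")
  }
  col <- fit_value_column(eic)
  x <- eic$time_min; y <- eic[[col]]
  if (length(x) < 2 * n + 3) {
    abort("Need at least 2n + 3 points to fit a Fourier series.",
          class = "decoctr_parameter_error")
  }
  span <- diff(range(x))
  w0 <- 2 * pi / span
  if (sd(y) == 0) {
    pars <- c(a0 = mean(y), w = w0,
              setNames(rep(0, 2 * n),
                       paste0(rep(c("a", "b"), n), rep(1:n, each = 2))))
    return(new_kinetic_fit("FOURIERN", n, pars, x, y,
                           fourier_eval(pars, x, n),
                           converged = TRUE, degenerate = TRUE))
  }
  solve_w <- function(w) {
    X <- matrix(1, nrow = length(x), ncol = 2 * n + 1)
    for (i in seq_len(n)) {
      X[, 2 * i] <- cos(i * w * x)
      X[, 2 * i + 1] <- sin(i * w * x)
    }
    fit <- lm.fit(X, y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    list(coef = cf, rss = sum(fit$residuals^2))
  }
  cand <- w0 * seq(0.2, 3, by = 0.1)
  dt <- median(diff(x))
  if (is.finite(dt) && dt > 0) {
    spec <- Mod(fft(y - mean(y)))[seq_len(floor(length(y) / 2))]
    k <- which.max(spec[-1])  # skip the zero-frequency bin
    cand <- c(cand, 2 * pi * k / (length(y) * dt))
  }
  rss <- vapply(cand, function(w) solve_w(w)$rss, numeric(1))
  wb <- cand[which.min(rss)]
  opt <- optimize(function(w) solve_w(w)$rss,
                  interval = c(wb / 1.6, wb * 1.6), tol = 1e-10)
  w <- opt$minimum
  sol <- solve_w(w)
  pars <- c(a0 = unname(sol$coef[1]), w = w)
  for (i in seq_len(n)) {
    pars[paste0("a", i)] <- unname(sol$coef[2 * i])
    pars[paste0("b", i)] <- unname(sol$coef[2 * i + 1])
  }
  new_kinetic_fit("FOURIERN", n, pars, x, y, fourier_eval(pars, x, n),
                  converged = TRUE)
}

#' Select the best kinetic fit
#'
#' Picks the fit with the highest adjusted R-squared; ties (within 1e-6) are
#' broken by the smaller parameter count, then deterministically by model
#' family and order, so the selection does not depend on the order in which
#' fits are supplied.  Fits whose R-squared is undefined (zero-variance
#' data) rank below any scored fit and fall back to the parsimony rule.
#'
#' @param fits A list of `kinetic_fit` objects (failed attempts may be
#'   `NULL`).
#'
#' @return The selected `kinetic_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  fits <- Filter(function(f) inherits(f, "kinetic_fit"), fits)
  if (!length(fits)) {
    abort("No successful fits to select from.", class = "decoctr_fit_error")
  }
  adj <- vapply(fits, function(f) {
    if (is.na(f$adj_r2)) -Inf else f$adj_r2
  }, numeric(1))
  npar <- vapply(fits, function(f) f$n_params, numeric(1))
  model <- vapply(fits, function(f) f$model, character(1))
  ord <- vapply(fits, function(f) f$n, numeric(1))
  top <- max(adj)
  cand <- which(if (is.finite(top)) adj >= top - 1e-6 else adj == top)
  cand <- cand[order(npar[cand], model[cand], ord[cand])]
  fits[[cand[1]]]
}

#' Signed percent change
#'
#' `100 * (final - reference) / reference`; the sign conveys direction
#' (a decline from 7360 to 3480 is -52.7).
#'
#' @param reference Reference value(s), strictly positive.
#' @param final Final value(s).
#'
#' @return Signed percent change (full precision; round for display).
#' @export
#' @examples
#' percent_change(7.36e3, 3.48e3)
percent_change <- function(reference, final) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    abort("`reference` must be strictly positive.",
          class = "decoctr_undefined_error")
  }
  100 * (final - reference) / reference
}

#' @export
print.kinetic_fit <- function(x, ...) {
  fam <- if (x$model == "GAUSSN") "Gaussian sum" else "Fourier series"
  cat("<kinetic_fit> ", fam, " (n = ", x$n, "), ", x$nobs, " points\n",
      sep = "")
  cat("  r2 = ", format(x$r2, digits = 6), ", adj r2 = ",
      format(x$adj_r2, digits = 6), ", rmse = ",
      format(x$rmse, digits = 4), "\n", sep = "")
  if (x$degenerate) cat("  flagged degenerate (zero-variance signal)\n")
  invisible(x)
}

#' Evaluate a fitted kinetic curve
#'
#' @param object A `kinetic_fit`.
#' @param newdata Optional numeric vector of times (minutes) or a data frame
#'   with a `time_min` column; defaults to the fitting grid.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) {
    object$curve$time_min
  } else if (is.data.frame(newdata)) {
    newdata$time_min
  } else {
    newdata
  }
  if (object$model == "GAUSSN") {
    gauss_sum_eval(object$params, t, object$n)
  } else {
    fourier_eval(object$params, t, object$n)
  }
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted coefficient.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row goodness-of-fit summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(model = x$model, order = x$n, r2 = x$r2, adj_r2 = x$adj_r2,
         rmse = x$rmse, nobs = x$nobs, n_params = x$n_params,
         converged = x$converged, degenerate = x$degenerate)
}

#' Plot a kinetic fit
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot: observed points and the fitted curve.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$time_min)) +
    geom_point(aes(y = .data$value), size = 0.4, alpha = 0.4) +
    geom_line(aes(y = .data$fitted), colour = "#2166ac", linewidth = 0.8) +
    labs(x = "Decoction time (min)", y = "Signal intensity",
         title = sprintf("%s fit (n = %d), adj r2 = %.5f",
                         object$model, object$n, object$adj_r2)) +
    theme_minimal()
}

#' Fit both curve families and keep the best
#'
#' Convenience wrapper running [fit_gaussian_sum()] over `gauss_orders` and
#' [fit_fourier()] over `fourier_orders`, then applying [select_model()].
#'
#' @inheritParams fit_gaussian_sum
#' @param gauss_orders Gaussian orders to try.
#' @param fourier_orders Fourier orders to try.
#' @return The selected `kinetic_fit`.
#' @export
fit_kinetics <- function(eic, gauss_orders = 1:3, fourier_orders = 1:2,
                         restarts = 5L) {
  fits <- c(
    purrr::map(gauss_orders, function(n) {
      tryCatch(fit_gaussian_sum(eic, n, restarts = restarts),
               error = function(e) NULL)
    }),
    purrr::map(fourier_orders, function(n) {
      tryCatch(fit_fourier(eic, n), error = function(e) NULL)
    }))
  select_model(fits)
}

#' Kinetic summary of a fitted curve
#'
#' Reads the reporting quantities off a fitted (or ground-truth) curve over
#' an evaluation window: initial, peak and final values, signed percent
#' change, a trend label, and the plateau (high-efficacy range).  Trend
#' rules: an interior peak exceeding both endpoints by more than 15% is
#' `BIPHASIC`; otherwise a percent change below 10% in magnitude is
#' `STABLE`; otherwise the sign of the change gives `RISING`/`DECLINING`.
#' The plateau is the longest interval on which the curve stays within a
#' fraction `delta` of its window maximum while the relative slope
#' `|y'(t)/y(t)|` stays below `s_max`.
#'
#' @param fit A `kinetic_fit`, or a tibble with `time_min` and a value
#'   column (a ground-truth trace).
#' @param window Numeric `c(start, end)` in minutes; defaults to the data
#'   range.
#' @param delta Plateau band fraction (default 0.10).
#' @param s_max Maximum relative slope inside the plateau, per minute
#'   (default 0.001, i.e. 0.1% per minute).
#' @param reference `"initial"` (default) or `"peak"`: the value percent
#'   change is measured from.
#' @param dt Evaluation grid spacing in minutes.
#'
#' @return One-row tibble: `initial`, `peak_value`, `peak_time`, `final`,
#'   `pct_change`, `trend`, `plateau_start`, `plateau_end`, `reliable`.
#' @export
summarize_kinetics <- function(fit, window = NULL, delta = 0.10,
                               s_max = 0.001,
                               reference = c("initial", "peak"), dt = 0.2) {
  reference <- match.arg(reference)
  if (inherits(fit, "kinetic_fit")) {
    rng <- range(fit$curve$time_min)
    if (is.null(window)) window <- rng
    t <- seq(window[1], window[2], by = dt)
    y <- predict(fit, t)
    reliable <- !fit$degenerate
  } else {
    stopifnot(is.data.frame(fit), "time_min" %in% names(fit))
    col <- fit_value_column(fit)
    if (is.null(window)) window <- range(fit$time_min)
    t <- seq(window[1], window[2], by = dt)
    y <- approx(fit$time_min, fit[[col]], xout = t, rule = 2,
                ties = "ordered")$y
    reliable <- TRUE
  }
  initial <- y[1]; final <- y[length(y)]
  pk <- which.max(y)
  peak_value <- y[pk]; peak_time <- t[pk]
  pct <- if (reference == "initial" && initial > 0) {
    percent_change(initial, final)
  } else if (reference == "peak" && peak_value > 0) {
    percent_change(peak_value, final)
  } else NA_real_
  interior <- pk > 1 && pk < length(y)
  biphasic <- interior && peak_value > 1.15 * max(initial, final)
  trend <- if (biphasic) {
    "BIPHASIC"
  } else if (!is.na(pct) && abs(pct) < 10) {
    "STABLE"
  } else if (is.na(pct)) {
    "STABLE"
  } else if (pct > 0) "RISING" else "DECLINING"
  slope <- c(diff(y) / dt, 0)
  slope[length(slope)] <- slope[length(slope) - 1]
  rel_slope <- abs(slope) / pmax(abs(y), 1e-12)
  ok <- y >= (1 - delta) * peak_value & rel_slope < s_max
  run <- rle(ok)
  plateau_start <- plateau_end <- NA_real_
  if (any(run$values)) {
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    best <- which(run$values)[which.max(run$lengths[run$values])]
    plateau_start <- t[starts[best]]
    plateau_end <- t[ends[best]]
  }
  tibble(initial = initial, peak_value = peak_value, peak_time = peak_time,
         final = final, pct_change = pct, trend = trend,
         plateau_start = plateau_start, plateau_end = plateau_end,
         reliable = reliable)
}

#' Compare single- and co-decoction kinetics of one compound
#'
#' @param summary_single,summary_co One-row tibbles from
#'   [summarize_kinetics()] for the single- and co-decoction systems.
#' @param compound_id Optional compound identifier carried into the output.
#'
#' @return One-row tibble with per-system initial/peak/final values and
#'   percent changes, `peak_ratio` (co-decoction peak over single-decoction
#'   peak), `rate_ratio` (magnitude of the single-decoction percent change
#'   over the co-decoction one), and `trend_concordant`.  Ratios with a
#'   non-positive denominator are `NA`.
#' @export
compare_modes <- function(summary_single, summary_co, compound_id = NA_character_) {
  s <- summary_single; co <- summary_co
  peak_ratio <- if (isTRUE(s$peak_value > 0)) co$peak_value / s$peak_value else NA_real_
  rate_ratio <- if (isTRUE(abs(co$pct_change) > 0)) {
    abs(s$pct_change) / abs(co$pct_change)
  } else NA_real_
  tibble(compound_id = compound_id,
         initial_single = s$initial, peak_single = s$peak_value,
         final_single = s$final, pct_change_single = s$pct_change,
         trend_single = s$trend,
         initial_co = co$initial, peak_co = co$peak_value,
         final_co = co$final, pct_change_co = co$pct_change,
         trend_co = co$trend,
         peak_ratio = peak_ratio, rate_ratio = rate_ratio,
         trend_concordant = identical(s$trend, co$trend))
}
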
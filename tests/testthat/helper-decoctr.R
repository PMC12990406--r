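# Shared fixtures built in code.

# Coarse grid used by most scenario-level tests (0.5-min spacing keeps the
# numeric chains fast while resolving every anchor time).
test_grid <- function(dt = 0.5) seq(0, 240, by = dt)

# Ground-truth curves of one system as a long intensity tibble.
scenario_curves <- function(system, grid = test_grid()) {
  sc <- build_zwd_scenario(system, grid = grid)
  dplyr::bind_rows(lapply(seq_len(nrow(sc)), function(i) {
    tibble::tibble(compound_id = sc$id[i], time_min = grid,
                   value = sc$trace[[i]]$value * sc$response_factor[i])
  }))
}

# A tiny two-compound library reused by stream-level tests.
mini_library <- function() {
  tibble::tibble(
    id = c("cmpd_a", "cmpd_b"),
    name = c("Compound A", "Compound B"),
    herb = "TestHerb",
    class = c("STABLE_DISSOLUTION_ONLY", "HYDROLYSIS_PRODUCT_RISING"),
    ion_mode = "pos",
    mz = c(300, 450),
    response_factor = c(1, 2))
}

# Constant-concentration traces covering `duration_min` for mini_library().
mini_traces <- function(duration_min, values = c(1000, 500)) {
  t <- seq(0, duration_min, by = duration_min / 50)
  dplyr::bind_rows(
    tibble::tibble(compound_id = "cmpd_a", time_min = t, value = values[1]),
    tibble::tibble(compound_id = "cmpd_b", time_min = t, value = values[2]))
}

# RK4 oracle for the dissolution-hydrolysis cascade.
cascade_rk4 <- function(params, grid, step = 0.01, init = NULL) {
  if (is.null(init)) {
    init <- c(M = (1 - params$f0) * params$M0, A = params$f0 * params$M0,
              B = 0, C = 0)
  }
  deriv <- function(t, y, p) {
    list(c(-p$k_d * y[1],
           p$k_d * y[1] - p$k1 * y[2],
           p$k1 * y[2] - (p$k2 / p$inhibition) * y[3],
           (p$k2 / p$inhibition) * y[3]))
  }
  times <- sort(unique(c(seq(0, max(grid), by = step), grid)))
  sol <- deSolve::ode(y = unname(init), times = times, func = deriv,
                      parms = params, method = "rk4")
  idx <- match(grid, times)
  tibble::tibble(time_min = grid, M = sol[idx, 2], A = sol[idx, 3],
                 B = sol[idx, 4], C = sol[idx, 5])
}
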
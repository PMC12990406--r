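toxin_curve <- function(half_life = 40, peak_t = 30, level = 1000,
                        grid = seq(0, 240, by = 1)) {
  v <- ifelse(grid <= peak_t, level * grid / peak_t,
              level * exp(-log(2) * (grid - peak_t) / half_life))
  tibble::tibble(compound_id = "toxin", time_min = grid, value = v)
}

test_that("a single threshold crossing yields one safe interval to the end", {
  cv <- toxin_curve()
  sw <- safety_window(cv, "toxin", theta_safety = 0.5)
  # rising phase passes below threshold too (start of heating), so the
  # compliant set is [0, t_rise] plus the post-crossing tail
  expect_equal(nrow(sw), 2)
  expect_equal(sw$end[2], 240)
  expect_equal(sw$start[2], 30 + 40, tolerance = 0.03)
  never <- dplyr::mutate(cv, value = 900 + 0 * value)
  never$value[1] <- 1000
  sw2 <- safety_window(never, "toxin", theta_safety = 0.5)
  expect_equal(nrow(sw2), 0)
})

test_that("loosening the safety threshold never shrinks the safe window", {
  cv <- toxin_curve()
  prev <- 0
  for (theta in c(0.2, 0.4, 0.6, 0.8)) {
    sw <- safety_window(cv, "toxin", theta_safety = theta)
    size <- if (nrow(sw)) sum(sw$end - sw$start) else 0
    expect_gte(size, prev)
    prev <- size
  }
})

test_that("bioactivity gating and rewards behave at the extremes", {
  grid <- seq(0, 240, by = 1)
  curves <- dplyr::bind_rows(
    tibble::tibble(compound_id = "prim", time_min = grid,
                   value = 100 - 0.3 * grid),        # declining primary
    tibble::tibble(compound_id = "sec", time_min = grid,
                   value = rep(50, length(grid))))   # secondary at its max
  # early: primary within 10% of its max -> gate open, secondary at max
  expect_equal(bioactivity_score(curves, "prim", "sec", 0), 1)
  # late: primary has fallen far out of its plateau band -> gated to zero
  expect_equal(bioactivity_score(curves, "prim", "sec", 200), 0)
  expect_error(bioactivity_score(curves, character(0), "sec", 0),
               class = "decoctr_undefined_error")
})

test_that("flat secondaries make the earliest safe time optimal", {
  grid <- seq(0, 240, by = 1)
  curves <- dplyr::bind_rows(
    toxin_curve(),
    tibble::tibble(compound_id = "prim", time_min = grid,
                   value = rep(10, length(grid))),
    tibble::tibble(compound_id = "sec", time_min = grid,
                   value = rep(5, length(grid))))
  cfg <- sbtef_config(toxic_ids = "toxin", primary_active_ids = "prim",
                      secondary_active_ids = "sec")
  dec <- decide_endpoint(curves, cfg)
  expect_equal(dec$endpoint_min, 0)  # the pre-dissolution interval is safe
})

test_that("strictly rising secondaries push the endpoint to the gate's edge", {
  grid <- seq(0, 240, by = 1)
  # primary plateau band ends where the curve drops 10% below its max
  prim <- 100 * exp(-pmax(grid - 120, 0) * 0.004)
  curves <- dplyr::bind_rows(
    toxin_curve(),
    tibble::tibble(compound_id = "prim", time_min = grid, value = prim),
    tibble::tibble(compound_id = "sec", time_min = grid, value = 1 + grid))
  cfg <- sbtef_config(toxic_ids = "toxin", primary_active_ids = "prim",
                      secondary_active_ids = "sec")
  dec <- decide_endpoint(curves, cfg)
  band_edge <- 120 + log(1 / 0.9) / 0.004
  expect_equal(dec$endpoint_min, floor(band_edge), tolerance = 1)
  expect_true(dec$endpoint_min >= 70)
  # identical inputs give identical decisions
  dec2 <- decide_endpoint(curves, cfg)
  expect_identical(dec$endpoint_min, dec2$endpoint_min)
  expect_identical(dec$rationale, dec2$rationale)
})

test_that("tightening the plateau band cannot move a rising-primary endpoint earlier", {
  grid <- seq(0, 240, by = 1)
  curves <- dplyr::bind_rows(
    toxin_curve(),
    tibble::tibble(compound_id = "prim", time_min = grid,
                   value = 100 * (1 - exp(-grid / 60))),  # rising primary
    tibble::tibble(compound_id = "sec", time_min = grid,
                   value = rep(5, length(grid))))
  prev <- -Inf
  for (delta in c(0.3, 0.2, 0.1, 0.05)) {
    cfg <- sbtef_config(delta_bioactivity = delta, toxic_ids = "toxin",
                        primary_active_ids = "prim",
                        secondary_active_ids = "sec")
    dec <- decide_endpoint(curves, cfg)
    expect_gte(dec$endpoint_min, prev)
    prev <- dec$endpoint_min
  }
})

test_that("an always-toxic system raises a NoSafeEndpoint condition", {
  grid <- seq(0, 240, by = 1)
  curves <- dplyr::bind_rows(
    tibble::tibble(compound_id = "toxin", time_min = grid,
                   value = 1000 - grid),  # never below half its peak
    tibble::tibble(compound_id = "prim", time_min = grid, value = 1),
    tibble::tibble(compound_id = "sec", time_min = grid, value = 1))
  cfg <- sbtef_config(toxic_ids = "toxin", primary_active_ids = "prim",
                      secondary_active_ids = "sec")
  expect_error(decide_endpoint(curves, cfg),
               class = "decoctr_no_safe_endpoint")
})

test_that("energy and cost follow the linear model exactly", {
  cfg <- sbtef_config()
  expect_equal(energy_and_cost(0, cfg)$energy_kwh, 0)
  expect_equal(energy_and_cost(0, cfg)$cost, 0)
  # 0.3 kW for 150 min is 0.75 kWh
  expect_equal(energy_and_cost(150, cfg)$energy_kwh, 0.75)
  e1 <- energy_and_cost(80, cfg); e2 <- energy_and_cost(160, cfg)
  expect_equal(e2$energy_kwh, 2 * e1$energy_kwh)
  expect_equal(e2$cost, 2 * e1$cost)
  expect_error(energy_and_cost(-5, cfg), class = "decoctr_config_error")
})

test_that("endpoint decisions serialise and tidy cleanly", {
  grid <- seq(0, 240, by = 1)
  curves <- dplyr::bind_rows(
    toxin_curve(),
    tibble::tibble(compound_id = "prim", time_min = grid,
                   value = rep(10, length(grid))),
    tibble::tibble(compound_id = "sec", time_min = grid, value = 1 + grid))
  cfg <- sbtef_config(toxic_ids = "toxin", primary_active_ids = "prim",
                      secondary_active_ids = "sec")
  dec <- decide_endpoint(curves, cfg)
  td <- tidy(dec)
  expect_true(all(c("endpoint_min", "bioactivity", "energy_kwh", "cost")
                  %in% names(td)))
  expect_equal(td$energy_kwh, cfg$power_kw * dec$endpoint_min / 60)
  f <- withr::local_tempfile(fileext = ".json")
  write_endpoint_decision(dec, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$endpoint_min, dec$endpoint_min)
})
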
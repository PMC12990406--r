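#' SBTEF endpoint-decision configuration
#'
#' Settings for the five-dimensional endpoint schema: Safety, Bioactivity,
#' Time, Energy and Financial cost.  The default decision mode is strictly
#' lexicographic with safety first: the endpoint must lie inside the safety
#' window (all toxic compounds at or below `theta_safety` of their fitted
#' peak), bioactivity is then maximised, and among bioactivity maximisers
#' the earliest time is chosen -- which simultaneously minimises time,
#' energy (proportional to time at constant heater power) and cost.  An
#' optional numeric-weight mode is available via `weights`.
#'
#' @param theta_safety Toxic threshold as a fraction of each toxic
#'   compound's fitted peak (0 < theta < 1); default 0.5.
#' @param delta_bioactivity Plateau band fraction used to gate primary
#'   actives (0 < delta < 1); default 0.10.
#' @param power_kw Heater power in kilowatts; default 0.3.
#' @param cost_energy_per_kwh Energy price per kWh; default 0.6.
#' @param cost_labor_per_min Labour price per minute; default 0.5.
#' @param toxic_ids,primary_active_ids,secondary_active_ids Compound-id
#'   character vectors; `NULL` means derive them from the compound library
#'   classes (toxic = DIESTER_TOXIC, primary = MONOESTER_ACTIVE, secondary =
#'   CONVERSION_PRODUCT, HYDROLYSIS_PRODUCT_RISING and
#'   INTERMEDIATE_BIPHASIC).
#' @param weights `NULL` (default) for the lexicographic mode, or a named
#'   numeric vector `c(S=, B=, T=, E=, F=)` for the weighted-sum mode.
#' @param grid_dt_min Endpoint search resolution in minutes; default 1.
#'
#' @return An object of class `sbtef_config`.
#' @export
sbtef_config <- function(theta_safety = 0.5, delta_bioactivity = 0.10,
                         power_kw = 0.3, cost_energy_per_kwh = 0.6,
                         cost_labor_per_min = 0.5, toxic_ids = NULL,
                         primary_active_ids = NULL,
                         secondary_active_ids = NULL, weights = NULL,
                         grid_dt_min = 1) {
  if (theta_safety <= 0 || theta_safety >= 1) {
    abort("`theta_safety` must lie in (0, 1).",
          class = "decoctr_config_error")
  }
  if (delta_bioactivity <= 0 || delta_bioactivity >= 1) {
    abort("`delta_bioactivity` must lie in (0, 1).",
          class = "decoctr_config_error")
  }
  if (power_kw < 0 || cost_energy_per_kwh < 0 || cost_labor_per_min < 0) {
    abort("Power and cost rates must be non-negative.",
          class = "decoctr_config_error")
  }
  if (!is.null(weights)) {
    if (!all(c("S", "B", "T", "E", "F") %in% names(weights))) {
      abort("`weights` must be named with S, B, T, E, F.",
            class = "decoctr_config_error")
    }
  }
  structure(list(theta_safety = theta_safety,
                 delta_bioactivity = delta_bioactivity,
                 power_kw = power_kw,
                 cost_energy_per_kwh = cost_energy_per_kwh,
                 cost_labor_per_min = cost_labor_per_min,
                 toxic_ids = toxic_ids,
                 primary_active_ids = primary_active_ids,
                 secondary_active_ids = secondary_active_ids,
                 weights = weights, grid_dt_min = grid_dt_min),
            class = "sbtef_config")
}

default_role_ids <- function(config, library) {
  list(
    toxic = config$toxic_ids %||%
      library$id[library$class == "DIESTER_TOXIC"],
    primary = config$primary_active_ids %||%
      library$id[library$class == "MONOESTER_ACTIVE"],
    secondary = config$secondary_active_ids %||%
      library$id[library$class %in% c("CONVERSION_PRODUCT",
                                      "HYDROLYSIS_PRODUCT_RISING",
                                      "INTERMEDIATE_BIPHASIC")])
}

curve_matrix <- function(curves, ids, grid) {
  out <- vapply(ids, function(id) {
    cv <- curves %>% filter(.data$compound_id == id)
    if (!nrow(cv)) {
      abort(paste0("No fitted curve supplied for compound '", id, "'."),
            class = "decoctr_config_error")
    }
    if (min(cv$time_min) > grid[1] || max(cv$time_min) < grid[length(grid)]) {
      abort(paste0("Curve for '", id, "' does not cover the decision window."),
            class = "decoctr_config_error")
    }
    approx(cv$time_min, cv$value, xout = grid, ties = "ordered")$y
  }, numeric(length(grid)))
  matrix(out, nrow = length(grid), ncol = length(ids),
         dimnames = list(NULL, ids))
}

runs_to_intervals <- function(mask, grid) {
  run <- rle(mask)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  keep <- which(run$values)
  tibble(start = grid[starts[keep]], end = grid[ends[keep]])
}

#' Safety-compliant time window
#'
#' The set of times at which every toxic compound's curve is at or below
#' `theta_safety` times its own fitted peak, returned as disjoint closed
#' intervals on the decision grid.
#'
#' @param curves Long tibble of fitted curves: `compound_id`, `time_min`,
#'   `value`.
#' @param toxic_ids Compound ids treated as toxic.
#' @param theta_safety Threshold fraction of each toxic peak.
#' @param window Numeric `c(start, end)` in minutes.
#' @param grid_dt_min Grid resolution in minutes.
#'
#' @return Tibble of intervals (`start`, `end`); zero rows when the window
#'   is never safe.
#' @export
safety_window <- function(curves, toxic_ids, theta_safety = 0.5,
                          window = c(0, 240), grid_dt_min = 1) {
  grid <- seq(window[1], window[2], by = grid_dt_min)
  if (!length(toxic_ids)) {
    warn("No toxic compounds configured; the whole window is treated as safe.")
    return(tibble(start = window[1], end = window[2]))
  }
  cm <- curve_matrix(curves, toxic_ids, grid)
  peaks <- apply(cm, 2, max)
  if (any(peaks <= 0)) {
    abort("Toxic curves must have positive peaks.",
          class = "decoctr_config_error")
  }
  mask <- rowSums(sweep(cm, 2, theta_safety * peaks, ">")) == 0
  runs_to_intervals(mask, grid)
}

in_intervals <- function(t, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (t >= intervals$start[i] & t <= intervals$end[i])
  }
  out
}

#' Bioactivity score at a decoction time
#'
#' Primary actives (monoester alkaloids) gate the score: it is 0 whenever
#' any of them sits outside its plateau band, i.e. below `(1 - delta)` of
#' its own curve maximum -- the high-efficacy range.  Inside the gate the
#' score is the mean over secondary actives (polyphenol hydrolysis products,
#' shogaols, zingerone, the tannin intermediate) of `curve(t) / max(curve)`,
#' rewarding later times while those products are still accumulating.
#'
#' @param curves Long tibble of fitted curves (`compound_id`, `time_min`,
#'   `value`).
#' @param primary_ids,secondary_ids Compound-id character vectors; both must
#'   be non-empty.
#' @param t Time(s) in minutes at which to score.
#' @param delta Plateau band fraction.
#' @param window Window over which curve maxima are taken.
#'
#' @return Numeric score(s) in \[0, 1\].
#' @export
bioactivity_score <- function(curves, primary_ids, secondary_ids, t,
                              delta = 0.10, window = c(0, 240)) {
  if (!length(primary_ids) || !length(secondary_ids)) {
    abort("Primary and secondary active lists must be non-empty.",
          class = "decoctr_undefined_error")
  }
  grid <- seq(window[1], window[2], by = min(1, diff(window) / 240))
  pm <- curve_matrix(curves, primary_ids, grid)
  sm <- curve_matrix(curves, secondary_ids, grid)
  pmax_ <- apply(pm, 2, max)
  smax_ <- apply(sm, 2, max)
  p_at <- curve_matrix(curves, primary_ids, sort(unique(t)))
  s_at <- curve_matrix(curves, secondary_ids, sort(unique(t)))
  idx <- match(t, sort(unique(t)))
  vapply(idx, function(i) {
    gate <- all(p_at[i, ] >= (1 - delta) * pmax_)
    if (!gate) return(0)
    mean(pmin(s_at[i, ] / pmax(smax_, 1e-12), 1))
  }, numeric(1))
}

#' Decide the optimal decoction endpoint (SBTEF)
#'
#' Applies the safety-first lexicographic rule: restrict to the safety
#' window, maximise the bioactivity score on the decision grid, and among
#' maximisers (within 1e-6) pick the earliest time, which also minimises
#' time, energy and cost.  When `config$weights` is supplied, a weighted
#' composite of the five normalised dimensions is maximised over the safety
#' window instead (safety remains a hard constraint).
#'
#' @param curves Long tibble of fitted curves: `compound_id`, `time_min`,
#'   `value`.
#' @param config An [sbtef_config()].
#' @param library Compound library used to derive default compound roles.
#' @param window Decision window `c(start, end)` in minutes.
#'
#' @return An `endpoint_decision` object with the chosen `endpoint_min`, the
#'   safety window, per-dimension scores at the endpoint and a rationale
#'   trail.  Errors with class `decoctr_no_safe_endpoint` when the safety
#'   window is empty.
#' @export
decide_endpoint <- function(curves, config = sbtef_config(),
                            library = zwd_compound_library(),
                            window = c(0, 240)) {
  stopifnot(inherits(config, "sbtef_config"))
  roles <- default_role_ids(config, library)
  rationale <- character(0)
  sw <- safety_window(curves, roles$toxic, config$theta_safety, window,
                      config$grid_dt_min)
  if (!nrow(sw)) {
    abort(paste0("No time in the window satisfies the safety threshold (",
                 "theta = ", config$theta_safety, "). Consider decocting ",
                 "longer or reviewing the threshold."),
          class = "decoctr_no_safe_endpoint")
  }
  rationale <- c(rationale, sprintf(
    "S: safety window(s) [%s] min where all toxic compounds (%s) are <= %.0f%% of their fitted peak.",
    paste(sprintf("%g-%g", sw$start, sw$end), collapse = ", "),
    paste(roles$toxic, collapse = ", "), 100 * config$theta_safety))
  grid <- seq(window[1], window[2], by = config$grid_dt_min)
  safe <- grid[in_intervals(grid, sw)]
  bio <- bioactivity_score(curves, roles$primary, roles$secondary, safe,
                           delta = config$delta_bioactivity, window = window)
  if (is.null(config$weights)) {
    best <- max(bio)
    cand <- safe[bio >= best - 1e-6]
    endpoint <- min(cand)
    rationale <- c(rationale, sprintf(
      "B: bioactivity maximised at score %.4f (primary gate: %s in plateau band; secondary reward: %s).",
      best, paste(roles$primary, collapse = ", "),
      paste(roles$secondary, collapse = ", ")),
      sprintf("T/E/F: earliest bioactivity maximiser chosen (%g min), minimising time, energy and cost.",
              endpoint))
  } else {
    tox <- curve_matrix(curves, roles$toxic, safe)
    toxfrac <- apply(sweep(tox, 2, apply(tox, 2, max), "/"), 1, max)
    span <- diff(window)
    comp <- config$weights[["S"]] * (1 - toxfrac) +
      config$weights[["B"]] * bio -
      config$weights[["T"]] * (safe - window[1]) / span -
      config$weights[["E"]] * (config$power_kw * safe / 60) -
      config$weights[["F"]] * (config$power_kw * safe / 60 *
                                 config$cost_energy_per_kwh +
                                 safe * config$cost_labor_per_min) /
        max(1e-12, config$power_kw * window[2] / 60 *
              config$cost_energy_per_kwh +
              window[2] * config$cost_labor_per_min)
    endpoint <- safe[which.max(comp)]
    rationale <- c(rationale,
                   sprintf("Weighted mode: composite maximised at %g min.",
                           endpoint))
  }
  ec <- energy_and_cost(endpoint, config)
  tox_at <- curve_matrix(curves, roles$toxic, c(window[1], endpoint))
  tox_peak <- apply(curve_matrix(curves, roles$toxic, grid), 2, max)
  scores <- tibble(
    toxic_fraction = max(tox_at[2, ] / tox_peak),
    bioactivity = bioactivity_score(curves, roles$primary, roles$secondary,
                                    endpoint,
                                    delta = config$delta_bioactivity,
                                    window = window),
    time_min = endpoint,
    energy_kwh = ec$energy_kwh,
    cost = ec$cost)
  structure(list(endpoint_min = endpoint, safe_window = sw,
                 scores = scores, rationale = rationale, config = config,
                 roles = roles, window = window),
            class = "endpoint_decision")
}

#' Energy and financial cost of decocting to an endpoint
#'
#' Energy is `power_kw * t / 60` kWh at constant heater power; cost is
#' energy times the energy price plus labour time at the labour rate.  Both
#' are strictly increasing in `t`.
#'
#' @param endpoint_min Endpoint time in minutes (>= 0).
#' @param config An [sbtef_config()].
#' @return One-row tibble with `energy_kwh` and `cost`.
#' @export
energy_and_cost <- function(endpoint_min, config = sbtef_config()) {
  if (any(endpoint_min < 0)) {
    abort("`endpoint_min` must be non-negative.",
          class = "decoctr_config_error")
  }
  energy <- config$power_kw * endpoint_min / 60
  tibble(energy_kwh = energy,
         cost = energy * config$cost_energy_per_kwh +
           endpoint_min * config$cost_labor_per_min)
}

#' @export
print.endpoint_decision <- function(x, ...) {
  cat("<endpoint_decision> optimal decoction endpoint:", x$endpoint_min,
      "min\n")
  cat("  safety window:",
      paste(sprintf("[%g, %g]", x$safe_window$start, x$safe_window$end),
            collapse = " U "), "min\n")
  cat(sprintf("  scores: toxic fraction %.3f | bioactivity %.3f | energy %.3f kWh | cost %.2f\n",
              x$scores$toxic_fraction, x$scores$bioactivity,
              x$scores$energy_kwh, x$scores$cost))
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' Tidy an endpoint decision
#'
#' @param x An `endpoint_decision`.
#' @param ... Unused.
#' @return One-row tibble of the endpoint and its per-dimension scores.
#' @method tidy endpoint_decision
#' @export
tidy.endpoint_decision <- function(x, ...) {
  dplyr::bind_cols(tibble(endpoint_min = x$endpoint_min,
                          safe_from = x$safe_window$start[1],
                          safe_to = x$safe_window$end[nrow(x$safe_window)]),
                   x$scores[, setdiff(names(x$scores), "time_min")])
}

#' Serialise an endpoint decision to JSON
#'
#' @param x An `endpoint_decision`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_endpoint_decision <- function(x, path) {
  jsonlite::write_json(
    list(endpoint_min = x$endpoint_min,
         safe_window = x$safe_window,
         scores = x$scores,
         rationale = x$rationale,
         roles = x$roles,
         config = unclass(x$config)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
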
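#' Calibration anchors for the Zhenwu Decoction scenario
#'
#' Published signal-intensity anchors (start, peak, end and timed point
#' values) for the monitored compounds in the single- and co-decoction
#' systems.  The scenario generator is calibrated by least squares so that
#' its traces, after response-factor scaling, pass within 5% of these
#' anchors; they also drive the worked percent-change examples.
#'
#' @return Tibble with columns `compound_id`, `system` (`SINGLE`/`CO`),
#'   `target` (`start`, `peak`, `end`, `at_time`), `time_min` (`NA` for
#'   `peak`) and `intensity`.
#' @export
zwd_anchors <- function() {
  out <- read.csv(system.file("extdata", "zwd_anchors.csv",
                              package = "decoctr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  as_tibble(out)
}

#' Published worked percent-change examples
#'
#' The intensity pairs behind the reported percent changes: each row names
#' the compound, the system, the convention (percent change from the
#' initial value, from the peak, or from a timed point to the peak), the
#' reference and final intensities, and the percentage as printed (one
#' decimal, or rounded to tens for the fastest riser).
#'
#' @return Tibble with columns `label`, `compound_id`, `system`,
#'   `convention`, `reference`, `final`, `printed_pct`.
#' @export
zwd_worked_examples <- function() {
  out <- read.csv(system.file("extdata", "zwd_worked_examples.csv",
                              package = "decoctr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  as_tibble(out)
}

#' Calibrated kinetic parameters of the Zhenwu Decoction scenario
#'
#' Each monitored compound in each system is generated as one observed
#' compartment of a linear first-order chain (`rates` and `init` are
#' semicolon-separated vectors, `observe` indexes the monitored
#' compartment), optionally modulated by a transient Gaussian loss factor
#' (`dip_*`) reproducing the mid-decoction dip of aconine in the
#' co-decoction matrix.  The tannin intermediate uses a multi-stage release
#' cascade, which produces its delayed sigmoidal rise.  The file is
#' produced once by least-squares calibration against [zwd_anchors()] and
#' versioned with the package.
#'
#' @return Tibble, one row per compound and system.
#' @export
zwd_scenario_params <- function() {
  out <- read.csv(system.file("extdata", "zwd_scenario_params.csv",
                              package = "decoctr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  as_tibble(out)
}

scenario_trace <- function(row, grid) {
  rates <- as.numeric(strsplit(row$rates, ";")[[1]])
  init <- as.numeric(strsplit(row$init, ";")[[1]])
  sol <- chain_solve(rates, init, grid)
  v <- sol[, row$observe]
  if (!is.na(row$dip_depth) && row$dip_depth > 0) {
    v <- v * (1 - row$dip_depth *
                exp(-((grid - row$dip_center) / row$dip_width)^2))
  }
  tibble(time_min = grid, value = pmax(v, 0))
}

#' Build the Zhenwu Decoction ground-truth scenario
#'
#' Generates noiseless concentration traces for every compound in the
#' bundled library in one decoction system, on the acquisition clock (5 Hz
#' by default, i.e. 0.2-second spacing over 240 min).  The traces are
#' deterministic; `seed` is accepted for interface symmetry with the
#' stochastic stages and does not alter the ground truth.
#'
#' @param system `"CO"` (all herbs together, default) or `"SINGLE"` (each
#'   herb decocted alone at the same concentration).
#' @param seed Unused by the deterministic generator; kept so scenario
#'   manifests can record one seed per stage.
#' @param grid Time grid in minutes; default `seq(0, 240, by = 1/300)`.
#' @param library Compound library tibble.
#' @param params Scenario parameter tibble (see [zwd_scenario_params()]).
#'
#' @return The library joined with a `system` column and a `trace` list
#'   column of tibbles `time_min`, `value` (concentration units; multiply
#'   by `response_factor` for intensity units).
#' @export
#' @examples
#' sc <- build_zwd_scenario("CO", grid = seq(0, 240, by = 1))
#' sc$trace[[1]]
build_zwd_scenario <- function(system = c("CO", "SINGLE"), seed = 1L,
                               grid = NULL,
                               library = zwd_compound_library(),
                               params = zwd_scenario_params()) {
  system <- match.arg(toupper(system), c("CO", "SINGLE"))
  if (is.null(grid)) grid <- seq(0, 240, by = 1 / 300)
  grid <- check_grid(grid)
  library <- validate_compound_library(library)
  pars <- params %>% filter(.data$system == !!system)
  missing <- setdiff(library$id, pars$compound_id)
  if (length(missing)) {
    abort(paste0("No scenario parameters for compound(s): ",
                 paste(missing, collapse = ", ")),
          class = "decoctr_config_error")
  }
  out <- library
  out$system <- system
  out$trace <- purrr::map(library$id, function(id) {
    row <- pars[pars$compound_id == id, , drop = FALSE]
    scenario_trace(row, grid)
  })
  out
}

#' Plot scenario traces
#'
#' @param scenario Output of [build_zwd_scenario()] (one or more systems
#'   row-bound together).
#' @param compounds Optional character vector of compound ids to show.
#' @return A ggplot faceted by compound, coloured by system.
#' @export
plot_scenario <- function(scenario, compounds = NULL) {
  df <- scenario %>% select("id", "system", "trace") %>%
    tidyr::unnest("trace")
  if (!is.null(compounds)) df <- df %>% filter(.data$id %in% compounds)
  ggplot(df, aes(x = .data$time_min, y = .data$value,
                 colour = .data$system)) +
    geom_line() +
    facet_wrap(~id, scales = "free_y") +
    labs(x = "Decoction time (min)", y = "Concentration (arb. units)") +
    theme_minimal()
}

#' Write scenario traces and a manifest to a directory
#'
#' One CSV (`time_min,value`) per compound, plus a YAML manifest recording
#' the system, seed and grid.
#'
#' @param scenario Output of [build_zwd_scenario()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_scenario <- function(scenario, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(nrow(scenario))) {
    f <- file.path(dir, paste0(scenario$id[i], "_",
                               tolower(scenario$system[i]), ".csv"))
    write.csv(scenario$trace[[i]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(scenario = "zwd", system = scenario$system[1],
                   seed = seed, n_compounds = nrow(scenario),
                   grid = list(start_min = min(scenario$trace[[1]]$time_min),
                               end_min = max(scenario$trace[[1]]$time_min),
                               n = nrow(scenario$trace[[1]])),
                   files = files)
  mf <- file.path(dir, "scenario_manifest.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}
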
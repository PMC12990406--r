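manifest_path <- function(dir) file.path(dir, "run_manifest.yaml")

read_manifest <- function(dir) {
  mp <- manifest_path(dir)
  if (file.exists(mp)) yaml::read_yaml(mp) else list(stages = list())
}

append_manifest <- function(dir, stage, config, seed, files) {
  man <- read_manifest(dir)
  prev_hash <- if (length(man$stages)) {
    man$stages[[length(man$stages)]]$hash
  } else "root"
  entry <- list(stage = stage,
                config_hash = rlang::hash(config),
                seed = seed,
                files = as.list(files),
                file_md5 = as.list(unname(tools::md5sum(
                  file.path(dir, unlist(files))))),
                package_version = as.character(utils::packageVersion("decoctr")),
                timestamp = format(Sys.time(), tz = "UTC"),
                prev = prev_hash)
  entry$hash <- rlang::hash(entry[setdiff(names(entry), "timestamp")])
  man$stages <- c(man$stages, list(entry))
  yaml::write_yaml(man, manifest_path(dir))
  invisible(entry)
}

#' Validate a pipeline run manifest
#'
#' Checks that every artifact file recorded in the manifest exists with the
#' recorded checksum and that the stage hash chain is intact.
#'
#' @param dir Run directory containing `run_manifest.yaml`.
#' @return `TRUE` invisibly; aborts on a broken chain or missing artifact.
#' @export
validate_manifest <- function(dir) {
  man <- read_manifest(dir)
  prev <- "root"
  for (entry in man$stages) {
    if (!identical(entry$prev, prev)) {
      abort("Manifest hash chain is broken.",
            class = "decoctr_manifest_error")
    }
    for (i in seq_along(entry$files)) {
      f <- file.path(dir, entry$files[[i]])
      if (!file.exists(f)) {
        abort(paste0("Artifact missing: ", f),
              class = "decoctr_manifest_error")
      }
    }
    prev <- entry$hash
  }
  invisible(TRUE)
}

#' Simulate a scenario and render its scan streams
#'
#' Stage 1 of the pipeline: builds the ground-truth scenario, writes one
#' trace CSV per compound, renders one scan stream per ion mode (JSON
#' lines) and records everything in the run manifest.
#'
#' @param out_dir Output directory.
#' @param system `"CO"` or `"SINGLE"`.
#' @param seed Integer seed for the stream noise.
#' @param scenario Scenario name; only `"zwd"` is bundled.
#' @param duration_min,scan_rate_hz,noise_cv,baseline_level Acquisition
#'   settings, see [acquisition_config()].
#' @param library Compound library.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, system = "CO", seed = 1L,
                         scenario = "zwd", duration_min = 240,
                         scan_rate_hz = 5, noise_cv = 0.05,
                         baseline_level = 0,
                         library = zwd_compound_library()) {
  if (!identical(scenario, "zwd")) {
    abort(paste0("Unknown scenario '", scenario, "'."),
          class = "decoctr_usage_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- seq(0, duration_min, by = 1 / (scan_rate_hz * 60))
  sc <- build_zwd_scenario(system, seed = seed, grid = grid,
                           library = library)
  files <- character(0)
  for (i in seq_len(nrow(sc))) {
    f <- paste0("trace_", sc$id[i], ".csv")
    write.csv(sc$trace[[i]], file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  for (mode in c("pos", "neg")) {
    cfg <- acquisition_config(scan_rate_hz = scan_rate_hz,
                              duration_min = duration_min,
                              noise_cv = noise_cv,
                              baseline_level = baseline_level,
                              mode = mode,
                              seed = seed + (mode == "neg"))
    stream <- render_stream(sc, library, cfg)
    f <- paste0("stream_", mode, ".jsonl")
    write_stream(stream, file.path(out_dir, f))
    files <- c(files, f)
  }
  append_manifest(out_dir, "simulate",
                  list(system = system, scenario = scenario,
                       duration_min = duration_min,
                       scan_rate_hz = scan_rate_hz, noise_cv = noise_cv,
                       baseline_level = baseline_level),
                  seed, files)
  invisible(out_dir)
}

#' Reconstruct EICs from the rendered streams
#'
#' Stage 2: reads each `stream_<mode>.jsonl` in the run directory, extracts
#' per-compound EICs, applies boxcar smoothing and downsampling, and writes
#' one `eic_<id>.csv` per compound plus a processing sidecar YAML.
#'
#' @param out_dir Run directory produced by [run_simulate()].
#' @param tol EIC half-width (m/z units).
#' @param points Boxcar window length.
#' @param target_dt_min Downsampling grid (minutes).
#' @param library Compound library.
#' @return `out_dir`, invisibly.
#' @export
run_process <- function(out_dir, tol = 0.5, points = 3L,
                        target_dt_min = 0.2,
                        library = zwd_compound_library()) {
  files <- character(0)
  for (mode in c("pos", "neg")) {
    sp <- file.path(out_dir, paste0("stream_", mode, ".jsonl"))
    if (!file.exists(sp)) next
    stream <- read_stream(sp)
    proc <- process_stream(stream, library, tol = tol, points = points,
                           target_dt_min = target_dt_min)
    for (i in seq_len(nrow(proc))) {
      f <- paste0("eic_", proc$id[i], ".csv")
      write_eic(proc$eic[[i]], file.path(out_dir, f))
      files <- c(files, f)
    }
  }
  settings <- list(tol = tol, points = as.integer(points),
                   target_dt_min = target_dt_min)
  yaml::write_yaml(settings, file.path(out_dir, "processing.yaml"))
  files <- c(files, "processing.yaml")
  append_manifest(out_dir, "process", settings, NA_integer_, files)
  invisible(out_dir)
}

#' Fit kinetic models to the reconstructed EICs
#'
#' Stage 3: fits Gaussian-sum and Fourier-series families to each
#' `eic_<id>.csv`, selects the better model, and writes one fit JSON per
#' compound plus a kinetic summary table.
#'
#' @param out_dir Run directory produced by [run_process()].
#' @param gauss_orders,fourier_orders Model orders to try.
#' @param library Compound library.
#' @return `out_dir`, invisibly.
#' @export
run_fit <- function(out_dir, gauss_orders = 1:3, fourier_orders = 1:2,
                    library = zwd_compound_library()) {
  eic_files <- sort(list.files(out_dir, pattern = "^eic_.*\\.csv$"))
  if (!length(eic_files)) {
    abort("No EIC files found; run the processing stage first.",
          class = "decoctr_usage_error")
  }
  files <- character(0)
  summaries <- list()
  for (f in eic_files) {
    id <- sub("^eic_(.*)\\.csv$", "\\1", f)
    eic <- as_tibble(read.csv(file.path(out_dir, f)))
    fit <- fit_kinetics(eic, gauss_orders, fourier_orders)
    summ <- summarize_kinetics(fit)
    rec <- list(compound_id = id, model = fit$model, order = fit$n,
                params = as.list(fit$params), r2 = fit$r2,
                adj_r2 = fit$adj_r2, rmse = fit$rmse,
                summary = as.list(summ))
    jf <- paste0("fit_", id, ".json")
    jsonlite::write_json(rec, file.path(out_dir, jf), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, jf)
    summaries[[id]] <- dplyr::bind_cols(tibble(compound_id = id), summ)
  }
  st <- dplyr::bind_rows(summaries)
  write.csv(st, file.path(out_dir, "kinetic_summaries.csv"),
            row.names = FALSE)
  files <- c(files, "kinetic_summaries.csv")
  append_manifest(out_dir, "fit",
                  list(gauss_orders = gauss_orders,
                       fourier_orders = fourier_orders),
                  NA_integer_, files)
  invisible(out_dir)
}

#' Build the single- vs co-decoction comparison table
#'
#' Joins the kinetic summaries of two fitted runs (one per system) into one
#' row per compound with peak and rate ratios.
#'
#' @param dir_single,dir_co Run directories fitted with [run_fit()].
#' @param path Optional CSV output path.
#' @return Comparison tibble (see [compare_modes()]).
#' @export
run_compare <- function(dir_single, dir_co, path = NULL) {
  s <- as_tibble(read.csv(file.path(dir_single, "kinetic_summaries.csv")))
  co <- as_tibble(read.csv(file.path(dir_co, "kinetic_summaries.csv")))
  ids <- intersect(s$compound_id, co$compound_id)
  out <- dplyr::bind_rows(lapply(ids, function(id) {
    compare_modes(s[s$compound_id == id, ], co[co$compound_id == id, ],
                  compound_id = id)
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Decide the decoction endpoint from a fitted run
#'
#' Stage 4: evaluates every fitted curve on the decision grid and applies
#' the SBTEF rule, writing `endpoint_decision.json` and a plain-text
#' rationale.
#'
#' @param out_dir Run directory produced by [run_fit()].
#' @param config An [sbtef_config()], or a path to a YAML file with
#'   matching fields.
#' @param library Compound library.
#' @param window Decision window in minutes.
#' @return The `endpoint_decision`, invisibly.
#' @export
run_endpoint <- function(out_dir, config = sbtef_config(),
                         library = zwd_compound_library(),
                         window = c(0, 240)) {
  if (is.character(config)) {
    fields <- yaml::read_yaml(config)
    config <- do.call(sbtef_config, fields)
  }
  fit_files <- sort(list.files(out_dir, pattern = "^fit_.*\\.json$"))
  if (!length(fit_files)) {
    abort("No fit files found; run the fitting stage first.",
          class = "decoctr_usage_error")
  }
  grid <- seq(window[1], window[2], by = config$grid_dt_min)
  curves <- dplyr::bind_rows(lapply(fit_files, function(f) {
    rec <- jsonlite::fromJSON(file.path(out_dir, f))
    pars <- unlist(rec$params)
    v <- if (rec$model == "GAUSSN") {
      gauss_sum_eval(pars, grid, rec$order)
    } else {
      fourier_eval(pars, grid, rec$order)
    }
    tibble(compound_id = rec$compound_id, time_min = grid,
           value = pmax(v, 0))
  }))
  decision <- decide_endpoint(curves, config, library, window)
  write_endpoint_decision(decision, file.path(out_dir,
                                              "endpoint_decision.json"))
  writeLines(c(paste("Optimal decoction endpoint:",
                     decision$endpoint_min, "min"),
               decision$rationale),
             file.path(out_dir, "endpoint_rationale.txt"))
  append_manifest(out_dir, "endpoint", unclass(config), NA_integer_,
                  c("endpoint_decision.json", "endpoint_rationale.txt"))
  invisible(decision)
}

#' Render a markdown run report
#'
#' Summarises a fitted run: per-compound kinetic summaries with percent
#' changes and, when present, the endpoint decision.
#'
#' @param out_dir Run directory.
#' @param path Output markdown path; defaults to `report.md` inside the run
#'   directory.
#' @return `path`, invisibly.
#' @export
run_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  st_path <- file.path(out_dir, "kinetic_summaries.csv")
  if (!file.exists(st_path)) {
    abort("No kinetic summaries found; run the fitting stage first.",
          class = "decoctr_usage_error")
  }
  st <- read.csv(st_path)
  lines <- c("# Decoction monitoring report", "",
             "## Kinetic summaries", "",
             "| compound | initial | peak | final | change (%) | trend |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(st))) {
    lines <- c(lines, sprintf(
      "| %s | %.3g | %.3g | %.3g | %+.1f | %s |",
      st$compound_id[i], st$initial[i], st$peak_value[i], st$final[i],
      st$pct_change[i], st$trend[i]))
  }
  dec_path <- file.path(out_dir, "endpoint_decision.json")
  if (file.exists(dec_path)) {
    dec <- jsonlite::fromJSON(dec_path)
    lines <- c(lines, "", "## SBTEF endpoint", "",
               sprintf("Optimal decoction endpoint: **%g min**.",
                       dec$endpoint_min), "",
               paste0("- ", dec$rationale))
  }
  writeLines(lines, path)
  invisible(path)
}
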
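#' Acquisition settings for a simulated ORT-MS run
#'
#' The acquisition contract of the monitoring device: continuous full scans
#' over m/z 100--1500 in one polarity.  The default 5 Hz clock over 240 min
#' yields 72,000 scans, i.e. 72,000 intensity values per monitored channel
#' per run.  Positive and negative modes are acquired as separate runs.
#'
#' @param scan_rate_hz Scans per second (> 0); default 5.
#' @param duration_min Acquisition length in minutes (> 0); default 240.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise (>= 0); default 0.05.
#' @param baseline_level Mean of the additive exponential baseline per
#'   channel, in intensity units; default 0 (off).
#' @param mode Ion mode, `"pos"` or `"neg"`.
#' @param seed Integer seed controlling the stochastic components.
#'
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(scan_rate_hz = 5, duration_min = 240,
                               noise_cv = 0.05, baseline_level = 0,
                               mode = c("pos", "neg"), seed = 1L) {
  mode <- match.arg(mode)
  if (scan_rate_hz <= 0 || duration_min <= 0 || noise_cv < 0 ||
      baseline_level < 0) {
    abort("Invalid acquisition settings: rates/durations must be positive, noise non-negative.",
          class = "decoctr_parameter_error")
  }
  structure(list(scan_rate_hz = scan_rate_hz, duration_min = duration_min,
                 noise_cv = noise_cv, baseline_level = baseline_level,
                 mode = mode, seed = as.integer(seed)),
            class = "acquisition_config")
}

new_scan_stream <- function(time_s, mode, mz, intensity) {
  stopifnot(is.matrix(intensity), nrow(intensity) == length(time_s),
            ncol(intensity) == length(mz))
  if (length(mz) && (is.unsorted(mz, strictly = TRUE) ||
                     any(mz < 100 | mz > 1500))) {
    abort("Scan m/z channels must be strictly ascending within [100, 1500].",
          class = "decoctr_parameter_error")
  }
  if (any(time_s < 0)) {
    abort("Scan times must be non-negative.",
          class = "decoctr_parameter_error")
  }
  structure(list(time_s = time_s, mode = mode, mz = mz,
                 intensity = intensity),
            class = "scan_stream")
}

#' @export
print.scan_stream <- function(x, ...) {
  cat("<scan_stream> ", length(x$time_s), " scans (", x$mode, " mode), ",
      length(x$mz), " m/z channels", sep = "")
  if (length(x$time_s)) {
    cat(", ", sprintf("%.1f", max(x$time_s) / 60), " min", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of scans in a stream
#' @param stream A `scan_stream`.
#' @return Integer scan count.
#' @export
n_scans <- function(stream) length(stream$time_s)

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Render concentration traces into a full-scan stream
#'
#' Turns ground-truth concentration traces into the raw data the monitoring
#' device would record: one full scan per clock tick, in which each
#' compound whose `ion_mode` matches the configured polarity deposits
#' `response_factor * concentration` at its nominal m/z channel.  Intensities
#' are perturbed by multiplicative lognormal noise with unit mean and
#' coefficient of variation `noise_cv`, plus an additive exponential baseline
#' with mean `baseline_level` on every channel.  Given the same seed the
#' stream is bit-reproducible.
#'
#' @param traces Tibble with columns `compound_id` and `trace` (a list column
#'   of tibbles `time_min`, `value`), as returned by [build_zwd_scenario()],
#'   or a long tibble with columns `compound_id`, `time_min`, `value`.
#' @param library Compound library tibble (see [read_compound_library()]).
#' @param config An [acquisition_config()].
#'
#' @return A `scan_stream` with `floor(scan_rate_hz * duration_min * 60)`
#'   scans.
#' @export
render_stream <- function(traces, library, config) {
  stopifnot(inherits(config, "acquisition_config"))
  library <- validate_compound_library(library)
  if (!is_tibble(traces) && is.data.frame(traces)) traces <- as_tibble(traces)
  if ("trace" %in% names(traces)) {
    idcol <- if ("compound_id" %in% names(traces)) "compound_id" else "id"
    traces <- traces %>%
      select(compound_id = dplyr::all_of(idcol), "trace") %>%
      tidyr::unnest("trace")
  }
  if (!all(c("compound_id", "time_min", "value") %in% names(traces))) {
    abort("`traces` must provide compound_id, time_min, value (possibly nested in a `trace` column).",
          class = "decoctr_parameter_error")
  }
  n <- floor(config$scan_rate_hz * config$duration_min * 60)
  time_s <- (seq_len(n) - 1) / config$scan_rate_hz
  t_min <- time_s / 60
  lib <- library %>% filter(.data$ion_mode == config$mode)
  lib <- lib[order(lib$mz), , drop = FALSE]
  channels <- sort(unique(lib$mz))
  inten <- matrix(0, nrow = n, ncol = length(channels))
  for (i in seq_len(nrow(lib))) {
    tr <- traces %>% filter(.data$compound_id == lib$id[i])
    if (!nrow(tr)) next
    if (min(tr$time_min) > min(t_min) || max(tr$time_min) < max(t_min)) {
      abort(paste0("Trace for '", lib$id[i],
                   "' does not cover the acquisition window."),
            class = "decoctr_coverage_error")
    }
    conc <- approx(tr$time_min, tr$value, xout = t_min, ties = "ordered")$y
    j <- match(lib$mz[i], channels)
    inten[, j] <- inten[, j] + lib$response_factor[i] * conc
  }
  with_seed(config$seed, {
    if (config$noise_cv > 0) {
      s <- sqrt(log(1 + config$noise_cv^2))
      noise <- rlnorm(length(inten), meanlog = -s^2 / 2, sdlog = s)
      inten <- inten * matrix(noise, nrow = n)
    }
    if (config$baseline_level > 0) {
      inten <- inten + matrix(rexp(length(inten),
                                   rate = 1 / config$baseline_level),
                              nrow = n)
    }
  })
  out <- new_scan_stream(time_s, config$mode, channels, inten)
  attr(out, "config") <- config
  out
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to the shortest representation that still round-trips
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

#' Write a scan stream to disk
#'
#' The canonical format is JSON lines: one scan per line with schema
#' `{"t_s": <sec>, "mode": "pos"|"neg", "mz": [...], "intensity": [...]}`.
#' Numbers are written with full precision so that
#' `read_stream(write_stream(x))` reproduces `x` bit-exactly.  An mzML
#' writer (requiring the mzR package) is provided for interoperability;
#' mzML round-trips values at float32 precision.
#'
#' @param stream A `scan_stream`.
#' @param path Output file path.
#' @param format `"jsonl"` (default) or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("jsonl", "mzml")) {
  stopifnot(inherits(stream, "scan_stream"))
  format <- match.arg(format)
  if (format == "jsonl") {
    n <- n_scans(stream)
    if (n == 0) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    mz_str <- paste(fmt_num(stream$mz), collapse = ",")
    im <- matrix(fmt_num(stream$intensity), nrow = n)
    rows <- do.call(paste, c(lapply(seq_len(ncol(im)), function(j) im[, j]),
                             list(sep = ",")))
    lines <- paste0('{"t_s":', fmt_num(stream$time_s),
                    ',"mode":"', stream$mode,
                    '","mz":[', mz_str,
                    '],"intensity":[', rows, "]}")
    writeLines(lines, path)
  } else {
    write_stream_mzml(stream, path)
  }
  invisible(path)
}

write_stream_mzml <- function(stream, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("mzML output requires the 'mzR' package.",
          class = "decoctr_dependency_error")
  }
  n <- n_scans(stream)
  pol <- if (stream$mode == "pos") 1L else 0L
  pks <- lapply(seq_len(n), function(i) {
    cbind(mz = stream$mz, intensity = stream$intensity[i, ])
  })
  tic <- rowSums(stream$intensity)
  bp <- max.col(stream$intensity, ties.method = "first")
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = pol, peaksCount = length(stream$mz), totIonCurrent = tic,
    retentionTime = stream$time_s,
    basePeakMZ = stream$mz[bp],
    basePeakIntensity = stream$intensity[cbind(seq_len(n), bp)],
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(stream$mz), highMZ = max(stream$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 100, scanWindowUpperLimit = 1500)
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}

#' Read a scan stream from disk
#'
#' @param path File written by [write_stream()] (JSON lines or mzML).
#' @param format `"jsonl"`, `"mzml"`, or `NULL` to infer from the file
#'   extension.
#' @return A `scan_stream`.
#' @export
read_stream <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "jsonl"
  }
  if (format == "mzml") return(read_stream_mzml(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(new_scan_stream(numeric(0), "pos", numeric(0),
                           matrix(0, 0, 0)))
  }
  scans <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) ||
        !all(c("t_s", "mode", "mz", "intensity") %in% names(rec)) ||
        length(rec$mz) != length(rec$intensity)) {
      abort(paste0("Malformed scan record at line ", i, " of ", path),
            class = "decoctr_parse_error")
    }
    scans[[i]] <- rec
  }
  modes <- vapply(scans, function(s) s$mode, character(1))
  if (length(unique(modes)) > 1L) {
    abort("Stream mixes ion modes; one polarity per stream is required.",
          class = "decoctr_parse_error")
  }
  mzs <- lapply(scans, function(s) as.numeric(s$mz))
  channels <- sort(unique(unlist(mzs)))
  inten <- matrix(0, nrow = length(scans), ncol = length(channels))
  for (i in seq_along(scans)) {
    idx <- match(mzs[[i]], channels)
    inten[i, idx] <- as.numeric(scans[[i]]$intensity)
  }
  new_scan_stream(vapply(scans, function(s) as.numeric(s$t_s), numeric(1)),
                  modes[1], channels, inten)
}

read_stream_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("mzML input requires the 'mzR' package.",
          class = "decoctr_dependency_error")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  n <- nrow(hdr)
  if (n == 0) {
    return(new_scan_stream(numeric(0), "pos", numeric(0), matrix(0, 0, 0)))
  }
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  channels <- sort(unique(unlist(lapply(pks, function(p) p[, 1]))))
  inten <- matrix(0, nrow = n, ncol = length(channels))
  for (i in seq_len(n)) {
    idx <- vapply(pks[[i]][, 1],
                  function(m) which.min(abs(channels - m)), integer(1))
    inten[i, idx] <- pks[[i]][, 2]
  }
  mode <- if (all(hdr$polarity == 0L)) "neg" else "pos"
  new_scan_stream(hdr$retentionTime, mode, channels, inten)
}
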
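#' Extract an ion chromatogram from a scan stream
#'
#' For every scan, sums the intensities of all m/z channels within
#' `tol` of `mz_center` (unit-resolution acquisition deposits each
#' compound's signal in a single integer channel, so the default half-width
#' of 0.5 captures exactly that channel).
#'
#' @param stream A `scan_stream`.
#' @param mz_center Nominal m/z of the monitored ion.
#' @param tol Half-width of the extraction window in m/z units (> 0).
#'
#' @return Tibble with columns `time_min` and `intensity`, one row per scan.
#' @export
extract_eic <- function(stream, mz_center, tol = 0.5) {
  stopifnot(inherits(stream, "scan_stream"))
  if (tol <= 0) {
    abort("`tol` must be positive.", class = "decoctr_parameter_error")
  }
  if (n_scans(stream) == 0) {
    abort("Cannot extract an EIC from an empty stream.",
          class = "decoctr_empty_stream_error")
  }
  sel <- abs(stream$mz - mz_center) <= tol
  vals <- if (any(sel)) {
    rowSums(stream$intensity[, sel, drop = FALSE])
  } else {
    rep(0, n_scans(stream))
  }
  tibble(time_min = stream$time_s / 60, intensity = vals)
}

#' Boxcar smoothing
#'
#' Centred unweighted moving average of odd window length `points`.  At the
#' edges the window shrinks symmetrically: position `i` averages over
#' `[i - h_i, i + h_i]` with `h_i = min((points-1)/2, i-1, n-i)`, so the
#' first and last points are returned unchanged and the output has the same
#' length as the input.  `points = 1` is the identity.
#'
#' @param values Numeric vector (length >= 1).
#' @param points Odd positive integer window length; default 3.
#'
#' @return Numeric vector of smoothed values, same length as `values`.
#' @export
#' @examples
#' boxcar_smooth(c(0, 0, 9, 0, 0), points = 3)
boxcar_smooth <- function(values, points = 3L) {
  if (!is.numeric(points) || length(points) != 1L || points < 1 ||
      points %% 2 == 0) {
    abort("`points` must be an odd positive integer.",
          class = "decoctr_config_error")
  }
  n <- length(values)
  if (n < 1L) {
    abort("`values` must have length >= 1.",
          class = "decoctr_parameter_error")
  }
  points <- as.integer(points)
  if (points == 1L || n == 1L) return(values)
  half <- (points - 1L) %/% 2L
  out <- as.numeric(stats::filter(values, rep(1 / points, points),
                                  sides = 2))
  for (i in seq_len(min(half, n))) {
    h <- min(half, i - 1L, n - i)
    out[i] <- mean(values[(i - h):(i + h)])
    j <- n - i + 1L
    h <- min(half, j - 1L, n - j)
    out[j] <- mean(values[(j - h):(j + h)])
  }
  out
}

#' Downsample an intensity series by block averaging
#'
#' Replaces consecutive windows of width `target_dt_min` by their mean,
#' stamped at the window centre.  A trailing partial window is dropped.
#'
#' @param eic Tibble with `time_min` and one or more value columns
#'   (`intensity`, `raw`, `smoothed`, ...).
#' @param target_dt_min Output spacing in minutes; must be coarser than the
#'   native spacing.
#'
#' @return Tibble with the same value columns on the coarser grid.
#' @export
downsample_eic <- function(eic, target_dt_min) {
  stopifnot(is.data.frame(eic), "time_min" %in% names(eic))
  t <- eic$time_min
  native <- median(diff(t))
  if (!is.finite(native) || target_dt_min <= native) {
    abort("`target_dt_min` must be coarser than the native spacing.",
          class = "decoctr_parameter_error")
  }
  origin <- t[1]
  block <- floor((t - origin) / target_dt_min)
  nb <- floor((t[length(t)] - origin + native) / target_dt_min)
  keep <- block < nb
  block <- block[keep]
  vals <- eic[keep, setdiff(names(eic), "time_min"), drop = FALSE]
  out <- tibble(time_min = origin + (unique(block) + 0.5) * target_dt_min)
  for (nm in names(vals)) {
    out[[nm]] <- as.numeric(tapply(vals[[nm]], block, mean))
  }
  out
}

#' Reconstruct per-compound intensity series from a scan stream
#'
#' The standard processing chain applied to raw full scans: per-compound EIC
#' extraction (sum within `tol` of the nominal m/z), boxcar denoising over
#' the full-rate series (`points = 3` by default), then block-mean
#' downsampling to a grid suitable for curve fitting.
#'
#' @param stream A `scan_stream`.
#' @param library Compound library tibble; only compounds whose `ion_mode`
#'   matches the stream's mode are processed.
#' @param tol EIC half-width in m/z units.
#' @param points Boxcar window length (odd).
#' @param target_dt_min Output spacing in minutes, or `NULL` to keep the
#'   full-rate series.
#'
#' @return A tibble with one row per processed compound and a list column
#'   `eic` of tibbles `time_min`, `raw`, `smoothed` (downsampled if
#'   requested).
#' @export
process_stream <- function(stream, library, tol = 0.5, points = 3L,
                           target_dt_min = 0.2) {
  stopifnot(inherits(stream, "scan_stream"))
  library <- validate_compound_library(library)
  lib <- library %>% filter(.data$ion_mode == stream$mode)
  eics <- purrr::map(seq_len(nrow(lib)), function(i) {
    e <- extract_eic(stream, lib$mz[i], tol = tol)
    e <- tibble(time_min = e$time_min, raw = e$intensity,
                smoothed = boxcar_smooth(e$intensity, points = points))
    if (!is.null(target_dt_min)) e <- downsample_eic(e, target_dt_min)
    e
  })
  out <- lib %>% select("id", "name", "herb", "class", "ion_mode", "mz",
                        "response_factor")
  out$eic <- eics
  out
}

#' Write an EIC table to CSV
#'
#' @param eic Tibble with `time_min`, `raw`, `smoothed` columns.
#' @param path Output path; the CSV has header `time_min,raw,smoothed`.
#' @return `path`, invisibly.
#' @export
write_eic <- function(eic, path) {
  write.csv(eic[, intersect(c("time_min", "raw", "smoothed"), names(eic))],
            path, row.names = FALSE)
  invisible(path)
}
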
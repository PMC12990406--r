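#' Kinetic class labels
#'
#' The closed set of phenomenological kinetic classes a monitored compound
#' can belong to during decoction: toxic diester alkaloids that hydrolyse
#' away, bioactive monoesters, aminoalcohol end products, biphasic
#' intermediates, monotonically rising hydrolysis products, heat-conversion
#' products, dissolution-only stable compounds, and glycosides that decline
#' in the co-decoction matrix.
#'
#' @return Character vector of the eight class labels.
#' @export
kinetic_classes <- function() {
  c("DIESTER_TOXIC", "MONOESTER_ACTIVE", "AMINOALCOHOL",
    "INTERMEDIATE_BIPHASIC", "HYDROLYSIS_PRODUCT_RISING",
    "CONVERSION_PRODUCT", "STABLE_DISSOLUTION_ONLY", "DECLINING_GLYCOSIDE")
}

validate_compound_library <- function(lib, call = rlang::caller_env()) {
  required <- c("id", "name", "herb", "class", "ion_mode", "mz",
                "response_factor")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    abort(paste0("Compound library is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "decoctr_library_error", call = call)
  }
  if (anyDuplicated(lib$id)) {
    abort("Compound ids must be unique.", class = "decoctr_library_error",
          call = call)
  }
  bad <- setdiff(unique(lib$class), kinetic_classes())
  if (length(bad)) {
    abort(paste0("Unknown kinetic class(es): ", paste(bad, collapse = ", ")),
          class = "decoctr_library_error", call = call)
  }
  if (!all(lib$ion_mode %in% c("pos", "neg"))) {
    abort("`ion_mode` must be 'pos' or 'neg'.",
          class = "decoctr_library_error", call = call)
  }
  if (any(lib$mz < 100 | lib$mz > 1500)) {
    abort("Nominal m/z must lie within the acquisition range [100, 1500].",
          class = "decoctr_library_error", call = call)
  }
  if (any(lib$response_factor <= 0)) {
    abort("`response_factor` must be positive.",
          class = "decoctr_library_error", call = call)
  }
  dup <- lib %>% group_by(.data$ion_mode, .data$mz) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>% filter(.data$n > 1L)
  if (nrow(dup)) {
    warn("Some compounds share a nominal m/z channel within one ion mode; their EICs will overlap.")
  }
  as_tibble(lib)
}

#' Read a compound library table
#'
#' A compound library lists every monitored species with its herb of origin,
#' kinetic class, ionisation mode, nominal (unit-resolution) m/z of the
#' monitored ion and ionisation response factor (signal intensity per
#' concentration unit).
#'
#' @param path Path to a CSV file with header
#'   `id,name,herb,class,ion_mode,mz,response_factor`.
#'
#' @return A validated tibble.
#' @export
read_compound_library <- function(path) {
  lib <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  validate_compound_library(lib)
}

#' Write a compound library table
#'
#' @param lib Compound library tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(lib, path) {
  validate_compound_library(lib)
  write.csv(lib, path, row.names = FALSE)
  invisible(path)
}

#' The Zhenwu Decoction compound library
#'
#' The bundled 18-compound library monitored in the Zhenwu Decoction (ZWD)
#' scenario: Fuzi alkaloids (diester, monoester, aminoalcohol and stable
#' types) in positive mode, ginger conversion products and atractylenolides
#' in positive mode, and peony glycosides, the pentagalloylglucose
#' intermediate and its polyphenolic hydrolysis products in negative mode.
#'
#' @return A tibble, one row per monitored compound.
#' @export
#' @examples
#' zwd_compound_library()
zwd_compound_library <- function() {
  read_compound_library(system.file("extdata", "zwd_compound_library.csv",
                                    package = "decoctr", mustWork = TRUE))
}
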
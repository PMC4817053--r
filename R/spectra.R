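# Spectral datasets.
#
# A spectral dataset is a tidy table of centroided peaks:
#   scan_time  acquisition time in minutes (LC retention time for LC-MS
#              runs, infusion time for direct-infusion time courses)
#   mz         centroid m/z
#   intensity  centroid intensity (arbitrary units, >= 0)
# Multi-run collections carry additional grouping columns (e.g. `group`,
# `replicate`). Plain data frames with these columns are accepted
# everywhere; all functions return tibbles.

#' Read / write the columnar spectra format
#'
#' The package's on-disk spectra format is a plain CSV with columns
#' `scan_time` (minutes), `mz` and `intensity`, one row per centroid;
#' any extra columns (e.g. `group`, `replicate`) are preserved.
#'
#' @param x spectra table.
#' @param path file path.
#' @return `read_spectra_csv()` returns a tibble; `write_spectra_csv()`
#'   returns `x` invisibly.
#' @export
read_spectra_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("scan_time", "mz", "intensity")
  missing <- setdiff(req, names(out))
  if (length(missing) > 0) {
    rlang::abort(paste0("Spectra CSV lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  out
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(x)
}

assert_spectra <- function(x) {
  req <- c("scan_time", "mz", "intensity")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("Spectra table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  invisible(x)
}
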
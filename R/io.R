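#' Read and write stopped-flow traces as CSV with a JSON sidecar
#'
#' The CSV holds columns `time_s`, `absorbance_au`, `saturated` (0/1); the
#' sidecar (`<path>.json`) holds the wavelength and metadata. A bare
#' two-column CSV (time, absorbance) is also accepted on read, in which case
#' the wavelength must be supplied.
#'
#' @param trace An `sf_trace`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   `sf_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sf_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              absorbance_au = trace$absorbance,
                              saturated = as.integer(trace$saturated)),
                   path, row.names = FALSE)
  side <- list(wavelength_nm = trace$wavelength, metadata = trace$metadata)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @param wavelength Wavelength (nm) for bare CSVs without a sidecar.
#' @export
read_trace <- function(path, wavelength = NULL) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  wl <- wavelength
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    wl <- side$wavelength_nm
    meta <- as.list(side$metadata)
  }
  if (is.null(wl)) stop("no sidecar found; supply `wavelength`", call. = FALSE)
  if (all(c("time_s", "absorbance_au") %in% names(df))) {
    sat <- if ("saturated" %in% names(df)) df$saturated > 0 else
      rep(FALSE, nrow(df))
    sf_trace(df$time_s, df$absorbance_au, wl, sat, meta)
  } else {
    sf_trace(df[[1]], df[[2]], wl, metadata = meta)
  }
}

#' Write/read a steady-state dataset or titration series as CSV
#'
#' @param x A `steady_state_dataset` or `titration_series`.
#' @param path CSV path.
#' @return The path (write) or the data frame (read), invisibly/visibly.
#' @export
write_dataset <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) utils::read.csv(path)
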
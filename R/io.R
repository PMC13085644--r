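#' Write / read a concentration design as CSV
#'
#' Dialect: UTF-8, comma-separated, dot decimal, header
#' `mix,<analyte1>,<analyte2>,...`, concentrations in ug/mL.
#'
#' @param design Runs x analytes matrix.
#' @param path Output file.
#' @export
write_design_csv <- function(design, path) {
  design <- as.matrix(design)
  df <- data.frame(mix = seq_len(nrow(design)), design, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param factors Optional factor list to attach to the result.
#' @export
read_design_csv <- function(path, factors = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "mix")
    stop(sprintf("parse error in %s: first column must be 'mix', got '%s'",
                 path, names(df)[1]), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("parse error in %s: non-numeric concentration column", path),
         call. = FALSE)
  rownames(m) <- NULL
  if (!is.null(factors)) m <- structure(m, factors = factors,
                                        class = c("concentration_design", class(m)))
  m
}

#' Write / read spectra as CSV
#'
#' First column `wavelength_nm`, one column per sample (AU). Samples are
#' stored as columns so a spectrum reads top to bottom.
#'
#' @param A Samples x wavelengths absorbance matrix.
#' @param grid A [wavelength_grid()].
#' @param path Output file.
#' @export
write_spectra_csv <- function(A, grid, path) {
  A <- as.matrix(A)
  if (ncol(A) != grid$n) stop("grid mismatch", call. = FALSE)
  df <- data.frame(wavelength_nm = grid$wavelengths, t(A))
  names(df)[-1] <- paste0("sample_", seq_len(nrow(A)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @return `read_spectra_csv`: list with `absorbance` (samples x
#'   wavelengths) and `grid`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop(sprintf("parse error in %s: first column must be 'wavelength_nm'",
                 path), call. = FALSE)
  lam <- df[[1]]
  step <- unique(round(diff(lam), 10))
  if (length(step) != 1)
    stop(sprintf("parse error in %s: non-uniform wavelength grid", path),
         call. = FALSE)
  A <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(A) <- lam
  list(absorbance = A,
       grid = wavelength_grid(lam[1], lam[length(lam)], step))
}

#' Serialize / restore a run report as JSON
#'
#' Lossless round trip of the nested numeric report structure.
#' @param report A list (e.g. from [run_end_to_end()]).
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run configuration as JSON
#' @param config A [run_config()].
#' @param path Output file.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of [run_config()] fields.
#' @export
read_config_json <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
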
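# Strict CSV dialects for the package's tabular datasets. All readers
# validate the exact header, reject non-numeric cells, and return the typed
# object; all writers produce files the matching reader ingests losslessly.

read_strict_csv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(df), columns))
    stop(sprintf("bad header in %s: expected '%s', found '%s'",
                 path, paste(columns, collapse = ","),
                 paste(names(df), collapse = ",")))
  if (nrow(df) == 0L) stop("empty table: ", path)
  for (cn in columns) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric cell(s) in column '%s' of %s", cn, path))
    df[[cn]] <- v
  }
  df
}

#' Read / write isomer spectra as CSV
#'
#' Dialect: header `wavelength_nm,eps_E,eps_Z`, UTF-8, `.` decimal separator,
#' wavelengths strictly increasing.
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns an [isomer_spectra] object.
#' @export
read_spectra_csv <- function(path) {
  df <- read_strict_csv(path, c("wavelength_nm", "eps_E", "eps_Z"))
  if (is.unsorted(df$wavelength_nm, strictly = TRUE))
    stop("wavelength_nm must be strictly increasing in ", path)
  isomer_spectra(df$wavelength_nm, df$eps_E, df$eps_Z)
}

#' @rdname read_spectra_csv
#' @param spectra An [isomer_spectra] object.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "isomer_spectra"))
  utils::write.csv(
    data.frame(wavelength_nm = spectra$wavelengths,
               eps_E = spectra$eps_E, eps_Z = spectra$eps_Z),
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write response traces as CSV
#'
#' Dialect: header `time_s,fz,effect,segment_id`, time non-decreasing.
#'
#' @param path File path.
#' @return `read_trace_csv()` returns a `response_trace` data frame.
#' @export
read_trace_csv <- function(path) {
  df <- read_strict_csv(path, c("time_s", "fz", "effect", "segment_id"))
  if (is.unsorted(df$time_s))
    stop("time_s must be non-decreasing in ", path)
  df$segment_id <- as.integer(df$segment_id)
  class(df) <- c("response_trace", "data.frame")
  df
}

#' @rdname read_trace_csv
#' @param trace A `response_trace` data frame.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("time_s", "fz", "effect", "segment_id") %in% names(trace)))
  utils::write.csv(
    as.data.frame(trace)[, c("time_s", "fz", "effect", "segment_id")],
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write dose-response sets as CSV
#'
#' Dialect: header `conc_M,response,replicate`, positive concentrations.
#'
#' @param path File path.
#' @return `read_doseresp_csv()` returns a `dose_response_set` data frame.
#' @export
read_doseresp_csv <- function(path) {
  df <- read_strict_csv(path, c("conc_M", "response", "replicate"))
  if (any(df$conc_M <= 0)) stop("concentrations must be positive in ", path)
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("dose_response_set", "data.frame")
  df
}

#' @rdname read_doseresp_csv
#' @param data A `dose_response_set` data frame.
#' @export
write_doseresp_csv <- function(data, path) {
  stopifnot(all(c("conc_M", "response", "replicate") %in% names(data)))
  utils::write.csv(
    as.data.frame(data)[, c("conc_M", "response", "replicate")],
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write action spectra as CSV
#'
#' Dialect: header `wavelength_nm,bioactivity,conc_M`.
#'
#' @param path File path.
#' @return `read_actionspec_csv()` returns an `action_spectrum_set` data
#'   frame.
#' @export
read_actionspec_csv <- function(path) {
  df <- read_strict_csv(path, c("wavelength_nm", "bioactivity", "conc_M"))
  class(df) <- c("action_spectrum_set", "data.frame")
  df
}

#' @rdname read_actionspec_csv
#' @param data An `action_spectrum_set` data frame.
#' @export
write_actionspec_csv <- function(data, path) {
  stopifnot(all(c("wavelength_nm", "bioactivity", "conc_M") %in% names(data)))
  utils::write.csv(
    as.data.frame(data)[, c("wavelength_nm", "bioactivity", "conc_M")],
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a flat key=value parameter file into pharmacology parameters
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and blank
#' lines ignored. Recognised keys: `kd_E`, `kd_Z`, `eff_E`, `eff_Z`, `basal`,
#' `tau`, `hill_n` (the last three optional with package defaults).
#'
#' @param path File path.
#' @return A [pharm_params] object.
#' @export
read_pharm_file <- function(path) {
  kv <- read_keyvalue_file(path)
  need <- c("kd_E", "kd_Z", "eff_E", "eff_Z")
  if (!all(need %in% names(kv)))
    stop("pharm file must define ", paste(need, collapse = ", "))
  num <- function(key, default = NULL) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  pharm_params(kd_E = num("kd_E"), kd_Z = num("kd_Z"),
               eff_E = num("eff_E"), eff_Z = num("eff_Z"),
               basal = num("basal", 0.04), tau = num("tau", 10),
               hill_n = num("hill_n", 1))
}

read_keyvalue_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("bad key=value line: ", ln)
    kv[[trimws(parts[1L])]] <- trimws(parts[2L])
  }
  kv
}
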
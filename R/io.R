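# Delimited-text codecs: bound-fraction series as CSV with a YAML sidecar
# for concentration context, ACF curves as CSV, reports as JSON. Parsing is
# strict: a malformed value fails with the offending row named.

#' Read a bound-fraction time series from CSV
#'
#' Expects columns `time_s` and `p`. Times must be strictly increasing and
#' all values finite; violations fail naming the first offending row. An
#' optional YAML sidecar supplies `CS_uM`, `CE_uM` and `kind`.
#'
#' @param path CSV file path.
#' @param sidecar optional YAML file path with fields `CS_uM`, `CE_uM`,
#'   `kind`; defaults to `<path>.yml` when that file exists.
#' @return a [bound_fraction_series()].
#' @export
read_series <- function(path, sidecar = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "p") %in% names(df))) {
    stop(sprintf("%s: need columns time_s, p", path), call. = FALSE)
  }
  for (col in c("time_s", "p")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or non-finite '%s' at row %d", path,
                   col, bad[1L]), call. = FALSE)
    }
    df[[col]] <- v
  }
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono)) {
    stop(sprintf("%s: time_s not strictly increasing at row %d", path,
                 nonmono[1L] + 1L), call. = FALSE)
  }
  if (is.null(sidecar)) {
    cand <- paste0(path, ".yml")
    if (file.exists(cand)) sidecar <- cand
  }
  CS <- CE <- NA_real_; kind <- "dissociation"
  if (!is.null(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$CS_uM)) CS <- uM(meta$CS_uM)
    if (!is.null(meta$CE_uM)) CE <- uM(meta$CE_uM)
    if (!is.null(meta$kind)) kind <- meta$kind
  }
  bound_fraction_series(df$time_s, df$p, CE = CE, CS = CS, kind = kind)
}

#' Write a bound-fraction series to CSV (+ YAML sidecar)
#'
#' @param series a [bound_fraction_series()].
#' @param path CSV output path; the sidecar goes to `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "bound_fraction_series"))
  utils::write.csv(data.frame(time_s = series$times, p = series$p), path,
                   row.names = FALSE)
  yaml::write_yaml(list(CS_uM = series$CS / 1e-6, CE_uM = series$CE / 1e-6,
                        kind = series$kind), paste0(path, ".yml"))
  invisible(path)
}

#' Read / write an autocorrelation curve as CSV
#'
#' Columns `lag_s`, `G` and optionally `sigma`.
#'
#' @param path CSV file path.
#' @return [read_acf_csv()]: an [fcs_curve()]; [write_acf_csv()]: `path`.
#' @export
read_acf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lag_s", "G") %in% names(df))) {
    stop(sprintf("%s: need columns lag_s, G", path), call. = FALSE)
  }
  for (col in intersect(c("lag_s", "G", "sigma"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or non-finite '%s' at row %d", path,
                   col, bad[1L]), call. = FALSE)
    }
    df[[col]] <- v
  }
  fcs_curve(df$lag_s, df$G, sigma = df$sigma, label = basename(path))
}

#' @rdname read_acf_csv
#' @param curve an [fcs_curve()].
#' @export
write_acf_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  df <- data.frame(lag_s = curve$lags, G = curve$G)
  if (!is.null(curve$sigma)) df$sigma <- curve$sigma
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Adds provenance metadata (package version, config hash, seed) under
#' `$meta`; the timestamp is isolated in the single field
#' `$meta$timestamp` so reports from identical configurations are otherwise
#' byte-identical.
#'
#' @param report named list of results.
#' @param path output JSON path.
#' @param config the configuration list the report was produced from.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = list()) {
  report$meta <- list(
    package = "fcskinetics",
    version = as.character(utils::packageVersion("fcskinetics")),
    config_hash = digest::digest(config),
    seed = config$seed %||% NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
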
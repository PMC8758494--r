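# Trace I/O. The archival format of the pipeline is CSV (header
# `time_s,value`, full float precision) with a JSON metadata sidecar
# (`<path>.json`: sampling rate, units, t0, label). All downstream modules
# consume TimeSeries / SpikeTrain objects, never raw files.

#' Write a trace to CSV (lossless)
#'
#' Writes columns `time_s,value` at full double precision (`%.17g`, so
#' write/read round-trips are bit-identical) plus a JSON sidecar at
#' `<path>.json` holding sampling rate, units, start time and label.
#'
#' @param ts a [TimeSeries-class].
#' @param path output CSV path.
#' @param sidecar logical; write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTrace(TimeSeries(rnorm(10), 5000, units = "mV"), f)
#' ts <- readTrace(f)
writeTrace <- function(ts, path, sidecar = TRUE) {
  if (!is(ts, "TimeSeries")) stop("'ts' must be a TimeSeries", call. = FALSE)
  validObject(ts)
  tvec <- startTime(ts) + (seq_along(samples(ts)) - 1) / samplingRate(ts)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(sprintf("%.17g", tvec), sprintf("%.17g", samples(ts)),
                   sep = ","), con)
  if (sidecar) {
    jsonlite::write_json(
      list(sampling_rate_hz = samplingRate(ts), units = traceUnits(ts),
           t0_s = startTime(ts), label = traceLabel(ts)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trace from file
#'
#' CSV traces use the dialect written by [writeTrace()]: a header row with a
#' `time_s` column and one or more value columns. The sampling rate is taken
#' from the JSON sidecar if present, otherwise from the `samplingRate`
#' argument; if neither is available an error is raised (the rate is never
#' silently inferred from the time column). ABF (Axon Binary Format) input is
#' not supported by this build: no ABF parser is available, so ABF files
#' must be exported to CSV first.
#'
#' @param path input file path.
#' @param format `"csv"` or `"abf"`.
#' @param channel for multi-column CSVs, the value column to read: a column
#'   name or a 1-based index among the non-time columns. Default: first
#'   value column.
#' @param samplingRate sampling rate in Hz, required for CSVs without a
#'   metadata sidecar.
#' @param units units override; defaults to the sidecar value or `"arbitrary"`.
#' @return a [TimeSeries-class].
#' @export
readTrace <- function(path, format = c("csv", "abf"), channel = NULL,
                      samplingRate = NULL, units = NULL) {
  format <- match.arg(format)
  if (format == "abf")
    stop("ABF input is not supported: no ABF parser is available in this ",
         "installation; export the recording to CSV (time_s,value) instead",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("CSV must contain a 'time_s' column: ", path, call. = FALSE)
  valueCols <- setdiff(names(df), "time_s")
  if (!length(valueCols)) stop("CSV has no value column: ", path, call. = FALSE)
  if (is.null(channel)) {
    col <- valueCols[1]
  } else if (is.character(channel)) {
    if (!channel %in% valueCols)
      stop("unknown channel '", channel, "'; available: ",
           paste(valueCols, collapse = ", "), call. = FALSE)
    col <- channel
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(valueCols))
      stop("channel index ", ch, " out of range 1..", length(valueCols),
           call. = FALSE)
    col <- valueCols[ch]
  }
  meta <- NULL
  sidecarPath <- paste0(path, ".json")
  if (file.exists(sidecarPath))
    meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  rate <- if (!is.null(samplingRate)) samplingRate else meta$sampling_rate_hz
  if (is.null(rate))
    stop("no sampling rate available for '", path,
         "': supply 'samplingRate' or provide a JSON sidecar", call. = FALSE)
  t0 <- if (!is.null(meta$t0_s)) meta$t0_s else df$time_s[1]
  u <- if (!is.null(units)) units
       else if (!is.null(meta$units)) meta$units else "arbitrary"
  lbl <- if (!is.null(meta$label) && length(valueCols) == 1L) meta$label else col
  TimeSeries(df[[col]], rate, t0 = t0, units = u, label = lbl)
}
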
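#' Uniformly sampled physiological signal
#'
#' Container for a single channel of uniformly sampled physiological data.
#' Units are carried as metadata and never converted: ECG in mV, PPG and
#' respiration in arbitrary units.
#'
#' @param samples numeric vector of samples; must be finite and non-empty.
#' @param fs sampling rate in Hz (> 0).
#' @param kind channel kind, one of `"ECG"`, `"PPG"`, `"RESP"`.
#' @param t0 start time in seconds (default 0).
#' @param units unit string; defaults to `"mV"` for ECG, `"a.u."` otherwise.
#'
#' @return An object of class `tsSignal`: a list with elements `samples`,
#'   `fs`, `kind`, `t0`, `units`.
#' @export
#' @examples
#' s <- tsSignal(sin(2 * pi * 1 * (0:511) / 512), fs = 512, kind = "ECG")
#' duration(s)
tsSignal <- function(samples, fs, kind = c("ECG", "PPG", "RESP"), t0 = 0,
                     units = NULL) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop("non-finite sample at index ", bad)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (is.null(units)) units <- if (kind == "ECG") "mV" else "a.u."
  structure(list(samples = samples, fs = fs, kind = kind,
                 t0 = as.numeric(t0), units = units),
            class = "tsSignal")
}

#' @export
print.tsSignal <- function(x, ...) {
  cat(sprintf("<tsSignal> %s: %d samples @ %g Hz (%.2f s), t0 = %g s, units = %s\n",
              x$kind, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0, x$units))
  invisible(x)
}

#' Signal duration in seconds
#' @param x a [tsSignal()].
#' @return Duration in seconds (`n / fs`).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "tsSignal"))
  length(x$samples) / x$fs
}

#' Sampling rate accessor
#' @param x a [tsSignal()].
#' @return Sampling rate in Hz.
#' @export
samplingRate <- function(x) {
  stopifnot(inherits(x, "tsSignal"))
  x$fs
}

#' Sample time axis
#' @param x a [tsSignal()].
#' @return Vector of sample times in seconds (`t0 + (0:(n-1))/fs`).
#' @export
signalTimes <- function(x) {
  stopifnot(inherits(x, "tsSignal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Extract a time window from a signal
#'
#' Returns the half-open window `[start, stop)` expressed in seconds from the
#' start of the signal.  `t0` of the result is updated accordingly so that
#' segmenting composes: `segmentSignal(segmentSignal(s, a, b), c, d)` equals
#' `segmentSignal(s, a + c, a + d)`.
#'
#' @param x a [tsSignal()].
#' @param start,stop window bounds in seconds, `0 <= start < stop <= duration`.
#' @return A [tsSignal()] holding the `(stop - start) * fs` samples of the
#'   window.
#' @export
segmentSignal <- function(x, start, stop) {
  stopifnot(inherits(x, "tsSignal"))
  dur <- duration(x)
  if (!(start >= 0 && start < stop && stop <= dur + 1e-9)) {
    stop(sprintf("invalid window [%g, %g) for a %.3f s signal", start, stop, dur))
  }
  i0 <- round(start * x$fs)
  i1 <- round(stop * x$fs)
  if (i1 <= i0) stop("empty window")
  out <- x
  out$samples <- x$samples[(i0 + 1):i1]
  out$t0 <- x$t0 + i0 / x$fs
  out
}

# ---------------------------------------------------------------------------
# CSV / EDF signal I/O

#' Read a physiological signal from disk
#'
#' CSV files must have a header row, either `time_s,value` (sampling rate
#' inferred from the time column when `fs` is not given) or a single `value`
#' column (then `fs` is required).  EDF files are read with a minimal
#' European-Data-Format reader; the channel whose label contains `kind` is
#' selected.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param kind channel kind (`"ECG"`, `"PPG"`, `"RESP"`).
#' @param fs sampling rate in Hz; required for single-column CSV.
#' @return A validated [tsSignal()].
#' @export
readSignal <- function(path, format = c("auto", "csv", "edf"),
                       kind = c("ECG", "PPG", "RESP"), fs = NULL) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(readEdf(path, kind = kind))

  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no data rows in ", path)
  if (all(c("time_s", "value") %in% names(df))) {
    vals <- suppressWarnings(as.numeric(df$value))
    if (anyNA(vals) || !all(is.finite(vals))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))[1L]
      stop("non-finite or unparseable value at data row ", bad, " of ", path)
    }
    tt <- as.numeric(df$time_s)
    # the file's own time column is authoritative for the sampling rate
    dt <- if (length(tt) > 1L) median(diff(tt)) else NA_real_
    if (is.finite(dt) && dt > 0) {
      fs <- 1 / dt
    } else if (is.null(fs)) {
      stop("cannot infer sampling rate from time column of ", path)
    }
    tsSignal(vals, fs = fs, kind = kind, t0 = tt[1L])
  } else if ("value" %in% names(df)) {
    if (is.null(fs)) stop("fs not given and not inferable for ", path)
    vals <- suppressWarnings(as.numeric(df$value))
    if (anyNA(vals) || !all(is.finite(vals))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))[1L]
      stop("non-finite or unparseable value at data row ", bad, " of ", path)
    }
    tsSignal(vals, fs = fs, kind = kind)
  } else {
    stop("unrecognised CSV header in ", path,
         " (expected `time_s,value` or `value`)")
  }
}

#' Write a signal to disk
#'
#' @param x a [tsSignal()].
#' @param path output path.
#' @param format `"csv"` (two columns `time_s,value`) or `"edf"` (16-bit).
#' @return `path`, invisibly.
#' @export
writeSignal <- function(x, path, format = c("csv", "edf")) {
  stopifnot(inherits(x, "tsSignal"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(time_s = signalTimes(x), value = x$samples)
    write.csv(df, path, row.names = FALSE)
  } else {
    writeEdf(x, path)
  }
  invisible(path)
}

# --- minimal EDF (European Data Format) support -----------------------------
# 16-bit integers, one data record holding the whole signal. Sufficient for
# exchanging single/multi-channel physiological recordings with standard
# readers; not a full implementation of EDF+ annotations.

padField <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

writeEdf <- function(x, path) {
  sigs <- if (inherits(x, "tsSignal")) list(x) else x
  ns <- length(sigs)
  n <- length(sigs[[1L]]$samples)
  fs <- sigs[[1L]]$fs
  for (s in sigs) {
    if (length(s$samples) != n || s$fs != fs) {
      stop("all EDF channels must share length and sampling rate")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField("X X X X", 80),
    padField("synthetic recording", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (ns + 1), 8),
    padField("", 44),
    padField("1", 8),                       # number of data records
    padField(format(n / fs, digits = 8), 8),# record duration (s)
    padField(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(f, w) {
    for (s in sigs) writeChar(padField(f(s), w), con, eos = NULL)
  }
  ranges <- lapply(sigs, function(s) {
    r <- range(s$samples)
    if (r[1] == r[2]) r <- r + c(-1, 1)   # avoid zero physical span
    r
  })
  fld(function(s) s$kind, 16)              # label
  fld(function(s) "", 80)                  # transducer
  fld(function(s) s$units, 8)              # physical dimension
  for (r in ranges) writeChar(padField(format(r[1], digits = 8), 8), con, eos = NULL)
  for (r in ranges) writeChar(padField(format(r[2], digits = 8), 8), con, eos = NULL)
  fld(function(s) "-32768", 8)             # digital min
  fld(function(s) "32767", 8)              # digital max
  fld(function(s) "", 80)                  # prefiltering
  fld(function(s) n, 8)                    # samples per record
  fld(function(s) "", 32)                  # reserved
  for (i in seq_len(ns)) {
    r <- ranges[[i]]
    dig <- round((sigs[[i]]$samples - r[1]) / (r[2] - r[1]) * 65535) - 32768
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

readEdf <- function(path, kind = "ECG") {
  con <- file(path, "rb")
  on.exit(close(con))
  rdChar <- function(w) readChar(con, w, useBytes = TRUE)
  rdChar(8 + 80 + 80 + 8 + 8)
  nbytes <- as.integer(rdChar(8))
  rdChar(44)
  nrec <- as.integer(rdChar(8))
  recdur <- as.numeric(rdChar(8))
  ns <- as.integer(rdChar(4))
  get <- function(w) vapply(seq_len(ns), function(i) trimws(rdChar(w)), "")
  labels <- get(16); get(80); units <- get(8)
  pmin <- as.numeric(get(8)); pmax <- as.numeric(get(8))
  dmin <- as.numeric(get(8)); dmax <- as.numeric(get(8))
  get(80)
  spr <- as.integer(get(8))
  get(32)
  chosen <- grep(kind, labels, ignore.case = TRUE)
  if (!length(chosen)) {
    stop("no channel labelled like '", kind, "' in ", path,
         " (labels: ", paste(labels, collapse = ", "), ")")
  }
  chosen <- chosen[1L]
  out <- NULL
  for (rec in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (i == chosen) {
        phys <- pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        out <- c(out, phys)
      }
    }
  }
  fs <- spr[chosen] / (recdur / 1)
  tsSignal(out, fs = spr[chosen] / recdur, kind = kind, units = units[chosen])
}

# ---------------------------------------------------------------------------
# Report I/O

#' Write an analysis report
#'
#' Serialises a (possibly nested) list of results.  JSON keeps full numeric
#' precision; CSV flattens scalar fields to a two-column `field,value` table;
#' TXT writes a human-readable listing.
#'
#' @param report non-empty named list (e.g. an `hrvMetrics` or session report).
#' @param path output path.
#' @param format `"json"`, `"csv"` or `"txt"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "csv", "txt")) {
  format <- match.arg(format)
  if (length(report) == 0L) stop("empty report")
  rep <- unclass(report)
  if (format == "json") {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    flat <- unlist(rep)
    df <- data.frame(field = names(flat), value = as.character(flat))
    if (format == "csv") {
      write.csv(df, path, row.names = FALSE)
    } else {
      writeLines(sprintf("%-28s %s", df$field, df$value), path)
    }
  }
  invisible(path)
}

#' Read back a JSON report
#' @param path path written by [writeReport()] with `format = "json"`.
#' @return The report as a list.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---------------------------------------------------------------------------

#' Biofeedback session configuration
#'
#' @param fs sampling rate in Hz.
#' @param channels channel kinds recorded in the session.
#' @param epoch_length analysis epoch length in seconds.
#' @param sweep_frequencies paced-breathing sweep grid in breaths/min; must
#'   lie in \[4, 7\] (default 4 to 7 in steps of 0.5).
#' @param seed integer seed for any simulated component.
#' @return An object of class `sessionConfig`.
#' @export
sessionConfig <- function(fs = 512, channels = c("ECG", "RESP"),
                          epoch_length = 300,
                          sweep_frequencies = seq(4, 7, by = 0.5),
                          seed = 1L) {
  if (any(sweep_frequencies < 4 - 1e-9) || any(sweep_frequencies > 7 + 1e-9)) {
    stop("sweep frequencies must lie within [4, 7] breaths/min")
  }
  if (fs <= 0) stop("fs must be positive")
  if (epoch_length <= 0) stop("epoch_length must be positive")
  structure(list(fs = fs, channels = channels, epoch_length = epoch_length,
                 sweep_frequencies = sort(sweep_frequencies),
                 seed = as.integer(seed)),
            class = "sessionConfig")
}
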
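# File I/O: raw-float with DCF sidecar, single-column delimited text,
# minimal 16-bit continuous EDF, and 3-column state schedules.

#' Write a trace to disk
#'
#' Formats:
#' \describe{
#'   \item{`raw-float`}{little-endian 64-bit doubles plus a `<path>.meta`
#'     sidecar (DCF text) holding rate, channel and start time.}
#'   \item{`delimited`}{one sample per line; the rate is *not* stored and
#'     must be supplied again on reading.}
#'   \item{`edf`}{minimal EDF (16-bit, 1 s data records); pass a list of
#'     traces for a multi-channel file. Quantized to the 16-bit range of
#'     each channel.}
#' }
#'
#' @param trace A [signal_trace()] (or list of traces for `edf`).
#' @param path Output file path.
#' @param format One of `"raw-float"`, `"delimited"`, `"edf"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("raw-float", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(trace, path))
  stopifnot(inherits(trace, "signal_trace"))
  if (format == "raw-float") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(trace$samples, con, size = 8, endian = "little")
    meta <- matrix(c(as.character(trace$rate), trace$channel_id,
                     as.character(trace$start_time)), nrow = 1,
                   dimnames = list(NULL, c("rate", "channel_id", "start_time")))
    write.dcf(meta, paste0(path, ".meta"))
  } else {
    writeLines(format(trace$samples, digits = 17, scientific = TRUE,
                      trim = TRUE), path)
  }
  invisible(path)
}

#' Read a trace from disk
#'
#' @param path Input file path.
#' @param format One of `"raw-float"`, `"delimited"`, `"edf"`.
#' @param rate Sampling rate override in Hz; required for `delimited`
#'   (which stores no metadata), optional otherwise.
#' @param channel_id Channel label override.
#' @return A [signal_trace()]; for `edf`, a list of one trace per channel.
#' @export
read_trace <- function(path, format = c("raw-float", "delimited", "edf"),
                       rate = NULL, channel_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") return(read_edf(path))
  if (format == "raw-float") {
    meta_path <- paste0(path, ".meta")
    meta <- if (file.exists(meta_path)) as.data.frame(read.dcf(meta_path),
                                                     stringsAsFactors = FALSE)
            else NULL
    if (is.null(rate)) {
      if (is.null(meta)) stop("missing sampling rate: no sidecar metadata and no override")
      rate <- as.numeric(meta$rate)
    }
    st <- if (!is.null(meta) && !is.null(meta$start_time))
      as.numeric(meta$start_time) else 0
    ch <- channel_id %||% (if (!is.null(meta)) meta$channel_id else "chan")
    n <- file.size(path) / 8
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n, size = 8, endian = "little")
    signal_trace(x, rate, st, ch)
  } else {
    if (is.null(rate)) stop("missing sampling rate: delimited traces carry no metadata")
    x <- as.numeric(readLines(path))
    signal_trace(x, rate, 0, channel_id %||% "chan")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF ----------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(traces, path) {
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  rates <- vapply(traces, function(t) t$rate, 0)
  if (length(unique(rates)) != 1L) stop("EDF writer requires a common sampling rate")
  rate <- rates[1L]
  if (abs(rate - round(rate)) > 1e-9) stop("EDF writer requires an integer rate")
  rate <- as.integer(round(rate))
  ns <- length(traces)
  nsamp <- min(vapply(traces, function(t) length(t$samples), 0L))
  nrec <- nsamp %/% rate
  if (nrec < 1L) stop("trace shorter than one 1 s EDF record")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80), pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  phys_min <- vapply(traces, function(t) min(t$samples[seq_len(nrec * rate)]), 0)
  phys_max <- vapply(traces, function(t) max(t$samples[seq_len(nrec * rate)]), 0)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8)
  fields <- list(
    vapply(traces, function(t) t$channel_id, ""),
    rep("", ns), rep("au", ns),
    formatC(phys_min, format = "g", digits = 7),
    formatC(phys_max, format = "g", digits = 7),
    rep("-32768", ns), rep("32767", ns),
    rep("", ns), rep(as.character(rate), ns))
  for (i in seq_along(fields))
    writeChar(paste(pad_field(fields[[i]], widths[i]), collapse = ""),
              con, eos = NULL)
  writeChar(paste(rep(pad_field("", 32), ns), collapse = ""), con, eos = NULL)
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (s in seq_len(ns)) {
      dig <- round((traces[[s]]$samples[idx] - phys_min[s]) / scale[s]) - 32768
      writeBin(as.integer(pmax(-32768, pmin(32767, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  nspr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  out <- lapply(seq_len(ns), function(s) numeric(nrec * nspr[s]))
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nspr[s], size = 2,
                     endian = "little", signed = TRUE)
      out[[s]][((r - 1L) * nspr[s] + 1L):(r * nspr[s])] <-
        phys_min[s] + (dig - dig_min[s]) *
          (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    }
  }
  lapply(seq_len(ns), function(s)
    signal_trace(out[[s]], nspr[s] / recdur, 0, labels[s]))
}

# ---- state schedules ------------------------------------------------------

#' State schedule
#'
#' Ordered, non-overlapping labelled epochs covering a contiguous span,
#' in the style of a hypnogram or a trial structure.
#'
#' @param start,end Numeric vectors of epoch bounds in seconds
#'   (half-open intervals `[start, end)`).
#' @param label Character vector of state labels (e.g. wake, SWS, task).
#' @return A `data.frame` of class `state_schedule`.
#' @export
state_schedule <- function(start, end, label) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("schedule must contain at least one epoch")
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end <= df$start)) stop("epoch end must exceed start")
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)] - 1e-9))
    stop("epochs overlap")
  if (nrow(df) > 1L && any(abs(df$start[-1L] - df$end[-nrow(df)]) > 1e-6))
    stop("epochs must cover a contiguous span")
  rownames(df) <- NULL
  class(df) <- c("state_schedule", "data.frame")
  df
}

#' Read / write a state schedule as 3-column delimited text
#' @param path File path.
#' @return [state_schedule()] for the reader; `path` invisibly for the writer.
#' @export
read_schedule <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  state_schedule(df[[1L]], df[[2L]], df[[3L]])
}

#' @rdname read_schedule
#' @param schedule A [state_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  write.table(data.frame(start_s = schedule$start, end_s = schedule$end,
                         label = schedule$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Label lookup: state of each time point (NA outside the schedule).
schedule_label_at <- function(schedule, times) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(schedule))) {
    sel <- times >= schedule$start[i] & times < schedule$end[i]
    out[sel] <- schedule$label[i]
  }
  out
}
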
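# Recording and event-log I/O: CSV (text fixtures), EDF/BDF (interchange).

#' Read a multichannel recording
#'
#' CSV files carry one column per channel, a label header and a leading
#' \code{# fs=... start_time=...} comment line. EDF (16-bit) and BDF
#' (24-bit) are the standard polygraphic interchange formats; labels,
#' sampling rate and physical scaling are taken from the file header.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"edf"}
#'   or \code{"bdf"}.
#' @return a \code{bci_recording}.
#' @seealso \code{\link{write_recording}}
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf", "bdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf", bdf = "bdf",
                     stop("cannot infer format from extension of ", path))
  }
  switch(format,
         csv = .read_csv_recording(path),
         edf = .read_edf_recording(path, bits = 16),
         bdf = .read_edf_recording(path, bits = 24))
}

#' Write a recording to CSV or EDF
#'
#' @param rec a \code{bci_recording}.
#' @param path destination; extension selects the format unless given.
#' @param format \code{"auto"}, \code{"csv"} or \code{"edf"}.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "bci_recording"))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", edf = "edf",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "csv") .write_csv_recording(rec, path) else .write_edf_recording(rec, path)
  invisible(path)
}

.write_csv_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g start_time=%.10g", rec$fs, rec$start_time), con)
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$labels
  utils::write.csv(df, con, row.names = FALSE)
}

.read_csv_recording <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*fs=", first)) stop("corrupt CSV recording header (expected '# fs=...'): ", path)
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", first))
  st <- if (grepl("start_time=", first)) {
    as.numeric(sub(".*start_time=([0-9.eE+-]+).*", "\\1", first))
  } else 0
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  recording(t(as.matrix(df)), fs = fs, labels = names(df), start_time = st)
}

# ---- EDF / BDF ----

.pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = -n, flag = " ")
}

.write_edf_recording <- function(rec, path) {
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  pmin_ <- apply(rec$samples, 1, min)
  pmax_ <- apply(rec$samples, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 * (1 + ns)
  # one data record holding the whole recording keeps the length exact
  writeChar(paste0(.pad("0", 8), .pad("X", 80), .pad("mealbci", 80),
                   .pad("01.01.00", 8), .pad("00.00.00", 8),
                   .pad(hdr_bytes, 8), .pad("", 44), .pad(1, 8),
                   .pad(format(n / rec$fs, digits = 7), 8), .pad(ns, 4)),
            con, eos = NULL)
  fld <- function(vals, w) writeChar(paste(vapply(vals, .pad, "", n = w), collapse = ""), con, eos = NULL)
  fld(rec$labels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(format(pmin_, digits = 7), 8)
  fld(format(pmax_, digits = 7), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(n, ns), 8)
  fld(rep("", ns), 32)
  for (s in seq_len(ns)) {
    scl <- (dmax - dmin) / (pmax_[s] - pmin_[s])
    dig <- as.integer(round((rec$samples[s, ] - pmin_[s]) * scl + dmin))
    writeBin(dig, con, size = 2, endian = "little")
  }
}

.read_edf_recording <- function(path, bits = 16) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    trimws(rawToChar(raw[raw != as.raw(0)]))
  }
  ver <- readBin(con, "raw", 8)
  is_bdf <- ver[1] == as.raw(255)
  if (bits == 24 && !is_bdf) stop("not a BDF file: ", path)
  invisible(rd(80)); invisible(rd(80)); invisible(rd(8)); invisible(rd(8))
  hdr_bytes <- as.integer(rd(8))
  invisible(rd(44))
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("corrupt EDF/BDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (bits == 16) {
        dig <- readBin(con, "integer", spr[s], size = 2, signed = TRUE, endian = "little")
      } else {
        raw3 <- readBin(con, "raw", 3 * spr[s])
        m <- matrix(as.integer(raw3), nrow = 3)
        dig <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        dig <- ifelse(dig >= 2^23, dig - 2^24, dig)
      }
      scl <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
      out[[s]][((r - 1) * spr[s] + 1):(r * spr[s])] <- (dig - dmin[s]) * scl + pmin_[s]
    }
  }
  fs <- spr[1] / rec_dur
  recording(do.call(rbind, out), fs = fs, labels = labels)
}

# ---- event logs ----

#' Construct an event log
#'
#' Event logs record ground-truth or detected occurrences on the recording
#' timeline: blink triples, cued stimulus frequencies, chew bursts,
#' classifications and robot commands.
#'
#' @param onset_s event onsets, seconds from recording start.
#' @param duration_s event durations, seconds (0 for instantaneous).
#' @param label event labels, e.g. \code{"eb"}, \code{"ssvep:9.8"},
#'   \code{"chew"}, \code{"cmd:FEED"}.
#' @param value optional numeric payload (stimulus index, evidence value).
#' @return a data frame of class \code{event_log}, ordered by onset.
#' @export
event_log <- function(onset_s = numeric(0), duration_s = numeric(0),
                      label = character(0), value = NA_real_) {
  df <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   label = as.character(label),
                   value = if (length(onset_s)) as.numeric(value) else numeric(0),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

#' @rdname event_log
#' @param ... event logs to concatenate.
#' @export
bind_events <- function(...) {
  parts <- Filter(function(d) nrow(d) > 0, list(...))
  if (length(parts) == 0) return(event_log())
  df <- do.call(rbind, lapply(parts, as.data.frame))
  event_log(df$onset_s, df$duration_s, df$label, df$value)
}

#' Read / write event logs as tab-separated text
#'
#' Columns: \code{onset_s}, \code{duration_s}, \code{label}, \code{value}.
#'
#' @param events an \code{event_log}.
#' @param path file path.
#' @return \code{read_event_log} returns an \code{event_log};
#'   \code{write_event_log} returns \code{path} invisibly.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  event_log(df$onset_s, df$duration_s, df$label,
            if ("value" %in% names(df)) df$value else NA_real_)
}
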
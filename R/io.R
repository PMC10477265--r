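# Readers and writers: per-channel CSV sessions, EDF recordings, score
# tables, feature tables. Session files are named <participant>_<time>.<ext>;
# score rows are matched on participant id + session time (timestamps are
# compared after stripping separators, so "2024-01-02T09:00:00" and
# "20240102T090000" match).

norm_time <- function(x) gsub("[^0-9A-Za-z]", "", as.character(x))

parse_session_filename <- function(path) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  us <- regexpr("_", base, fixed = TRUE)
  if (us < 0) return(list(participant = base, time = NA_character_))
  list(participant = substr(base, 1L, us - 1L),
       time = substr(base, us + 1L, nchar(base)))
}

#' Read a per-session score table
#'
#' Delimited text (TSV or CSV, sniffed from the header line) with columns
#' `participant_id`, `session_time`, `dd_score` and optionally `medicated`
#' and `notes`. Empty `dd_score` cells become `NA`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), quote = "\"")
  need <- c("participant_id", "session_time", "dd_score")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  df$dd_score <- suppressWarnings(as.integer(df$dd_score))
  if (is.null(df$medicated)) df$medicated <- FALSE
  df$medicated <- as.logical(df$medicated)
  if (is.null(df$notes)) df$notes <- ""
  df
}

lookup_score <- function(score_table, participant, time) {
  if (is.null(score_table)) return(NULL)
  hit <- score_table$participant_id == participant &
    norm_time(score_table$session_time) == norm_time(time)
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(NULL)
  score_table[which(hit)[1L], ]
}

#' Read one EEG session from disk
#'
#' Reads an EDF/EDF+ continuous recording or a per-channel CSV (header row
#' of channel labels, one sample per line, microvolts) and attaches the DD
#' score looked up in `score_table`. A session absent from the score table
#' gets `dd_score = NA` (it is excluded later by [filter_sessions()], not
#' here). A channel count differing from `channel_labels` is a structural
#' error.
#'
#' @param path Session file, `.edf` or `.csv`. Files are expected to be
#'   named `<participant>_<session_time>.<ext>` unless `participant_id` and
#'   `session_time` are given explicitly.
#' @param score_table Data frame from [read_score_table()], or `NULL`.
#' @param config An [analysis_config()] (currently carried for interface
#'   symmetry; reading does not depend on it).
#' @param participant_id,session_time Optional explicit identifiers
#'   overriding the filename convention.
#' @param channel_labels Expected channel labels in recording order.
#' @param sampling_rate Sampling rate for CSV input (EDF carries its own).
#' @return An [eeg_session()].
#' @export
read_session <- function(path, score_table = NULL, config = analysis_config(),
                         participant_id = NULL, session_time = NULL,
                         channel_labels = epoc_montage, sampling_rate = 128) {
  if (!file.exists(path)) stop("session file not found: ", path)
  meta <- parse_session_filename(path)
  if (is.null(participant_id)) participant_id <- meta$participant
  if (is.null(session_time)) session_time <- meta$time

  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "edf") {
    edf <- read_edf(path)
    sig <- edf$signal
    labels <- edf$labels
    sampling_rate <- edf$sampling_rate
  } else {
    parsed <- tryCatch(
      read.table(path, header = TRUE, sep = ",", colClasses = "numeric",
                 check.names = FALSE),
      error = function(e) stop("format error while parsing ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    labels <- names(parsed)
    sig <- t(as.matrix(parsed))
  }
  if (length(labels) != length(channel_labels))
    stop("structural error: ", path, " has ", length(labels),
         " channels but ", length(channel_labels), " labels were declared")
  # reorder to the declared montage when labels match by name
  if (all(channel_labels %in% labels)) {
    sig <- sig[match(channel_labels, labels), , drop = FALSE]
    labels <- channel_labels
  }

  row <- lookup_score(score_table, participant_id, session_time)
  eeg_session(sig, channel_labels = labels, sampling_rate = sampling_rate,
              participant_id = participant_id, session_time = session_time,
              dd_score = if (is.null(row)) NA_integer_ else row$dd_score,
              notes = if (is.null(row)) "" else row$notes,
              medicated = if (is.null(row)) FALSE else isTRUE(row$medicated))
}

#' Write one session as per-channel CSV
#'
#' Inverse of the CSV dialect read by [read_session()]: header row of
#' channel labels, one sample per line, microvolts.
#'
#' @param session An [eeg_session()].
#' @param path Output path.
#' @export
write_session_csv <- function(session, path) {
  df <- as.data.frame(t(session$signal))
  names(df) <- session$channel_labels
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a score table
#'
#' @param scores Data frame with `participant_id`, `session_time`,
#'   `dd_score`, and optionally `medicated`, `notes`.
#' @param path Output path (TSV).
#' @export
write_score_table <- function(scores, path) {
  write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

feature_table_columns <- c("participant", "session", "channel",
                           "frequency_hz", "mras", "mna", "prr",
                           "n_resets", "n_cycles")

#' Write a feature table
#'
#' Long-format tab-separated file, one row per (session, channel,
#' frequency), numeric values at full double precision so that
#' [read_feature_table()] inverts the write exactly.
#'
#' @param table A feature table data frame (see [extract_features()]).
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table is empty; nothing to write")
  cols <- intersect(feature_table_columns, names(table))
  out <- table[, cols, drop = FALSE]
  for (nm in cols) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path File path.
#' @return A data frame of class `c("prr_features", "data.frame")`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (nm in intersect(c("frequency_hz", "mras", "mna", "prr", "n_cycles"),
                       names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  if ("n_resets" %in% names(df)) df$n_resets <- as.integer(round(as.numeric(df$n_resets)))
  class(df) <- c("prr_features", "data.frame")
  df
}

read_ascii <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

#' Minimal EDF/EDF+ continuous reader
#'
#' Parses the 256-byte fixed header, the per-signal header block, and the
#' interleaved 16-bit data records of a continuous EDF recording, applying
#' the physical calibration `phys = physmin + (dig - digmin) * gain`.
#' Annotation channels (`EDF Annotations`) are dropped. All retained
#' signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return List with `signal` (channels x samples matrix), `labels`,
#'   `sampling_rate`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (!identical(version, "0"))
    stop("format error in ", path, ": not an EDF file (version field '",
         version, "')")
  invisible(read_ascii(con, 80L))  # patient id
  invisible(read_ascii(con, 80L))  # recording id
  invisible(read_ascii(con, 8L))   # start date
  invisible(read_ascii(con, 8L))   # start time
  invisible(read_ascii(con, 8L))   # header bytes
  invisible(read_ascii(con, 44L))  # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  record_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("format error in ", path, ": bad signal count")

  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- fld(16L)
  invisible(fld(80L))  # transducer
  invisible(fld(8L))   # physical dimension
  physmin <- as.numeric(fld(8L))
  physmax <- as.numeric(fld(8L))
  digmin <- as.numeric(fld(8L))
  digmax <- as.numeric(fld(8L))
  invisible(fld(80L))  # prefiltering
  nsamp <- as.integer(fld(8L))
  invisible(fld(32L))  # reserved

  if (anyNA(c(physmin, physmax, digmin, digmax, nsamp, n_records, record_dur)))
    stop("format error in ", path, ": unparseable signal header fields")

  keep <- labels != "EDF Annotations"
  gain <- (physmax - physmin) / (digmax - digmin)
  data <- vector("list", ns)
  for (i in which(keep)) data[[i]] <- numeric(n_records * nsamp[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(raw) < nsamp[i])
        stop("format error in ", path, ": truncated data record ", r)
      if (keep[i])
        data[[i]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <-
          physmin[i] + (raw - digmin[i]) * gain[i]
    }
  }
  data <- data[keep]
  labels <- labels[keep]
  nsamp <- nsamp[keep]
  if (length(unique(nsamp)) != 1L)
    stop("EDF signals have differing sampling rates; not supported")
  list(signal = do.call(rbind, data), labels = labels,
       sampling_rate = nsamp[1L] / record_dur)
}
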
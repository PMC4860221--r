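# PSG container types and file I/O: 16-bit EDF for signals, a small
# documented XML dialect (with a JSON mirror) for scored events.

#' Construct a single PSG channel
#'
#' A channel is a uniformly sampled signal with a label (e.g. `"C3-A2"`),
#' a sampling rate in Hz and physical units.
#'
#' @param label Channel label, unique within a recording.
#' @param fs Sampling rate in samples/second (> 0).
#' @param samples Numeric vector of samples.
#' @param units Physical dimension string (e.g. `"uV"`, `"%"`).
#' @return An object of class `psg_channel`.
#' @export
psg_channel <- function(label, fs, samples, units = "uV") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is_scalar_num(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("channel '", label, "' contains NA samples", call. = FALSE)
  structure(list(label = label, fs = fs, units = units, samples = samples),
            class = "psg_channel")
}

#' @export
print.psg_channel <- function(x, ...) {
  cat(sprintf("<psg_channel> %s: %d samples @ %g Hz [%s]\n",
              x$label, length(x$samples), x$fs, x$units))
  invisible(x)
}

channel_duration <- function(ch) length(ch$samples) / ch$fs

#' Construct a multichannel PSG recording
#'
#' All channels must span the same duration (sample count / fs). Labels
#' must be unique.
#'
#' @param patient_id Patient identifier string.
#' @param channels List of [psg_channel()] objects.
#' @return An object of class `psg_recording` with fields `patient_id`,
#'   `channels` (named by label) and `duration` in seconds.
#' @export
psg_recording <- function(patient_id, channels) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (length(channels) == 0L) stop("recording needs at least one channel", call. = FALSE)
  labs <- vapply(channels, function(ch) ch$label, character(1))
  if (anyDuplicated(labs)) stop("duplicate channel labels: ",
                                paste(unique(labs[duplicated(labs)]), collapse = ", "),
                                call. = FALSE)
  durs <- vapply(channels, channel_duration, numeric(1))
  if (diff(range(durs)) > 1e-9)
    stop("channels span different durations: ",
         paste(sprintf("%s=%.3fs", labs, durs), collapse = ", "), call. = FALSE)
  names(channels) <- labs
  structure(list(patient_id = patient_id, channels = channels,
                 duration = durs[[1]]),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> patient %s: %d channels, %.1f s\n",
              x$patient_id, length(x$channels), x$duration))
  for (ch in x$channels)
    cat(sprintf("  %-10s %7g Hz  [%s]\n", ch$label, ch$fs, ch$units))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Annotations

ANNOTATION_KINDS <- c("stage", "apnea", "hypopnea", "leg_movement",
                      "artefact", "plm_series")

#' Construct an annotation set
#'
#' Timed scored events. Times are seconds from recording start; every event
#' occupies the half-open interval `[onset, onset + duration)`.
#'
#' @param events Data frame with columns `kind` (one of `r
#'   paste(ANNOTATION_KINDS, collapse = ", ")`), `onset`, `duration`
#'   (seconds), and optionally `channel` and `value` (e.g. the stage name
#'   or a position code). Missing optional columns are filled with `NA`.
#' @param duration Optional recording duration used to validate event
#'   extents.
#' @return A data frame of class `psg_annotations`, sorted by onset.
#' @export
psg_annotations <- function(events = NULL, duration = NULL) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(kind = character(), onset = numeric(),
                         duration = numeric(), channel = character(),
                         value = character(), stringsAsFactors = FALSE)
  } else {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
    for (col in c("channel", "value"))
      if (is.null(events[[col]])) events[[col]] <- NA_character_
    events <- events[, c("kind", "onset", "duration", "channel", "value")]
    events$kind <- as.character(events$kind)
    events$onset <- as.numeric(events$onset)
    events$duration <- as.numeric(events$duration)
    events$channel <- as.character(events$channel)
    events$value <- as.character(events$value)
  }
  bad <- setdiff(unique(events$kind), ANNOTATION_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(ANNOTATION_KINDS, collapse = ", "), call. = FALSE)
  if (any(events$onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
  if (any(events$duration < 0)) stop("event durations must be >= 0", call. = FALSE)
  if (!is.null(duration) && nrow(events) &&
      any(events$onset + events$duration > duration + 1e-9))
    stop("event extends beyond recording duration (", duration, " s)", call. = FALSE)
  events <- events[order(events$onset, events$kind), , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "recording_duration") <- duration
  class(events) <- c("psg_annotations", "data.frame")
  events
}

events_of_kind <- function(ann, kinds) {
  as.data.frame(ann)[ann$kind %in% kinds, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit) reader/writer.
#
# Layout: a 256-byte fixed header, 256 bytes per signal of per-signal
# header fields, then data records of interleaved little-endian int16
# blocks (one block of ns samples per signal per record). Record duration
# is fixed at 1 s here, so sampling rates must be positive integers and
# recordings are padded (by repeating the final sample) to a whole second.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 5), 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits using per-channel physical ranges taken
#' from the data, so round-trip error is at most half a quantization step
#' `(physMax - physMin)/65535`. Record duration is 1 s; sampling rates must
#' therefore be positive integers, and signals are padded to a whole second
#' by repeating the final sample.
#'
#' @param recording A [psg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "psg_recording"))
  chans <- recording$channels
  fs <- vapply(chans, function(ch) ch$fs, numeric(1))
  if (any(fs != round(fs)))
    stop("EDF writer requires integer sampling rates (1-s records); offending: ",
         paste(names(chans)[fs != round(fs)], collapse = ", "), call. = FALSE)
  n_rec <- as.integer(ceiling(recording$duration))
  ns <- length(chans)

  pmin_ <- pmax_ <- numeric(ns)
  digital <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- chans[[i]]$samples
    need <- n_rec * fs[i]
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    lo <- min(x); hi <- max(x)
    if (!is.finite(lo) || !is.finite(hi))
      stop("channel '", chans[[i]]$label, "' has non-finite samples", call. = FALSE)
    if (hi - lo < 1e-12) hi <- lo + 1   # constant channel: unit span
    pmin_[i] <- lo; pmax_[i] <- hi
    d <- round((x - lo) / (hi - lo) * 65535) - 32768
    digital[[i]] <- as.integer(pmin(pmax(d, -32768L), 32767L))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$patient_id, 80),
    edf_pad("plmdetect", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste(vapply(chans, function(ch) edf_pad(ch$label, 16), character(1)), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_pad("", 80), ns), collapse = ""), con, eos = NULL)   # transducer
  writeChar(paste(vapply(chans, function(ch) edf_pad(ch$units, 8), character(1)), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(seq_len(ns), function(i) edf_num(pmin_[i], 8), character(1)), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(seq_len(ns), function(i) edf_num(pmax_[i], 8), character(1)), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_pad(-32768, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_pad(32767, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_pad("", 80), ns), collapse = ""), con, eos = NULL)   # prefiltering
  writeChar(paste(vapply(seq_len(ns), function(i) edf_pad(fs[i], 8), character(1)), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_pad("", 32), ns), collapse = ""), con, eos = NULL)

  # interleave: record r holds fs[i] samples of signal i, signals in order
  idx <- lapply(seq_len(ns), function(i)
    matrix(digital[[i]], nrow = fs[i], ncol = n_rec))
  out <- matrix(0L, nrow = sum(fs), ncol = n_rec)
  off <- 0L
  for (i in seq_len(ns)) {
    out[(off + 1L):(off + fs[i]), ] <- idx[[i]]
    off <- off + as.integer(fs[i])
  }
  writeBin(as.integer(out), con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1):(off + width)]))
}

#' Read a recording from an EDF file
#'
#' @param path Path to a 16-bit EDF file.
#' @param patient_id Optional patient id override; defaults to the EDF
#'   local patient identification field.
#' @return A [psg_recording()].
#' @export
read_recording <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (header truncated): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  pid <- read_edf_field(hdr, 8, 80)
  n_rec <- suppressWarnings(as.integer(read_edf_field(hdr, 236, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_edf_field(hdr, 244, 8)))
  ns <- suppressWarnings(as.integer(read_edf_field(hdr, 252, 4)))
  if (is.na(ns) || ns <= 0) stop("invalid EDF header field 'number of signals'", call. = FALSE)
  if (is.na(n_rec) || n_rec < 0) stop("invalid EDF header field 'number of data records'", call. = FALSE)
  if (is.na(rec_dur) || rec_dur <= 0) stop("invalid EDF header field 'record duration'", call. = FALSE)
  shdr <- readBin(con, "raw", 256 * ns)
  if (length(shdr) < 256 * ns) stop("EDF signal header truncated", call. = FALSE)
  fld <- function(off0, width)
    vapply(seq_len(ns), function(i)
      read_edf_field(shdr, off0 * ns + (i - 1) * width, width), character(1))
  labels <- fld(0, 16)
  units <- fld(16 + 80, 8)
  pmin_ <- as.numeric(fld(16 + 80 + 8, 8))
  pmax_ <- as.numeric(fld(16 + 80 + 16, 8))
  dmin <- as.numeric(fld(16 + 80 + 24, 8))
  dmax <- as.numeric(fld(16 + 80 + 32, 8))
  spr <- as.integer(fld(16 + 80 + 8 * 5 + 80, 8))
  if (anyNA(spr) || any(spr <= 0)) stop("invalid EDF header field 'samples per record'", call. = FALSE)
  if (anyNA(pmin_) || anyNA(pmax_)) stop("invalid EDF header field 'physical min/max'", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate EDF signal labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)

  total <- sum(spr) * n_rec
  raw_data <- readBin(con, "integer", n = total, size = 2L, endian = "little")
  if (length(raw_data) < total)
    stop("EDF data section truncated: expected ", total, " samples, got ",
         length(raw_data), call. = FALSE)
  block <- matrix(raw_data, nrow = sum(spr), ncol = n_rec)
  offs <- c(0L, cumsum(spr))
  chans <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- as.numeric(block[(offs[i] + 1L):offs[i + 1L], ])
    phys <- pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    chans[[i]] <- psg_channel(labels[i], fs = spr[i] / rec_dur,
                              samples = phys, units = units[i])
  }
  psg_recording(if (is.null(patient_id)) pid else patient_id, chans)
}

# ---------------------------------------------------------------------------
# Annotation dialect.
#
# XML:  <annotations duration="21600">
#         <event kind="stage" onset="0" duration="30" value="N2"/>
#         <event kind="artefact" onset="12.5" duration="3" channel="C3-A2"/>
#       </annotations>
# JSON mirror: {"duration": 21600, "events": [{"kind": ..., ...}]}
# Onsets/durations are seconds from recording start, written with
# millisecond precision.

#' Write annotations to XML or JSON
#'
#' The format is chosen from the file extension (`.xml` or `.json`).
#'
#' @param annotations A [psg_annotations()] object.
#' @param path Output path ending in `.xml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "psg_annotations"))
  ev <- as.data.frame(annotations)
  dur <- attr(annotations, "recording_duration")
  ext <- tolower(tools::file_ext(path))
  fmt <- function(x) sprintf("%.3f", x)
  if (ext == "xml") {
    root <- xml2::xml_new_root("annotations")
    if (!is.null(dur)) xml2::xml_set_attr(root, "duration", fmt(dur))
    for (i in seq_len(nrow(ev))) {
      node <- xml2::xml_add_child(root, "event",
                                  kind = ev$kind[i],
                                  onset = fmt(ev$onset[i]),
                                  duration = fmt(ev$duration[i]))
      if (!is.na(ev$channel[i])) xml2::xml_set_attr(node, "channel", ev$channel[i])
      if (!is.na(ev$value[i])) xml2::xml_set_attr(node, "value", ev$value[i])
    }
    xml2::write_xml(root, path)
  } else if (ext == "json") {
    obj <- list(events = ev)
    if (!is.null(dur)) obj$duration <- dur
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else stop("unsupported annotation format '.", ext, "' (use .xml or .json)",
              call. = FALSE)
  invisible(path)
}

#' Read annotations from XML or JSON
#'
#' @param path Path to a file written by [write_annotations()] (or any
#'   document in the same dialect).
#' @return A [psg_annotations()] object.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xml") {
    doc <- xml2::read_xml(path)
    dur <- xml2::xml_attr(doc, "duration")
    dur <- if (is.na(dur)) NULL else as.numeric(dur)
    nodes <- xml2::xml_find_all(doc, "./event")
    ga <- function(a) xml2::xml_attr(nodes, a)
    ev <- data.frame(kind = ga("kind"),
                     onset = as.numeric(ga("onset")),
                     duration = as.numeric(ga("duration")),
                     channel = ga("channel"),
                     value = ga("value"),
                     stringsAsFactors = FALSE)
    psg_annotations(ev, duration = dur)
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ev <- obj$events
    if (is.null(ev) || (is.data.frame(ev) && nrow(ev) == 0L)) ev <- NULL
    psg_annotations(ev, duration = obj$duration)
  } else stop("unsupported annotation format '.", ext, "' (use .xml or .json)",
              call. = FALSE)
}
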
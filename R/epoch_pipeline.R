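# 5-second epoch segmentation, the three exclusion stages (artefact,
# apnea-adjacent, wake), and class balancing with per-patient stratified
# subsampling.

#' Segment a recording into fixed-length epochs
#'
#' Epochs are half-open intervals `[index * epoch_length, (index + 1) *
#' epoch_length)`; a trailing partial interval is dropped.
#'
#' @param recording A [psg_recording()], or a duration in seconds.
#' @param epoch_length Epoch length in seconds (default 5, the minimum
#'   PLM onset-to-onset interval).
#' @param patient_id Patient id (taken from the recording if given one).
#' @return A data frame of class `epoch_set` with columns `patient_id`,
#'   `index`, `start`, `end`, `label`, and logical exclusion flags
#'   `excl_artefact`, `excl_apnea_adjacent`, `excl_wake`.
#' @export
segment <- function(recording, epoch_length = 5, patient_id = NULL) {
  if (inherits(recording, "psg_recording")) {
    dur <- recording$duration
    if (is.null(patient_id)) patient_id <- recording$patient_id
  } else {
    dur <- as.numeric(recording)
    if (is.null(patient_id)) patient_id <- "unknown"
  }
  if (!is_scalar_num(epoch_length) || epoch_length <= 0)
    stop("epoch_length must be > 0", call. = FALSE)
  if (dur < epoch_length)
    stop("recording duration (", dur, " s) shorter than one epoch (",
         epoch_length, " s)", call. = FALSE)
  n <- floor(dur / epoch_length)
  es <- data.frame(patient_id = patient_id,
                   index = seq_len(n) - 1L,
                   start = (seq_len(n) - 1L) * epoch_length,
                   end = seq_len(n) * epoch_length,
                   label = NA_character_,
                   excl_artefact = FALSE,
                   excl_apnea_adjacent = FALSE,
                   excl_wake = FALSE,
                   stringsAsFactors = FALSE)
  class(es) <- c("epoch_set", "data.frame")
  es
}

flag_overlaps <- function(epoch_set, onsets, durations, margin = 0) {
  flag <- rep(FALSE, nrow(epoch_set))
  if (length(onsets)) for (i in seq_along(onsets)) {
    flag <- flag | intervals_overlap(epoch_set$start, epoch_set$end,
                                     max(0, onsets[i] - margin),
                                     onsets[i] + durations[i] + margin)
  }
  flag
}

#' Flag epochs overlapping artefact events
#'
#' An epoch overlapping an artefact on any channel is excluded from
#' classification.
#'
#' @param epoch_set An [segment()] result.
#' @param annotations A [psg_annotations()] object.
#' @return The epoch set with `excl_artefact` updated.
#' @export
exclude_artefacts <- function(epoch_set, annotations) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  ev <- events_of_kind(annotations, "artefact")
  epoch_set$excl_artefact <- flag_overlaps(epoch_set, ev$onset, ev$duration)
  epoch_set
}

#' Flag epochs adjacent to apneas/hypopneas
#'
#' Each respiratory event interval is dilated by `margin` seconds on both
#' sides (clamped at the recording start) and any overlapping epoch is
#' flagged, so retained leg movements are at least `margin` seconds from
#' any respiratory event.
#'
#' @param epoch_set An [segment()] result.
#' @param annotations A [psg_annotations()] object.
#' @param margin Dilation in seconds (default 15).
#' @return The epoch set with `excl_apnea_adjacent` updated.
#' @export
exclude_apnea_adjacent <- function(epoch_set, annotations, margin = 15) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  ev <- events_of_kind(annotations, c("apnea", "hypopnea"))
  epoch_set$excl_apnea_adjacent <-
    flag_overlaps(epoch_set, ev$onset, ev$duration, margin = margin)
  epoch_set
}

# Stage of the 30-s scoring page containing time `t`, from stage events.
stage_at <- function(t, stage_events, page = 30) {
  page_start <- floor(t / page) * page
  hit <- stage_events$onset <= page_start &
    page_start < stage_events$onset + stage_events$duration
  if (!any(hit)) return(NA_character_)
  stage_events$value[which(hit)[1L]]
}

#' Flag epochs scored as wakefulness
#'
#' A 5-s epoch inherits the stage of the 30-s scoring page containing its
#' start; epochs on Wake pages are flagged.
#'
#' @param epoch_set An [segment()] result.
#' @param annotations A [psg_annotations()] with stage events tiling the
#'   recording.
#' @return The epoch set with `excl_wake` updated.
#' @export
exclude_wake <- function(epoch_set, annotations) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  ev <- events_of_kind(annotations, "stage")
  if (nrow(ev) == 0L) stop("no stage events in annotations", call. = FALSE)
  stages <- vapply(epoch_set$start, stage_at, character(1), stage_events = ev)
  if (anyNA(stages)) {
    gaps <- unique(floor(epoch_set$start[is.na(stages)] / 30) * 30)
    stop("no stage coverage for scoring page(s) starting at: ",
         paste(utils::head(gaps, 5), collapse = ", "), " s", call. = FALSE)
  }
  epoch_set$excl_wake <- stages == "Wake"
  epoch_set
}

#' Apply all three exclusion stages
#'
#' Flags are computed independently, so the stages commute.
#'
#' @inheritParams exclude_apnea_adjacent
#' @return The epoch set with all three exclusion flags updated.
#' @export
exclude_all <- function(epoch_set, annotations, margin = 15) {
  epoch_set <- exclude_artefacts(epoch_set, annotations)
  epoch_set <- exclude_apnea_adjacent(epoch_set, annotations, margin)
  exclude_wake(epoch_set, annotations)
}

#' Retained (non-excluded) epochs
#'
#' @param epoch_set An epoch set with exclusion flags.
#' @return The subset of rows with no exclusion flag set.
#' @export
retained <- function(epoch_set) {
  es <- epoch_set[!(epoch_set$excl_artefact | epoch_set$excl_apnea_adjacent |
                      epoch_set$excl_wake), , drop = FALSE]
  class(es) <- c("epoch_set", "data.frame")
  es
}

#' Exclusion bookkeeping
#'
#' @param epoch_set An epoch set with exclusion flags.
#' @return Named integer vector: `total`, per-stage flag counts,
#'   `excluded` (union) and `retained`.
#' @export
provenance_counts <- function(epoch_set) {
  excl <- epoch_set$excl_artefact | epoch_set$excl_apnea_adjacent |
    epoch_set$excl_wake
  c(total = nrow(epoch_set),
    artefact = sum(epoch_set$excl_artefact),
    apnea_adjacent = sum(epoch_set$excl_apnea_adjacent),
    wake = sum(epoch_set$excl_wake),
    excluded = sum(excl),
    retained = sum(!excl))
}

#' Balance classes and subsample per patient
#'
#' Two deterministic stages given `seed`: (1) the majority class is
#' randomly downsampled to the minority class size, allocated across
#' patients proportionally to each patient's majority-class count
#' (largest-remainder rounding); (2) both classes are then subsampled to
#' `sample_percent` of the balanced per-class size, again allocated
#' proportionally per patient, sampling uniformly over each patient's
#' recording. Only recorded epochs are used; nothing is duplicated or
#' synthesized.
#'
#' @param epoch_set A labelled epoch set (typically `retained()` output).
#' @param sample_percent Percentage of the balanced size to keep
#'   (default 10).
#' @param seed Integer seed.
#' @return The sampled epoch set, sorted by patient and index.
#' @export
balance_and_subsample <- function(epoch_set, sample_percent = 10, seed = 1) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  if (anyNA(epoch_set$label)) stop("all epochs must be labelled", call. = FALSE)
  counts <- table(epoch_set$label)
  if (length(counts) < 2L || any(counts == 0))
    stop("both classes must be non-empty; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "), call. = FALSE)
  if (sample_percent <= 0 || sample_percent > 100)
    stop("sample_percent must be in (0, 100]", call. = FALSE)

  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  n_min <- min(counts)

  sample_class <- function(es, target) {
    # allocate `target` across patients proportionally, then sample
    # uniformly within each patient
    pats <- unique(es$patient_id)
    avail <- vapply(pats, function(p) sum(es$patient_id == p), integer(1))
    take <- apportion(target, avail, cap = avail)
    idx <- unlist(lapply(seq_along(pats), function(i) {
      rows <- which(es$patient_id == pats[i])
      if (take[i] >= length(rows)) rows else sort(sample(rows, take[i]))
    }))
    es[idx, , drop = FALSE]
  }

  with_seed(seed, {
    min_set <- epoch_set[epoch_set$label == minority, , drop = FALSE]
    maj_set <- epoch_set[epoch_set$label == majority, , drop = FALSE]
    maj_bal <- sample_class(maj_set, n_min)
    per_class <- max(1L, round(n_min * sample_percent / 100))
    out <- rbind(sample_class(min_set, per_class),
                 sample_class(maj_bal, per_class))
    out <- out[order(out$patient_id, out$index), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("epoch_set", "data.frame")
    out
  })
}
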
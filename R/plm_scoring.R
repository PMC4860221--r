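# Coleman-rule scoring of the leg-EMG channel. Used ONLY to produce
# ground-truth leg-movement / PLM-series events and epoch labels; leg EMG
# never contributes features.

#' Detect candidate leg movements on a leg-EMG channel
#'
#' The signal is rectified and smoothed with a moving-RMS envelope;
#' maximal runs where the envelope exceeds `resting_level +
#' threshold_delta` become candidate movements, and candidates with
#' duration outside \[0.5, 5\] s are discarded (Coleman movement-duration
#' rule).
#'
#' @param leg_emg A [psg_channel()] (the leg EMG).
#' @param resting_level Resting EMG envelope amplitude (signal units).
#'   If `NULL`, estimated as the median of the envelope.
#' @param threshold_delta Required excess over the resting level (signal
#'   units; the scoring standard's "8 above resting" criterion, with units
#'   carried by the channel metadata). Default 8.
#' @param smooth_window Moving-RMS window in seconds. Default 0.1.
#' @return Data frame with columns `onset`, `duration` (seconds).
#' @export
detect_movements <- function(leg_emg, resting_level = NULL, threshold_delta = 8,
                             smooth_window = 0.1) {
  stopifnot(inherits(leg_emg, "psg_channel"))
  x <- leg_emg$samples
  if (length(x) == 0L) stop("empty leg-EMG signal", call. = FALSE)
  fs <- leg_emg$fs
  w <- max(1L, round(smooth_window * fs))
  env <- sqrt(as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2)))
  env[is.na(env)] <- 0
  if (is.null(resting_level)) resting_level <- stats::median(env, na.rm = TRUE)
  if (resting_level < 0) stop("resting_level must be >= 0", call. = FALSE)
  above <- env > resting_level + threshold_delta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  onset <- (starts[keep] - 1L) / fs
  dur <- r$lengths[keep] / fs
  ok <- dur >= 0.5 & dur <= 5
  data.frame(onset = onset[ok], duration = dur[ok])
}

#' Group movements into periodic (PLM) series
#'
#' Greedy left-to-right chaining under the Coleman periodicity rule: a
#' chain extends while the next onset-to-onset interval lies in \[5, 90\]
#' s. An interval shorter than 5 s terminates the chain and the offending
#' movement is skipped; an interval longer than 90 s terminates the chain
#' and starts a new one. Chains of at least 4 movements are reported as
#' series.
#'
#' @param movements Data frame with `onset`, `duration`, sorted by onset.
#' @return A list of data frames (one per series), each a subset of
#'   `movements`.
#' @export
group_periodic_series <- function(movements) {
  movements <- as.data.frame(movements)
  if (nrow(movements) == 0L) return(list())
  if (is.unsorted(movements$onset)) movements <- movements[order(movements$onset), ]
  out <- list()
  chain <- 1L
  flush <- function(chain) {
    if (length(chain) >= 4L)
      out[[length(out) + 1L]] <<- movements[chain, , drop = FALSE]
  }
  for (i in seq_len(nrow(movements))[-1L]) {
    if (length(chain) == 0L) { chain <- i; next }
    gap <- movements$onset[i] - movements$onset[chain[length(chain)]]
    if (gap >= 5 && gap <= 90) {
      chain <- c(chain, i)
    } else if (gap > 90) {
      flush(chain); chain <- i
    } else {
      # interval < 5 s: not periodic; chain broken and the movement skipped
      flush(chain); chain <- integer(0)
    }
  }
  flush(chain)
  out
}

#' PLM index (movements per hour of sleep)
#'
#' @param series A list of series as returned by
#'   [group_periodic_series()].
#' @param total_sleep_time Total sleep time in hours (> 0).
#' @return Movements inside all series divided by `total_sleep_time`.
#' @export
plm_index <- function(series, total_sleep_time) {
  if (!is_scalar_num(total_sleep_time) || total_sleep_time <= 0)
    stop("total_sleep_time must be > 0 hours", call. = FALSE)
  sum(vapply(series, nrow, integer(1))) / total_sleep_time
}

#' Label epochs by PLM overlap
#'
#' An epoch is positive iff any movement belonging to a PLM series
#' overlaps its half-open interval; a movement spanning an epoch boundary
#' therefore labels both epochs.
#'
#' @param epoch_set An [segment()] result.
#' @param plm_movements Data frame of in-series movements (`onset`,
#'   `duration`).
#' @return The epoch set with its `label` column set to `"PLM"` /
#'   `"non-PLM"`.
#' @export
label_epochs <- function(epoch_set, plm_movements) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  mv <- as.data.frame(plm_movements)
  pos <- rep(FALSE, nrow(epoch_set))
  if (nrow(mv)) {
    for (i in seq_len(nrow(mv))) {
      pos <- pos | intervals_overlap(epoch_set$start, epoch_set$end,
                                     mv$onset[i], mv$onset[i] + mv$duration[i])
    }
  }
  epoch_set$label <- ifelse(pos, "PLM", "non-PLM")
  epoch_set
}

#' Score a leg-EMG channel end to end
#'
#' Runs [detect_movements()] and [group_periodic_series()] and returns
#' annotation events (`leg_movement` for in-series movements,
#' `plm_series` per series) in the package's annotation dialect.
#'
#' @inheritParams detect_movements
#' @return A [psg_annotations()] object.
#' @export
score_leg_emg <- function(leg_emg, resting_level = NULL, threshold_delta = 8) {
  mv <- detect_movements(leg_emg, resting_level, threshold_delta)
  series <- group_periodic_series(mv)
  if (length(series) == 0L) return(psg_annotations())
  inset <- do.call(rbind, series)
  ser <- do.call(rbind, lapply(series, function(s)
    data.frame(kind = "plm_series", onset = s$onset[1],
               duration = s$onset[nrow(s)] + s$duration[nrow(s)] - s$onset[1],
               channel = leg_emg$label, value = as.character(nrow(s)))))
  psg_annotations(rbind(
    data.frame(kind = "leg_movement", onset = inset$onset,
               duration = inset$duration, channel = leg_emg$label,
               value = NA_character_),
    ser))
}
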
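# Per-epoch DSP features: Haar wavelet EEG subbands, DFT band powers,
# time-domain statistics, spectral entropy, oximetry and contextual
# attributes. The default registry is the 77 (channel, feature) pairs
# used for classification; leg EMG is never read.

HAAR_SQRT2 <- sqrt(2)

haar_step <- function(X) {
  # one analysis level on the rows of X (length must be even)
  n <- nrow(X)
  odd <- seq(1L, n, by = 2L)
  list(a = (X[odd, , drop = FALSE] + X[odd + 1L, , drop = FALSE]) / HAAR_SQRT2,
       d = (X[odd, , drop = FALSE] - X[odd + 1L, , drop = FALSE]) / HAAR_SQRT2)
}

haar_unstep <- function(a, d) {
  n <- 2L * nrow(a)
  X <- matrix(0, n, ncol(a))
  odd <- seq(1L, n, by = 2L)
  X[odd, ] <- (a + d) / HAAR_SQRT2
  X[odd + 1L, ] <- (a - d) / HAAR_SQRT2
  X
}

# Multilevel orthonormal Haar analysis of the columns of X.
# Returns detail coefficient matrices (level 1 = finest) and the final
# approximation.
haar_analysis <- function(X, levels) {
  details <- vector("list", levels)
  a <- X
  for (k in seq_len(levels)) {
    if (nrow(a) %% 2L != 0L)
      stop("segment length not divisible by 2^", k,
           "; Haar level ", k, " unavailable", call. = FALSE)
    s <- haar_step(a)
    details[[k]] <- s$d
    a <- s$a
  }
  list(details = details, approx = a)
}

# Reconstruct the time-domain component carried by detail level k alone.
haar_reconstruct_level <- function(d, k) {
  X <- haar_unstep(matrix(0, nrow(d), ncol(d)), d)
  while (k > 1L) {
    k <- k - 1L
    X <- haar_unstep(X, matrix(0, nrow(X), ncol(X)))
  }
  X
}

# Dyadic detail levels approximating the nominal EEG bands at sampling
# rate fs (a power of two >= 64). Level k spans [fs/2^(k+1), fs/2^k) Hz:
# beta ~ 16-32 Hz, alpha ~ 8-16, theta ~ 4-8, delta ~ 0.5-4 (union of the
# deeper detail levels; the 0-0.5 Hz approximation is excluded so slow
# drift and DC never enter the delta feature).
haar_band_levels <- function(fs) {
  if (!is_scalar_num(fs) || fs < 64 || log2(fs) != round(log2(fs)))
    stop("fs must be a power of two >= 64 Hz to represent the beta band",
         call. = FALSE)
  beta <- as.integer(round(log2(fs / 32)))
  list(beta = beta, alpha = beta + 1L, theta = beta + 2L,
       delta = seq.int(beta + 3L, as.integer(log2(fs))))
}

#' Haar wavelet EEG subband components
#'
#' Decomposes a segment with the orthonormal multilevel Haar transform
#' and reconstructs one time-domain component per nominal EEG band,
#' mapping each band to the nearest dyadic detail range (at 256 Hz: beta
#' from the 16-32 Hz level, alpha 8-16, theta 4-8, delta the union of the
#' 0.5-4 Hz levels). Exact 13 Hz / 30 Hz edges are unattainable with a
#' dyadic filter bank; the mapping is documented and fixed.
#'
#' @param segment Numeric vector; length must be divisible by
#'   `2^log2(fs)`.
#' @param fs Sampling rate in Hz, a power of two >= 64.
#' @return Named list of numeric vectors `delta`, `theta`, `alpha`,
#'   `beta`, each the same length as `segment`.
#' @export
haar_subbands <- function(segment, fs) {
  lv <- haar_band_levels(fs)
  max_level <- max(unlist(lv))
  X <- matrix(as.numeric(segment), ncol = 1L)
  dec <- haar_analysis(X, max_level)
  comp <- function(levels) {
    out <- numeric(length(segment))
    for (k in levels)
      out <- out + as.numeric(haar_reconstruct_level(dec$details[[k]], k))
    out
  }
  list(delta = comp(lv$delta), theta = comp(lv$theta),
       alpha = comp(lv$alpha), beta = comp(lv$beta))
}

#' Band power of a subband component
#'
#' Mean squared magnitude of the component's DFT spectrum, normalized so
#' that it equals the time-domain mean square (discrete Parseval): a
#' unit-amplitude sinusoid at a DFT bin frequency has power 0.5.
#'
#' @param component Numeric vector (a [haar_subbands()] component).
#' @return Non-negative scalar power.
#' @export
band_power <- function(component) {
  n <- length(component)
  if (n == 0L) stop("empty component", call. = FALSE)
  mean(Mod(stats::fft(component))^2) / n
}

#' Zero-crossing count
#'
#' Number of adjacent sample pairs with strictly opposite signs (a zero
#' sample never counts).
#'
#' @param segment Numeric vector of length >= 2.
#' @return Integer count.
#' @export
zero_crossings <- function(segment) {
  n <- length(segment)
  if (n < 2L) stop("segment must have at least 2 samples", call. = FALSE)
  sum(sign(segment[-n]) * sign(segment[-1L]) < 0)
}

#' Mean and RMS of a segment
#'
#' @param segment Non-empty numeric vector.
#' @return List with `mean` and `rms`.
#' @export
basic_stats <- function(segment) {
  if (length(segment) == 0L) stop("empty segment", call. = FALSE)
  list(mean = mean(segment), rms = sqrt(mean(segment^2)))
}

#' Mean power spectrum and spectral entropy
#'
#' The segment mean is removed, then a one-sided periodogram is formed
#' over the positive-frequency DFT bins. `mean_power_spectrum` is its
#' mean; `spectral_entropy` is the Shannon entropy (bits) of the
#' periodogram normalized to a probability distribution, with the
#' convention that an all-zero (degenerate) spectrum has entropy 0.
#'
#' @param segment Numeric vector of length >= 8.
#' @param fs Sampling rate (Hz); retained for interface symmetry, the
#'   two statistics do not depend on it.
#' @return List with `mean_power_spectrum` and `spectral_entropy`.
#' @export
spectral_features <- function(segment, fs = NULL) {
  n <- length(segment)
  if (n < 8L) stop("segment must have at least 8 samples", call. = FALSE)
  x <- segment - mean(segment)
  P <- Mod(stats::fft(x))[2:(floor(n / 2) + 1L)]^2 / n
  tot <- sum(P)
  entropy <- if (tot <= 0) 0 else {
    p <- P / tot
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  list(mean_power_spectrum = mean(P), spectral_entropy = entropy)
}

#' Oximetry features of an epoch
#'
#' @param spo2 Numeric vector of SpO2 percentages in \[0, 100\].
#' @return List with `desaturation` (max - min within the epoch, %
#'   points), `lowest_spo2` (min) and `rms`.
#' @export
spo2_features <- function(spo2) {
  if (length(spo2) == 0L) stop("empty SpO2 segment", call. = FALSE)
  if (any(spo2 < 0 | spo2 > 100)) stop("SpO2 values must lie in [0, 100]", call. = FALSE)
  list(desaturation = max(spo2) - min(spo2),
       lowest_spo2 = min(spo2),
       rms = sqrt(mean(spo2^2)))
}

#' Integer codes for sleep stages
#'
#' Fixed code table used for the `sleep_stage` attribute: Wake 0, N1 1,
#' N2 2, N3 3, REM 5 (the conventional scoring code for REM).
#'
#' @return Named integer vector.
#' @export
stage_codes <- function() c(Wake = 0L, N1 = 1L, N2 = 2L, N3 = 3L, REM = 5L)

#' Contextual features of an epoch
#'
#' @param epoch Two-element numeric `c(start, end)` in seconds, or a
#'   one-row epoch-set slice.
#' @param annotations A [psg_annotations()] object.
#' @param channels Named list of [psg_channel()]s (needs `HR` and
#'   `Position` if those features are wanted; missing channels yield
#'   `NA`).
#' @return List with `apnea_flag` (1 iff any apnea/hypopnea overlaps the
#'   epoch), `sleep_stage` (integer code, see [stage_codes()]),
#'   `position` (dominant position code in the epoch) and `heart_rate`
#'   (mean of the HR channel over the epoch).
#' @export
context_features <- function(epoch, annotations, channels = list()) {
  if (is.data.frame(epoch)) epoch <- c(epoch$start[1], epoch$end[1])
  start <- epoch[1]; end <- epoch[2]
  resp <- events_of_kind(annotations, c("apnea", "hypopnea"))
  apnea_flag <- as.integer(nrow(resp) > 0 &&
    any(intervals_overlap(start, end, resp$onset, resp$onset + resp$duration)))
  stg <- stage_at(start, events_of_kind(annotations, "stage"))
  stage_code <- if (is.na(stg)) NA_integer_ else stage_codes()[[stg]]
  seg_of <- function(lab) {
    ch <- channels[[lab]]
    if (is.null(ch)) return(NULL)
    idx <- (floor(start * ch$fs) + 1L):min(length(ch$samples), ceiling(end * ch$fs))
    ch$samples[idx]
  }
  pos_seg <- seg_of("Position")
  position <- if (is.null(pos_seg)) NA_real_ else
    as.numeric(names(which.max(table(pos_seg))))
  hr_seg <- seg_of("HR")
  heart_rate <- if (is.null(hr_seg)) NA_real_ else mean(hr_seg)
  list(apnea_flag = apnea_flag, sleep_stage = stage_code,
       position = position, heart_rate = heart_rate)
}

# ---------------------------------------------------------------------------
# Registry and the bulk extractor

EEG_DERIVATIONS <- c("C3-A2", "C4-A1", "F3-A2", "F4-A1", "O1-A2", "O2-A1")
SPECTRAL_SET <- c("zero_crossings", "mean", "mean_power_spectrum", "rms",
                  "spectral_entropy")

#' The default 77-attribute registry
#'
#' The fixed (channel, feature) table used for classification, in
#' registry order: 9 attributes (four Haar band powers, zero crossings,
#' mean, mean power spectrum, RMS, spectral entropy) for each of the 6
#' EEG derivations; the apnea flag; the sleep stage; abdominal, airflow,
#' EOG, snore-sound, thoracic and SpO2 RMS values; body position; the
#' ECG and chin-EMG spectral sets; mean heart rate; and the SpO2
#' desaturation and minimum. Leg EMG never appears.
#'
#' @return Data frame with columns `channel`, `feature`, `name` (the
#'   `channel.feature` column label), 77 rows.
#' @export
feature_registry <- function() {
  rows <- list()
  for (ch in EEG_DERIVATIONS)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = ch,
      feature = c("delta", "theta", "alpha", "beta", SPECTRAL_SET))
  rows[[length(rows) + 1L]] <- data.frame(
    channel = c("Airflow", "EEG", "Abdo", "Airflow", "Position"),
    feature = c("apnea_flag", "sleep_stage", "rms", "rms", "position"))
  rows[[length(rows) + 1L]] <- data.frame(channel = "ECG", feature = SPECTRAL_SET)
  rows[[length(rows) + 1L]] <- data.frame(channel = "Chin EMG", feature = SPECTRAL_SET)
  rows[[length(rows) + 1L]] <- data.frame(
    channel = c("HR", "LOC", "ROC", "Sound", "SpO2", "SpO2", "SpO2", "Thor"),
    feature = c("heart_rate", "rms", "rms", "rms",
                "desaturation", "lowest_spo2", "rms", "rms"))
  reg <- do.call(rbind, rows)
  reg$name <- paste(reg$channel, reg$feature, sep = ".")
  rownames(reg) <- NULL
  reg
}

# Segment a channel into an (samples-per-epoch x n-epochs) matrix for the
# given epoch starts.
epoch_matrix <- function(ch, starts, epoch_length) {
  spe <- ch$fs * epoch_length
  if (spe != round(spe))
    stop("epoch length ", epoch_length, " s not a whole number of samples at ",
         ch$fs, " Hz (channel ", ch$label, ")", call. = FALSE)
  spe <- as.integer(spe)
  idx <- outer(seq_len(spe), as.integer(round(starts * ch$fs)), `+`)
  matrix(ch$samples[idx], nrow = spe)
}

col_band_powers <- function(X, fs) {
  lv <- haar_band_levels(fs)
  dec <- haar_analysis(X, max(unlist(lv)))
  n <- nrow(X)
  pw <- function(levels) {
    out <- numeric(ncol(X))
    for (k in levels) out <- out + colSums(dec$details[[k]]^2)
    out / n
  }
  list(delta = pw(lv$delta), theta = pw(lv$theta),
       alpha = pw(lv$alpha), beta = pw(lv$beta))
}

col_zero_crossings <- function(X) {
  n <- nrow(X)
  colSums(sign(X[-n, , drop = FALSE]) * sign(X[-1L, , drop = FALSE]) < 0)
}

col_spectral <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  P <- Mod(stats::mvfft(Xc)[2:(floor(n / 2) + 1L), , drop = FALSE])^2 / n
  tot <- colSums(P)
  mps <- colMeans(P)
  se <- vapply(seq_len(ncol(P)), function(j) {
    if (tot[j] <= 0) return(0)
    p <- P[, j] / tot[j]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  list(mean_power_spectrum = mps, spectral_entropy = se)
}

#' Extract the feature table for a set of epochs
#'
#' Computes every registry attribute for each epoch in `epoch_set`
#' (typically the retained, labelled set). The leg-EMG channel is never
#' read: outputs are identical whether or not it is present.
#'
#' @param recording A [psg_recording()] containing every registry channel
#'   (leg EMG optional and ignored).
#' @param annotations A [psg_annotations()] (stages and respiratory
#'   events feed the contextual attributes).
#' @param epoch_set Epoch set whose rows become the table rows.
#' @param registry Attribute registry (default [feature_registry()]).
#' @return Data frame of class `feature_table`: id columns `patient_id`,
#'   `epoch_index`, `label`, then one numeric column per registry row, in
#'   registry order. The registry is attached as attribute `"registry"`.
#' @export
extract_feature_table <- function(recording, annotations, epoch_set,
                                  registry = feature_registry()) {
  stopifnot(inherits(recording, "psg_recording"), inherits(epoch_set, "epoch_set"))
  needed <- setdiff(unique(registry$channel), "EEG")
  missing <- setdiff(needed, names(recording$channels))
  if (length(missing))
    stop("registry channel(s) missing from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)

  starts <- epoch_set$start
  epoch_length <- unique(epoch_set$end - epoch_set$start)
  stopifnot(length(epoch_length) == 1L)
  n_ep <- nrow(epoch_set)
  vals <- vector("list", nrow(registry))
  names(vals) <- registry$name

  for (ch_lab in needed) {
    feats <- registry$feature[registry$channel == ch_lab]
    ch <- recording$channels[[ch_lab]]
    X <- epoch_matrix(ch, starts, epoch_length)
    if (any(feats %in% c("delta", "theta", "alpha", "beta"))) {
      bp <- col_band_powers(X, ch$fs)
      for (b in intersect(feats, names(bp)))
        vals[[paste(ch_lab, b, sep = ".")]] <- bp[[b]]
    }
    if ("zero_crossings" %in% feats)
      vals[[paste(ch_lab, "zero_crossings", sep = ".")]] <- col_zero_crossings(X)
    if ("mean" %in% feats)
      vals[[paste(ch_lab, "mean", sep = ".")]] <- colMeans(X)
    if ("rms" %in% feats)
      vals[[paste(ch_lab, "rms", sep = ".")]] <- sqrt(colMeans(X^2))
    if (any(c("mean_power_spectrum", "spectral_entropy") %in% feats)) {
      sp <- col_spectral(X)
      for (f in intersect(feats, names(sp)))
        vals[[paste(ch_lab, f, sep = ".")]] <- sp[[f]]
    }
    if ("desaturation" %in% feats)
      vals[[paste(ch_lab, "desaturation", sep = ".")]] <-
        apply(X, 2L, max) - apply(X, 2L, min)
    if ("lowest_spo2" %in% feats)
      vals[[paste(ch_lab, "lowest_spo2", sep = ".")]] <- apply(X, 2L, min)
    if ("heart_rate" %in% feats)
      vals[[paste(ch_lab, "heart_rate", sep = ".")]] <- colMeans(X)
    if ("position" %in% feats)
      vals[[paste(ch_lab, "position", sep = ".")]] <- apply(X, 2L, function(col)
        as.numeric(names(which.max(table(col)))))
    if ("apnea_flag" %in% feats) {
      resp <- events_of_kind(annotations, c("apnea", "hypopnea"))
      vals[[paste(ch_lab, "apnea_flag", sep = ".")]] <-
        as.numeric(flag_overlaps(epoch_set, resp$onset, resp$duration))
    }
  }
  if ("EEG.sleep_stage" %in% registry$name) {
    ev <- events_of_kind(annotations, "stage")
    stg <- vapply(starts, stage_at, character(1), stage_events = ev)
    vals[["EEG.sleep_stage"]] <- as.numeric(stage_codes()[stg])
  }

  ft <- data.frame(patient_id = epoch_set$patient_id,
                   epoch_index = epoch_set$index,
                   label = epoch_set$label,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in registry$name) ft[[nm]] <- vals[[nm]]
  attr(ft, "registry") <- registry
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Numeric feature columns of a feature table
#'
#' @param feature_table A [extract_feature_table()] result.
#' @return Numeric matrix (epochs x attributes).
#' @export
feature_matrix <- function(feature_table) {
  id <- c("patient_id", "epoch_index", "label")
  as.matrix(feature_table[, setdiff(names(feature_table), id), drop = FALSE])
}
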
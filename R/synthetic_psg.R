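# Synthetic polysomnography generator. Produces a Recording/AnnotationSet
# pair with the statistical structure the downstream pipeline assumes:
# stage-structured EEG band power, respiration with apnea/hypopnea events
# and lagged SpO2 desaturations, an ECG/heart-rate pair, body position,
# snore sound, and Coleman-compliant periodic-leg-movement trains on the
# leg-EMG channel with configurable coupling of each movement into the
# non-leg channels. Coupling 0 gives channels statistically independent of
# the PLM labels.

SLEEP_STAGES <- c("Wake", "N1", "N2", "N3", "REM")

#' Periodic-leg-movement train specification
#'
#' Parameters are constrained to the Coleman scoring bounds: movement
#' durations within \[0.5, 5\] s, onset-to-onset intervals within \[5, 90\] s,
#' at least 4 movements per series.
#'
#' @param series_rate PLM series per hour.
#' @param movements_per_series Movements in each series (>= 4).
#' @param interval Two-element range of onset-to-onset intervals (s).
#' @param movement_duration Two-element range of movement durations (s).
#' @param burst_amplitude Leg-EMG burst amplitude above the resting level
#'   (signal units, RMS).
#' @return A list of class `plm_spec`.
#' @export
plm_spec <- function(series_rate = 10, movements_per_series = 10,
                     interval = c(10, 30), movement_duration = c(0.5, 3),
                     burst_amplitude = 20) {
  if (series_rate < 0) stop("series_rate must be >= 0", call. = FALSE)
  if (movements_per_series < 4)
    stop("movements_per_series must be >= 4 (Coleman series criterion)", call. = FALSE)
  if (interval[1] < 5 || interval[2] > 90 || interval[1] > interval[2])
    stop("interval range must lie within [5, 90] s (Coleman criterion)", call. = FALSE)
  if (movement_duration[1] < 0.5 || movement_duration[2] > 5 ||
      movement_duration[1] > movement_duration[2])
    stop("movement_duration range must lie within [0.5, 5] s (Coleman criterion)",
         call. = FALSE)
  if (burst_amplitude <= 0) stop("burst_amplitude must be > 0", call. = FALSE)
  structure(list(series_rate = series_rate,
                 movements_per_series = as.integer(movements_per_series),
                 interval = interval, movement_duration = movement_duration,
                 burst_amplitude = burst_amplitude), class = "plm_spec")
}

#' PLM-to-channel coupling specification
#'
#' Effect sizes linking each leg movement to transient signatures in
#' non-leg channels. All-zero coupling makes every non-leg channel
#' statistically independent of the PLM labels.
#'
#' @param eeg EEG alpha/beta burst gain (multiples of 10 uV band noise).
#' @param chin Chin-EMG burst standard deviation gain (multiples of 4 uV).
#' @param spo2 Depth of the movement-locked SpO2 dip (% points).
#' @param hr Transient heart-rate acceleration (beats/min).
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(eeg = 2, chin = 4, spo2 = 4, hr = 15) {
  x <- list(eeg = eeg, chin = chin, spo2 = spo2, hr = hr)
  if (any(unlist(x) < 0)) stop("coupling effect sizes must be >= 0", call. = FALSE)
  structure(x, class = "coupling_spec")
}

#' @rdname coupling_spec
#' @export
coupling_none <- function() coupling_spec(0, 0, 0, 0)

#' Default per-stage EEG band amplitude profile
#'
#' Amplitudes (uV, standard deviation of the band-limited component) of
#' delta/theta/alpha/beta EEG activity per sleep stage: alpha-dominant
#' wake, theta-dominant N1/REM, increasing delta through N2 and N3.
#'
#' @return A 5 x 4 numeric matrix (stages x bands).
#' @export
default_band_profiles <- function() {
  m <- rbind(Wake = c(5, 5, 15, 10),
             N1   = c(10, 15, 8, 5),
             N2   = c(20, 15, 7, 4),
             N3   = c(40, 12, 5, 3),
             REM  = c(10, 15, 7, 8))
  colnames(m) <- c("delta", "theta", "alpha", "beta")
  m
}

#' Simulation configuration
#'
#' Defaults describe a 6-hour severe-PLMD night: stage mix matching a
#' typical PLMD cohort (sleep efficiency ~85%, N2-dominant), 5 apneas/hour
#' with lagged desaturations, and 100 leg movements per hour (10 series/h
#' of 10 movements). Coupling defaults to [coupling_spec()]'s strong
#' signatures; use `coupling = coupling_none()` for label-independent
#' channels.
#'
#' @param patient_id Patient identifier.
#' @param duration Recording duration in seconds (integer).
#' @param seed Integer seed; the same (config, seed) pair always generates
#'   bit-identical output.
#' @param eeg_fs,emg_fs,ecg_fs,effort_fs Sampling rates (Hz) for EEG/EOG,
#'   EMG, ECG and thorax/abdomen channels. EEG rates must be a power of
#'   two >= 64 so the Haar subband features are computable.
#' @param airflow_fs Sampling rate for airflow and snore sound (Hz).
#' @param stage_probs Named stage occupancy probabilities over
#'   Wake/N1/N2/N3/REM (normalized internally).
#' @param mean_stage_dwell Mean stage bout length in seconds (rounded to
#'   30-s pages).
#' @param band_profiles Stage x band EEG amplitude matrix, see
#'   [default_band_profiles()].
#' @param resp_rate Respiration rate (Hz).
#' @param apnea_rate Apnea/hypopnea events per hour.
#' @param apnea_duration Two-element range of event durations (s).
#' @param desat_depth Mean SpO2 desaturation depth following apneas (%).
#' @param desat_lag Two-element range of desaturation lags after apnea
#'   onset (s).
#' @param plm A [plm_spec()].
#' @param coupling A [coupling_spec()].
#' @param artefact_rate Artefact events per hour.
#' @param artefact_duration Two-element range of artefact durations (s).
#' @param emg_resting Resting leg/chin EMG noise level (uV, RMS).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(patient_id = "P001", duration = 21600, seed = 1,
                       eeg_fs = 128, emg_fs = 128, ecg_fs = 128,
                       airflow_fs = 256, effort_fs = 128,
                       stage_probs = c(Wake = 0.15, N1 = 0.06, N2 = 0.49,
                                       N3 = 0.17, REM = 0.13),
                       mean_stage_dwell = 300,
                       band_profiles = default_band_profiles(),
                       resp_rate = 0.25,
                       apnea_rate = 5, apnea_duration = c(10, 30),
                       desat_depth = 5, desat_lag = c(10, 20),
                       plm = plm_spec(),
                       coupling = coupling_spec(),
                       artefact_rate = 4, artefact_duration = c(1, 8),
                       emg_resting = 2) {
  if (!is_scalar_num(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  duration <- as.integer(round(duration))
  if (!inherits(plm, "plm_spec")) plm <- do.call(plm_spec, plm)
  if (!inherits(coupling, "coupling_spec")) coupling <- do.call(coupling_spec, coupling)
  if (is.null(names(stage_probs)) || !setequal(names(stage_probs), SLEEP_STAGES))
    stop("stage_probs must be named over ", paste(SLEEP_STAGES, collapse = "/"),
         call. = FALSE)
  stage_probs <- stage_probs[SLEEP_STAGES] / sum(stage_probs)
  if (log2(eeg_fs) != round(log2(eeg_fs)) || eeg_fs < 64)
    stop("eeg_fs must be a power of two >= 64 Hz", call. = FALSE)
  structure(list(patient_id = patient_id, duration = duration, seed = seed,
                 eeg_fs = eeg_fs, emg_fs = emg_fs, ecg_fs = ecg_fs,
                 airflow_fs = airflow_fs, effort_fs = effort_fs,
                 stage_probs = stage_probs, mean_stage_dwell = mean_stage_dwell,
                 band_profiles = band_profiles, resp_rate = resp_rate,
                 apnea_rate = apnea_rate, apnea_duration = apnea_duration,
                 desat_depth = desat_depth, desat_lag = desat_lag,
                 plm = plm, coupling = coupling,
                 artefact_rate = artefact_rate,
                 artefact_duration = artefact_duration,
                 emg_resting = emg_resting),
            class = "sim_config")
}

# ---------------------------------------------------------------------------
# Hypnogram

hypnogram_draw <- function(config) {
  dur <- config$duration
  mean_pages <- max(1, config$mean_stage_dwell / 30)
  segs <- list(); t <- 0
  while (t < dur) {
    stage <- sample(SLEEP_STAGES, 1L, prob = config$stage_probs)
    pages <- 1L + stats::rgeom(1L, prob = min(1, 1 / mean_pages))
    len <- min(pages * 30, dur - t)
    segs[[length(segs) + 1L]] <- list(onset = t, duration = len, value = stage)
    t <- t + len
  }
  data.frame(kind = "stage",
             onset = vapply(segs, `[[`, numeric(1), "onset"),
             duration = vapply(segs, `[[`, numeric(1), "duration"),
             channel = NA_character_,
             value = vapply(segs, `[[`, character(1), "value"),
             stringsAsFactors = FALSE)
}

#' Generate a hypnogram
#'
#' Draws contiguous stage bouts (in 30-s pages, geometric dwell) tiling
#' `[0, duration)` with stage occupancy given by `config$stage_probs`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [psg_annotations()] containing only `stage` events.
#' @export
generate_hypnogram <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ev <- with_seed(seed, hypnogram_draw(config))
  psg_annotations(ev, duration = config$duration)
}

# ---------------------------------------------------------------------------
# Event-train helpers (draw from the current RNG stream)

# Non-overlapping random events: onsets uniform, durations uniform in
# `dur_range`; events closer than `gap` to a kept predecessor are dropped.
draw_events <- function(n, total, dur_range, gap = 0) {
  if (n <= 0) return(data.frame(onset = numeric(), duration = numeric()))
  onset <- sort(stats::runif(n, 0, max(0, total - dur_range[2])))
  duration <- stats::runif(n, dur_range[1], dur_range[2])
  keep <- logical(n); last_end <- -Inf
  for (i in seq_len(n)) {
    if (onset[i] >= last_end + gap) {
      keep[i] <- TRUE
      last_end <- onset[i] + duration[i]
    }
  }
  data.frame(onset = onset[keep], duration = duration[keep])
}

# PLM series as a renewal process: each series occupies its footprint
# (movements + intervals), then a > 90 s gap follows so consecutive
# series stay distinct under the Coleman chaining rule. The exponential
# part of the gap is calibrated so the realized series rate matches
# `series_rate` when the night is long enough to fit them.
draw_plm_trains <- function(config) {
  spec <- config$plm
  if (spec$series_rate <= 0) return(list())
  m <- spec$movements_per_series
  footprint <- (m - 1L) * mean(spec$interval) + mean(spec$movement_duration)
  spacing <- 3600 / spec$series_rate
  gap_mean <- max(5, spacing - footprint - 91)
  series <- list()
  t <- stats::runif(1, 0, spacing / 2)
  repeat {
    gaps <- stats::runif(m - 1L, spec$interval[1], spec$interval[2])
    onsets <- t + c(0, cumsum(gaps))
    durs <- stats::runif(m, spec$movement_duration[1], spec$movement_duration[2])
    ok <- onsets + durs <= config$duration
    if (sum(ok) >= 4L) {
      series[[length(series) + 1L]] <-
        data.frame(onset = onsets[ok], duration = durs[ok])
    }
    if (!all(ok)) break
    t <- onsets[m] + durs[m] + 91 + stats::rexp(1, 1 / gap_mean)
    if (t >= config$duration - 5) break
  }
  series
}

# Band-limited unit-variance Gaussian noise via a Butterworth bandpass.
band_noise <- function(n, band, fs) {
  ny <- fs / 2
  w <- pmin(pmax(band / ny, 1e-4), 0.999)
  bf <- signal::butter(2, w, type = "pass")
  x <- signal::filter(bf, stats::rnorm(n))
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Per-sample envelope from piecewise-constant per-second values.
per_sample <- function(values_1hz, fs) rep(values_1hz, each = fs)

# Stage index per second of the recording.
stage_per_second <- function(stage_events, duration) {
  sec <- integer(duration)
  for (i in seq_len(nrow(stage_events))) {
    a <- floor(stage_events$onset[i]) + 1L
    b <- min(duration, ceiling(stage_events$onset[i] + stage_events$duration[i]))
    if (b >= a) sec[a:b] <- match(stage_events$value[i], SLEEP_STAGES)
  }
  sec
}

# Add `vals` (length L per event) into x at each event start index.
add_pulses <- function(x, starts, template) {
  L <- length(template)
  for (s in starts) {
    if (s < 1L || s + L - 1L > length(x)) next
    idx <- s:(s + L - 1L)
    x[idx] <- x[idx] + template
  }
  x
}

# ---------------------------------------------------------------------------

#' Generate a synthetic PSG recording with ground-truth annotations
#'
#' Synthesizes the full channel montage (6 EEG derivations, 2 EOG, chin
#' and leg EMG, ECG, SpO2, airflow, thorax, abdomen, snore sound, body
#' position, heart rate) together with stage, apnea/hypopnea,
#' leg-movement, PLM-series and artefact annotations. Leg movements are
#' Coleman-compliant trains; each movement is injected into the leg-EMG
#' channel and, with the configured coupling effect sizes, into non-leg
#' channels.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recording` ([psg_recording()]) and
#'   `annotations` ([psg_annotations()]).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_recording_impl(config))
}

generate_recording_impl <- function(config) {
  dur <- config$duration
  hours <- dur / 3600
  cpl <- config$coupling

  stage_ev <- hypnogram_draw(config)
  stage_sec <- stage_per_second(stage_ev, dur)

  # -- respiratory events ---------------------------------------------------
  apnea <- draw_events(stats::rpois(1L, config$apnea_rate * hours),
                       dur, config$apnea_duration, gap = 30)
  if (nrow(apnea)) {
    apnea$kind <- rep_len(c("apnea", "hypopnea"), nrow(apnea))
  } else apnea$kind <- character(0)

  # -- PLM trains -----------------------------------------------------------
  series <- draw_plm_trains(config)
  movements <- if (length(series)) do.call(rbind, series) else
    data.frame(onset = numeric(), duration = numeric())

  # -- artefacts ------------------------------------------------------------
  artefact <- draw_events(stats::rpois(1L, config$artefact_rate * hours),
                          dur, config$artefact_duration, gap = 60)

  channels <- list()

  # -- EEG ------------------------------------------------------------------
  fs <- config$eeg_fs
  n <- dur * fs
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  eeg_labels <- c("C3-A2", "C4-A1", "F3-A2", "F4-A1", "O1-A2", "O2-A1")
  # movement-burst window weights at EEG rate, per movement
  mov_win <- function(fs_ch) {
    if (nrow(movements) == 0 || cpl$eeg <= 0) return(NULL)
    lapply(seq_len(nrow(movements)), function(i) {
      a <- floor(movements$onset[i] * fs_ch) + 1L
      len <- max(1L, round(max(movements$duration[i], 1) * fs_ch))
      b <- min(n, a + len - 1L)
      if (a > n) NULL else a:b
    })
  }
  eeg_windows <- mov_win(fs)
  for (lab in eeg_labels) {
    x <- numeric(n)
    ab_burst <- numeric(0)
    for (b in names(bands)) {
      bn <- band_noise(n, bands[[b]], fs)
      amp <- per_sample(config$band_profiles[stage_sec, b], fs)
      x <- x + bn * amp
      if (b %in% c("alpha", "beta") && !is.null(eeg_windows)) {
        for (idx in eeg_windows) if (!is.null(idx))
          x[idx] <- x[idx] + cpl$eeg * 10 * bn[idx]
      }
    }
    x <- x + stats::rnorm(n, sd = 2)  # measurement noise
    channels[[lab]] <- psg_channel(lab, fs, x, "uV")
  }

  # -- EOG ------------------------------------------------------------------
  eog_amp <- c(Wake = 30, N1 = 20, N2 = 10, N3 = 5, REM = 40)
  for (lab in c("LOC", "ROC")) {
    bn <- band_noise(n, c(0.5, 3), fs)
    x <- bn * per_sample(eog_amp[stage_sec], fs) + stats::rnorm(n, sd = 3)
    channels[[lab]] <- psg_channel(lab, fs, x, "uV")
  }

  # -- chin EMG -------------------------------------------------------------
  chin_sd <- c(Wake = 8, N1 = 5, N2 = 4, N3 = 3, REM = 1.5)
  x <- stats::rnorm(n, sd = 1) * per_sample(chin_sd[stage_sec], config$emg_fs)
  if (nrow(movements) && cpl$chin > 0) {
    for (i in seq_len(nrow(movements))) {
      a <- floor(movements$onset[i] * config$emg_fs) + 1L
      b <- min(n, a + max(1L, round(movements$duration[i] * config$emg_fs)) - 1L)
      if (a <= n) x[a:b] <- x[a:b] + stats::rnorm(b - a + 1L, sd = cpl$chin * 4)
    }
  }
  channels[["Chin EMG"]] <- psg_channel("Chin EMG", config$emg_fs, x, "uV")

  # -- heart rate and ECG ---------------------------------------------------
  tsec <- seq_len(dur) - 1
  hr <- 60 + 4 * sin(2 * pi * tsec / 300) +
    as.numeric(stats::filter(stats::rnorm(dur, sd = 0.6), 0.95, method = "recursive"))
  if (nrow(movements) && cpl$hr > 0) {
    for (i in seq_len(nrow(movements))) {
      a <- floor(movements$onset[i]) + 1L
      b <- min(dur, a + 7L)
      if (a <= dur) hr[a:b] <- hr[a:b] + cpl$hr * exp(-(0:(b - a)) / 3)
    }
  }
  hr <- pmin(pmax(hr, 35), 180)
  channels[["HR"]] <- psg_channel("HR", 1, hr, "bpm")

  fs_e <- config$ecg_fs
  phase <- cumsum(rep(hr / 60, each = fs_e) / fs_e)
  beat_idx <- which(diff(floor(c(0, phase))) > 0)
  qrs_t <- seq(-0.04, 0.06, by = 1 / fs_e)
  template <- 1.2 * exp(-(qrs_t / 0.012)^2) - 0.25 * exp(-((qrs_t - 0.035) / 0.02)^2)
  x <- stats::rnorm(dur * fs_e, sd = 0.03)
  x <- add_pulses(x, beat_idx, template)
  channels[["ECG"]] <- psg_channel("ECG", fs_e, x, "mV")

  # -- respiration: airflow, effort, sound ----------------------------------
  resp_env_1hz <- function(reduced) {
    env <- rep(1, dur)
    if (nrow(apnea)) for (i in seq_len(nrow(apnea))) {
      a <- floor(apnea$onset[i]) + 1L
      b <- min(dur, ceiling(apnea$onset[i] + apnea$duration[i]))
      env[a:b] <- if (apnea$kind[i] == "apnea") reduced[1] else reduced[2]
    }
    env
  }
  fs_a <- config$airflow_fs
  ta <- seq_len(dur * fs_a) / fs_a
  flow_env <- per_sample(resp_env_1hz(c(0.05, 0.3)), fs_a)
  x <- sin(2 * pi * config$resp_rate * ta) * flow_env + stats::rnorm(dur * fs_a, sd = 0.05)
  channels[["Airflow"]] <- psg_channel("Airflow", fs_a, x, "a.u.")

  fs_f <- config$effort_fs
  tf <- seq_len(dur * fs_f) / fs_f
  eff_env <- per_sample(resp_env_1hz(c(0.6, 0.5)), fs_f)
  for (lab in c("Thor", "Abdo")) {
    ph <- stats::runif(1, 0, 2 * pi)
    x <- 0.8 * sin(2 * pi * config$resp_rate * tf + ph) * eff_env +
      stats::rnorm(dur * fs_f, sd = 0.04)
    channels[[lab]] <- psg_channel(lab, fs_f, x, "a.u.")
  }

  x <- abs(stats::rnorm(dur * fs_a, sd = 0.05)) *
    (1 + 0.6 * pmax(sin(2 * pi * config$resp_rate * ta), 0) * flow_env)
  channels[["Sound"]] <- psg_channel("Sound", fs_a, x, "a.u.")

  # -- SpO2 -----------------------------------------------------------------
  spo2 <- 96 + as.numeric(stats::filter(stats::rnorm(dur, sd = 0.08),
                                        0.98, method = "recursive"))
  add_dip <- function(s, t0, depth, fall, recover) {
    a <- floor(t0) + 1L
    shape <- c(seq(0, depth, length.out = fall),
               seq(depth, 0, length.out = recover))
    b <- min(dur, a + length(shape) - 1L)
    if (a <= dur) s[a:b] <- s[a:b] - shape[seq_len(b - a + 1L)]
    s
  }
  if (nrow(apnea)) for (i in seq_len(nrow(apnea))) {
    lag <- stats::runif(1, config$desat_lag[1], config$desat_lag[2])
    depth <- max(1, config$desat_depth + stats::rnorm(1, sd = 0.5)) *
      (if (apnea$kind[i] == "apnea") 1 else 0.6)
    spo2 <- add_dip(spo2, apnea$onset[i] + lag, depth, 8, 12)
  }
  if (nrow(movements) && cpl$spo2 > 0) for (i in seq_len(nrow(movements)))
    spo2 <- add_dip(spo2, movements$onset[i] + 1, cpl$spo2, 2, 3)
  spo2 <- pmin(pmax(spo2, 70), 100)
  channels[["SpO2"]] <- psg_channel("SpO2", 1, spo2, "%")

  # -- body position --------------------------------------------------------
  n_turn <- stats::rpois(1L, 1.5 * hours)
  turns <- sort(stats::runif(n_turn, 0, dur))
  pos <- integer(dur)
  codes <- c(0L, sample(0:3, n_turn, replace = TRUE))
  bounds <- c(0, floor(turns), dur)
  for (i in seq_len(length(bounds) - 1L))
    if (bounds[i + 1L] > bounds[i]) pos[(bounds[i] + 1L):bounds[i + 1L]] <- codes[i]
  channels[["Position"]] <- psg_channel("Position", 1, pos, "code")

  # -- leg EMG --------------------------------------------------------------
  fs_l <- config$emg_fs
  x <- stats::rnorm(dur * fs_l, sd = config$emg_resting)
  if (nrow(movements)) {
    burst_sd <- config$emg_resting + config$plm$burst_amplitude
    ramp <- max(1L, round(0.05 * fs_l))
    for (i in seq_len(nrow(movements))) {
      a <- floor(movements$onset[i] * fs_l) + 1L
      len <- max(2L * ramp, round(movements$duration[i] * fs_l))
      b <- min(dur * fs_l, a + len - 1L)
      if (a > dur * fs_l) next
      m <- b - a + 1L
      env <- rep(1, m)
      r <- min(ramp, floor(m / 2))
      if (r > 0) {
        env[seq_len(r)] <- seq(0.2, 1, length.out = r)
        env[(m - r + 1L):m] <- seq(1, 0.2, length.out = r)
      }
      x[a:b] <- x[a:b] + stats::rnorm(m, sd = burst_sd) * env
    }
  }
  channels[["Leg EMG"]] <- psg_channel("Leg EMG", fs_l, x, "uV")

  # -- artefact injection ---------------------------------------------------
  art_rows <- NULL
  if (nrow(artefact)) {
    labs <- names(channels)
    art_ch <- sample(labs, nrow(artefact), replace = TRUE)
    for (i in seq_len(nrow(artefact))) {
      ch <- channels[[art_ch[i]]]
      a <- floor(artefact$onset[i] * ch$fs) + 1L
      b <- min(length(ch$samples),
               a + max(1L, round(artefact$duration[i] * ch$fs)) - 1L)
      if (a > length(ch$samples)) next
      amp <- 8 * max(stats::sd(ch$samples), 1e-6)
      ch$samples[a:b] <- ch$samples[a:b] + stats::rnorm(b - a + 1L, sd = amp)
      channels[[art_ch[i]]] <- ch
    }
    art_rows <- data.frame(kind = "artefact", onset = artefact$onset,
                           duration = artefact$duration, channel = art_ch,
                           value = NA_character_, stringsAsFactors = FALSE)
  }

  # -- annotations ----------------------------------------------------------
  ev <- stage_ev
  if (nrow(apnea))
    ev <- rbind(ev, data.frame(kind = apnea$kind, onset = apnea$onset,
                               duration = apnea$duration,
                               channel = "Airflow", value = NA_character_))
  if (nrow(movements)) {
    ev <- rbind(ev, data.frame(kind = "leg_movement", onset = movements$onset,
                               duration = movements$duration,
                               channel = "Leg EMG", value = NA_character_))
    ser <- do.call(rbind, lapply(seq_along(series), function(i) {
      s <- series[[i]]
      data.frame(kind = "plm_series", onset = s$onset[1],
                 duration = s$onset[nrow(s)] + s$duration[nrow(s)] - s$onset[1],
                 channel = "Leg EMG", value = as.character(nrow(s)))
    }))
    ev <- rbind(ev, ser)
  }
  if (!is.null(art_rows)) ev <- rbind(ev, art_rows)

  list(recording = psg_recording(config$patient_id, unname(channels)),
       annotations = psg_annotations(ev, duration = dur))
}
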
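# Synthetic PSG generator: determinism, hypnogram statistics, PLM train
# counts, physiological clamps, leg-EMG burst energy.

test_that("identical config and seed give bit-identical output", {
  cfg <- small_sim(seed = 42, duration = 600)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1$annotations, g2$annotations)
  for (lab in names(g1$recording$channels))
    expect_identical(g1$recording$channels[[lab]]$samples,
                     g2$recording$channels[[lab]]$samples)
  # hypnogram determinism
  expect_identical(generate_hypnogram(cfg, seed = 7),
                   generate_hypnogram(cfg, seed = 7))
})

test_that("hypnogram tiles the recording and respects stage occupancy", {
  cfg <- small_sim(duration = 300,
                   stage_probs = c(Wake = 0, N1 = 0, N2 = 1, N3 = 0, REM = 0))
  h <- generate_hypnogram(cfg, seed = 1)
  expect_identical(unique(h$value), "N2")
  expect_equal(sum(h$duration), 300)
  expect_equal(h$onset[1], 0)
  if (nrow(h) > 1)
    expect_equal(h$onset[-1], cumsum(h$duration)[-nrow(h)])

  # wake occupancy ~ configured fraction (Monte Carlo over 20 seeds, 8 h)
  cfg8 <- sim_config(duration = 8 * 3600,
                     stage_probs = c(Wake = 0.1, N1 = 0.1, N2 = 0.5,
                                     N3 = 0.15, REM = 0.15))
  wake_frac <- vapply(1:20, function(s) {
    h <- generate_hypnogram(cfg8, seed = s)
    sum(h$duration[h$value == "Wake"]) / sum(h$duration)
  }, numeric(1))
  expect_lt(abs(mean(wake_frac) - 0.1), 0.05)
})

test_that("PLM train counts scale with the configured rate", {
  # 6 series/h x 4 movements over 2 h -> about 48 movements
  counts <- vapply(1:5, function(s) {
    cfg <- sim_config(duration = 7200, seed = s,
                      plm = plm_spec(series_rate = 6, movements_per_series = 4),
                      coupling = coupling_none())
    ann <- generate_recording(cfg)$annotations
    sum(ann$kind == "leg_movement")
  }, numeric(1))
  expect_gt(mean(counts), 48 - 3 * sqrt(48))
  expect_lt(mean(counts), 48 + 3 * sqrt(48))
})

test_that("generated events respect Coleman bounds and physiological clamps", {
  cfg <- small_sim(seed = 3, duration = 1800)
  gen <- generate_recording(cfg)
  ann <- gen$annotations
  mv <- ann[ann$kind == "leg_movement", ]
  expect_true(all(mv$duration >= 0.5 & mv$duration <= 5))
  # onset-to-onset intervals inside each series lie within [5, 90]
  series <- group_periodic_series(mv[, c("onset", "duration")])
  expect_gt(length(series), 0)
  for (s in series) {
    gaps <- diff(s$onset)
    expect_true(all(gaps >= 5 & gaps <= 90))
    expect_gte(nrow(s), 4)
  }
  spo2 <- gen$recording$channels[["SpO2"]]$samples
  expect_true(all(spo2 >= 70 & spo2 <= 100))
  # Coleman-violating configs are rejected outright
  expect_error(plm_spec(movements_per_series = 3), "Coleman")
  expect_error(plm_spec(interval = c(2, 30)), "Coleman")
  expect_error(plm_spec(movement_duration = c(0.5, 6)), "Coleman")
})

test_that("leg-EMG energy inside movements exceeds resting by the burst amplitude", {
  cfg <- small_sim(seed = 5, duration = 1800, coupling = coupling_none())
  gen <- generate_recording(cfg)
  leg <- gen$recording$channels[["Leg EMG"]]
  mv <- gen$annotations[gen$annotations$kind == "leg_movement", ]
  in_mov <- rep(FALSE, length(leg$samples))
  for (i in seq_len(nrow(mv))) {
    a <- floor(mv$onset[i] * leg$fs) + 1
    b <- min(length(leg$samples), ceiling((mv$onset[i] + mv$duration[i]) * leg$fs))
    in_mov[a:b] <- TRUE
  }
  # exclude artefact windows from the resting estimate
  art <- gen$annotations[gen$annotations$kind == "artefact" &
                           gen$annotations$channel == "Leg EMG", ]
  ok <- rep(TRUE, length(leg$samples))
  for (i in seq_len(nrow(art))) {
    a <- floor(art$onset[i] * leg$fs) + 1
    b <- min(length(leg$samples), ceiling((art$onset[i] + art$duration[i]) * leg$fs))
    ok[a:b] <- FALSE
  }
  rms_in <- sqrt(mean(leg$samples[in_mov & ok]^2))
  rms_out <- sqrt(mean(leg$samples[!in_mov & ok]^2))
  expect_gt(rms_in - rms_out, 0.8 * cfg$plm$burst_amplitude)
})

test_that("zero coupling leaves non-leg features uninformative about labels", {
  cfg <- small_sim(seed = 11, duration = 2400, coupling = coupling_none())
  gen <- generate_recording(cfg)
  es <- retained(exclude_all(segment(gen$recording), gen$annotations))
  mv <- gen$annotations[gen$annotations$kind == "leg_movement", c("onset", "duration")]
  es <- label_epochs(es, do.call(rbind, group_periodic_series(mv)))
  ft <- extract_feature_table(gen$recording, gen$annotations, es)
  expect_setequal(unique(ft$label), c("PLM", "non-PLM"))
  # permutation null for the maximum gain ratio across attributes
  X <- feature_matrix(ft)
  max_gr <- max(vapply(seq_len(ncol(X)), function(j)
    gain_ratio(X[, j], ft$label), numeric(1)))
  set.seed(99)
  null_max <- vapply(1:19, function(s) {
    perm <- sample(ft$label)
    max(vapply(seq_len(ncol(X)), function(j)
      gain_ratio(X[, j], perm), numeric(1)))
  }, numeric(1))
  # observed max should look like a draw from the permutation null
  expect_lte(max_gr, max(null_max) * 1.5)
})

test_that("classifier accuracy is non-decreasing in coupling effect size", {
  # 3 coupling levels x 5 seeds on short single-patient nights; the
  # downstream 1-NN accuracy must rise with coupling, within sampling
  # noise of 3 percentage points
  levels_ <- list(none = coupling_none(),
                  mid = coupling_spec(eeg = 0.7, chin = 1.4, spo2 = 1.4, hr = 5),
                  strong = coupling_spec())
  acc <- vapply(levels_, function(cpl) {
    mean(vapply(1:5, function(s)
      run_synthetic_experiment(seed = 7000 + s, coupling = cpl,
                               n_patients = 1, duration = 2700,
                               cv_k = 5)$accuracy,
      numeric(1)))
  }, numeric(1))
  expect_gte(acc[["mid"]], acc[["none"]] - 0.03)
  expect_gte(acc[["strong"]], acc[["mid"]] - 0.03)
  expect_gt(acc[["strong"]], acc[["none"]] + 0.2)
})

test_that("recording carries the full montage with configured rates", {
  gen <- generate_recording(small_sim(duration = 600))
  rec <- gen$recording
  expect_setequal(
    names(rec$channels),
    c("C3-A2", "C4-A1", "F3-A2", "F4-A1", "O1-A2", "O2-A1", "LOC", "ROC",
      "Chin EMG", "HR", "ECG", "Airflow", "Thor", "Abdo", "Sound", "SpO2",
      "Position", "Leg EMG"))
  expect_equal(rec$channels[["Airflow"]]$fs, 256)
  expect_equal(rec$channels[["SpO2"]]$fs, 1)
  expect_equal(rec$duration, 600)
  # every annotation lies inside the recording
  ann <- gen$annotations
  expect_true(all(ann$onset >= 0))
  expect_true(all(ann$onset + ann$duration <= 600 + 1e-9))
})
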
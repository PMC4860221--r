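# DSP features: Haar subbands, band power, zero crossings, statistics,
# spectral entropy, oximetry, context, and the 77-attribute registry.

test_that("Haar decomposition conserves energy and places sinusoids dyadically", {
  set.seed(1)
  fs <- 256
  x <- rnorm(5 * fs)
  sb <- haar_subbands(x, fs)
  expect_equal(lengths(sb), c(delta = 1280L, theta = 1280L,
                              alpha = 1280L, beta = 1280L))
  # zero in, zero out
  z <- haar_subbands(numeric(5 * fs), fs)
  expect_true(all(vapply(z, function(c) all(c == 0), logical(1))))

  # Parseval: band energies + residual (approximation + >32 Hz details)
  # cannot exceed the total, and a full reconstruction is exact
  e_bands <- sum(vapply(sb, function(c) sum(c^2), numeric(1)))
  expect_lte(e_bands, sum(x^2) * (1 + 1e-9))
  # orthogonality: component energies from coefficients match reconstruction
  lt <- haar_subbands(sin(2 * pi * 6 * (0:1279) / fs), fs)
  e <- vapply(lt, function(c) sum(c^2), numeric(1))
  # dyadic placement oracle (matches an independent Haar implementation):
  # a 6 Hz tone lands dominantly in theta with share ~0.540
  expect_identical(names(which.max(e)), "theta")
  expect_equal(unname(e["theta"] / sum(e)), 0.540, tolerance = 0.01)
  expect_error(haar_subbands(numeric(160), 32), "64")
})

test_that("band power is the spectral mean square (discrete Parseval)", {
  fs <- 128
  t <- (0:639) / fs
  x <- sin(2 * pi * 8 * t)  # 8 Hz on a DFT bin (640 samples, 0.2 Hz bins)
  expect_equal(band_power(x), 0.5, tolerance = 1e-12)
  expect_identical(band_power(numeric(64)), 0)
  set.seed(2)
  y <- rnorm(640)
  expect_equal(band_power(y), mean(y^2), tolerance = 1e-9)
})

test_that("Haar band powers track direct DFT band integration for band-limited noise", {
  set.seed(3)
  fs <- 256
  nominal <- list(delta = c(0.5, 4), theta = c(4, 8),
                  alpha = c(8, 16), beta = c(16, 32))
  for (b in names(nominal)) {
    # noise confined to the band's dyadic range
    n <- 5 * fs
    X <- rep(0 + 0i, n)
    freqs <- (seq_len(n) - 1) * fs / n
    sel <- freqs >= nominal[[b]][1] & freqs < nominal[[b]][2]
    X[sel] <- complex(real = rnorm(sum(sel)), imaginary = rnorm(sum(sel)))
    x <- Re(stats::fft(X, inverse = TRUE)) / n
    sb <- haar_subbands(x, fs)
    hp <- band_power(sb[[b]])
    dp <- dft_band_power(x, fs, nominal[[b]][1], nominal[[b]][2])
    # Haar octave filters are leaky: the matching detail level captures
    # roughly half to three quarters of the true in-band energy (measured
    # against the direct DFT integral; identical in any Haar implementation)
    expect_gt(hp / dp, 0.35)
    expect_lt(hp / dp, 0.9)
    # and the matching band always dominates the other three
    others <- vapply(sb[setdiff(names(sb), b)], band_power, numeric(1))
    expect_gt(hp, max(others))
  }
})

test_that("zero crossings count strictly opposite adjacent signs", {
  expect_identical(zero_crossings(rep(3, 10)), 0L)
  expect_identical(zero_crossings(c(1, -1, 1, -1)), 3L)
  # 5 Hz over 5 s at fs = 128, phase 0.1 rad: crossings at t = (k*pi - 0.1)/(10*pi)
  # for k = 1..49 fall inside the sampled grid (the 50th lies 4 ms past the
  # final sample), so enumeration gives 49
  t <- (0:639) / 128
  expect_identical(zero_crossings(sin(2 * pi * 5 * t + 0.1)), 49L)
  # a full 5-s grid with phase 0 picks up 2 crossings per cycle x 25 cycles
  t2 <- (0:640) / 128
  expect_identical(zero_crossings(sin(2 * pi * 5 * t2 + 1e-9)), 50L)
  # zeros never count
  expect_identical(zero_crossings(c(1, 0, 1, 0, 1)), 0L)
  expect_error(zero_crossings(1), "at least 2")
})

test_that("basic statistics and oximetry features", {
  expect_equal(basic_stats(numeric(5)), list(mean = 0, rms = 0))
  expect_equal(basic_stats(rep(-2, 4)), list(mean = -2, rms = 2))
  expect_equal(basic_stats(c(3, 4)), list(mean = 3.5, rms = sqrt(12.5)))

  expect_equal(spo2_features(rep(96, 5)),
               list(desaturation = 0, lowest_spo2 = 96, rms = 96))
  dip <- c(97, 94, 91, 94, 97)
  f <- spo2_features(dip)
  expect_equal(f$desaturation, 6)
  expect_equal(f$lowest_spo2, 91)
  expect_gte(f$desaturation, 0)
  expect_error(spo2_features(numeric(0)), "empty")
  expect_error(spo2_features(c(96, 101)), "\\[0, 100\\]")
})

test_that("spectral entropy hits its closed-form extremes", {
  fs <- 128
  t <- (0:639) / fs
  # single-bin sinusoid: all mass in one bin -> entropy 0
  s <- spectral_features(sin(2 * pi * 8 * t), fs)
  expect_equal(s$spectral_entropy, 0, tolerance = 1e-9)
  # two equal sinusoids at distinct bins -> 1 bit
  s2 <- spectral_features(sin(2 * pi * 8 * t) + sin(2 * pi * 16 * t), fs)
  expect_equal(s2$spectral_entropy, 1, tolerance = 1e-9)
  # flat spectrum (impulse) -> log2(#bins); all-zero -> 0 by convention
  imp <- c(1, numeric(63))
  expect_equal(spectral_features(imp)$spectral_entropy, log2(32),
               tolerance = 1e-6)
  expect_identical(spectral_features(numeric(64))$spectral_entropy, 0)
  expect_error(spectral_features(1:4), "at least 8")
})

test_that("context features read annotations and slow channels", {
  ann <- psg_annotations(data.frame(
    kind = c("stage", "apnea"), onset = c(0, 40), duration = c(120, 10),
    value = c("N2", NA)))
  chans <- list(HR = psg_channel("HR", 1, rep(60, 120), "bpm"),
                Position = psg_channel("Position", 1, rep(0, 120), "code"))
  cf <- context_features(c(10, 15), ann, chans)
  expect_equal(cf, list(apnea_flag = 0L, sleep_stage = 2L, position = 0,
                        heart_rate = 60))
  # epoch overlapping the apnea (pre-exclusion) flags it
  expect_identical(context_features(c(45, 50), ann, chans)$apnea_flag, 1L)
  # stage codes round-trip through the documented table
  codes <- stage_codes()
  expect_identical(names(codes)[match(codes, codes)], names(codes))
  # missing HR channel -> NA
  expect_true(is.na(context_features(c(10, 15), ann, list())$heart_rate))
})

test_that("the default registry is the fixed 77-attribute table", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 77L)
  expect_false(any(grepl("Leg", reg$channel)))
  expect_identical(reg$name[1], "C3-A2.delta")
  expect_identical(reg$name[55], "Airflow.apnea_flag")
  expect_identical(reg$name[56], "EEG.sleep_stage")
  expect_identical(reg$name[70], "HR.heart_rate")
  expect_identical(reg$name[77], "Thor.rms")
  expect_identical(sum(reg$channel %in% c("C3-A2", "C4-A1", "F3-A2", "F4-A1",
                                          "O1-A2", "O2-A1")), 54L)
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("feature extraction is leg-EMG independent and dimensioned correctly", {
  cfg <- small_sim(seed = 17, duration = 900)
  gen <- generate_recording(cfg)
  es <- retained(exclude_all(segment(gen$recording), gen$annotations))
  mv <- gen$annotations[gen$annotations$kind == "leg_movement", c("onset", "duration")]
  es <- label_epochs(es, do.call(rbind, group_periodic_series(mv)))

  ft <- extract_feature_table(gen$recording, gen$annotations, es)
  expect_identical(ncol(ft), 80L)  # 77 attributes + 3 id columns
  expect_identical(nrow(ft), nrow(es))
  expect_identical(names(ft)[1:3], c("patient_id", "epoch_index", "label"))

  # dropping the leg-EMG channel changes nothing
  rec2 <- gen$recording
  rec2$channels[["Leg EMG"]] <- NULL
  ft2 <- extract_feature_table(rec2, gen$annotations, es)
  expect_identical(ft, ft2)

  # energy features non-negative; entropy within [0, log2(bins)]
  for (nm in grep("(delta|theta|alpha|beta|rms)$", names(ft), value = TRUE))
    expect_true(all(ft[[nm]] >= 0), info = nm)
  for (nm in grep("spectral_entropy$", names(ft), value = TRUE)) {
    fs_ch <- gen$recording$channels[[sub("\\..*", "", nm)]]$fs
    expect_true(all(ft[[nm]] >= 0 & ft[[nm]] <= log2(5 * fs_ch / 2)), info = nm)
  }
  # apnea flag is identically 0 on retained epochs (by construction of the
  # apnea-adjacency exclusion)
  expect_true(all(ft[["Airflow.apnea_flag"]] == 0))

  # a missing registry channel is a named error
  rec3 <- gen$recording
  rec3$channels[["Thor"]] <- NULL
  expect_error(extract_feature_table(rec3, gen$annotations, es), "Thor")
})

test_that("extraction on an all-zero recording yields zero power features", {
  fs <- 64; dur <- 30
  mk <- function(lab, f = fs) psg_channel(lab, f, numeric(dur * f), "uV")
  rec <- psg_recording("Z", lapply(
    c("C3-A2", "C4-A1", "F3-A2", "F4-A1", "O1-A2", "O2-A1", "LOC", "ROC",
      "Chin EMG", "ECG", "Airflow", "Thor", "Abdo", "Sound"), mk))
  rec$channels <- c(rec$channels,
                    list(HR = psg_channel("HR", 1, numeric(dur), "bpm"),
                         SpO2 = psg_channel("SpO2", 1, numeric(dur) + 90, "%"),
                         Position = psg_channel("Position", 1, numeric(dur), "code")))
  es <- segment(dur); es$label <- "non-PLM"
  ft <- extract_feature_table(rec, sleep_stages_ann(dur), es)
  for (nm in grep("(delta|theta|alpha|beta|zero_crossings|mean|rms)$",
                  names(ft), value = TRUE))
    if (!grepl("SpO2|HR|Position", nm))
      expect_true(all(ft[[nm]] == 0), info = nm)
})
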
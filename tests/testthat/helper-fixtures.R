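# Shared fixtures and independent oracles, all built in code.

# Small recording: a few channels with simple deterministic content.
tiny_recording <- function(duration = 60, patient_id = "T01") {
  fs <- 64
  t <- seq_len(duration * fs) / fs
  psg_recording(patient_id, list(
    psg_channel("C3-A2", fs, sin(2 * pi * 10 * t), "uV"),
    psg_channel("SpO2", 1, rep(96, duration), "%"),
    psg_channel("HR", 1, rep(60, duration), "bpm")
  ))
}

# Short all-sleep hypnogram annotation set.
sleep_stages_ann <- function(duration, stage = "N2") {
  psg_annotations(data.frame(kind = "stage", onset = 0, duration = duration,
                             value = stage), duration = duration)
}

# Fast small-scale simulation config for pipeline tests.
small_sim <- function(seed = 1, duration = 1200, coupling = coupling_spec(),
                      patient_id = "S01", ...) {
  sim_config(patient_id = patient_id, duration = duration, seed = seed,
             coupling = coupling, ...)
}

# Independent brute-force gain-ratio oracle: a plain double loop over the
# contingency table of (discretized attribute, class), no shared code with
# gain_ratio() beyond discretize().
oracle_gain_ratio <- function(values, labels, n_bins = 10) {
  bins <- if (is.numeric(values)) discretize(values, n_bins) else values
  ub <- unique(bins); ul <- unique(labels)
  n <- length(labels)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  # H(Class)
  pc <- vapply(ul, function(l) sum(labels == l) / n, numeric(1))
  h_class <- ent(pc)
  # H(Class | Attr) and H(Attr)
  h_cond <- 0; pa <- numeric(length(ub))
  for (i in seq_along(ub)) {
    in_bin <- bins == ub[i]
    pa[i] <- sum(in_bin) / n
    pcl <- vapply(ul, function(l) sum(labels == l & in_bin) / sum(in_bin),
                  numeric(1))
    h_cond <- h_cond + pa[i] * ent(pcl)
  }
  h_attr <- ent(pa)
  if (h_attr == 0) return(0)
  (h_class - h_cond) / h_attr
}

# Direct DFT band-power oracle: integrate the one-sided periodogram over
# [lo, hi) Hz, on the mean-square scale used by band_power().
dft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- (freqs >= lo & freqs < hi) | (freqs > fs - hi & freqs <= fs - lo)
  sum(Mod(X[sel])^2) / n^2
}
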
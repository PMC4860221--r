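# End-to-end pipeline commands: simulate -> extract -> rank -> evaluate.
# These functions are the package's command surface; inst/cli/plmdetect.R
# is a thin Rscript wrapper over them.

#' Pipeline configuration
#'
#' Defaults equal the published pipeline parameters: 5-s epochs, 15-s
#' apnea margin, 10% subsample, 10 discretization bins, 10-fold
#' cross-validation repeated 10 times.
#'
#' @param sim_configs List of [sim_config()]s (one per simulated
#'   patient).
#' @param epoch_length Epoch length (s).
#' @param apnea_margin Apnea-adjacency exclusion margin (s).
#' @param sample_percent Per-class subsample percentage after balancing.
#' @param n_bins Discretization bins for gain-ratio ranking.
#' @param cv_k,cv_repeats Cross-validation folds and repeats.
#' @param models List of [model_spec()]s to evaluate.
#' @param seed Master seed for balancing and fold assignment.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_configs = list(sim_config()),
                            epoch_length = 5, apnea_margin = 15,
                            sample_percent = 10, n_bins = 10,
                            cv_k = 10, cv_repeats = 10,
                            models = list(model_spec("knn"),
                                          model_spec("random_forest"),
                                          model_spec("mlp"),
                                          model_spec("logistic_regression")),
                            seed = 1) {
  structure(list(sim_configs = sim_configs, epoch_length = epoch_length,
                 apnea_margin = apnea_margin, sample_percent = sample_percent,
                 n_bins = n_bins, cv_k = cv_k, cv_repeats = cv_repeats,
                 models = models, seed = seed),
            class = "pipeline_config")
}

#' Simulate recordings to disk
#'
#' Writes one EDF + annotation XML pair per simulated patient, plus a
#' `manifest.csv` listing every file.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest (patient_id, edf, annotations), invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(config$sim_configs, function(sc) {
    gen <- generate_recording(sc)
    edf <- file.path(out_dir, paste0(sc$patient_id, ".edf"))
    xml <- file.path(out_dir, paste0(sc$patient_id, ".annotations.xml"))
    write_recording(gen$recording, edf)
    write_annotations(gen$annotations, xml)
    data.frame(patient_id = sc$patient_id, edf = edf, annotations = xml,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# Segment + exclude + label one recording/annotation pair.
label_retained_epochs <- function(recording, annotations, epoch_length = 5,
                                  apnea_margin = 15) {
  es <- segment(recording, epoch_length)
  es <- exclude_all(es, annotations, margin = apnea_margin)
  mv <- events_of_kind(annotations, "leg_movement")
  series <- group_periodic_series(mv[, c("onset", "duration")])
  inset <- if (length(series)) do.call(rbind, series) else
    data.frame(onset = numeric(), duration = numeric())
  es <- label_epochs(es, inset)
  es
}

#' Extract a labelled, balanced feature table from recordings
#'
#' For each patient: segment into epochs, apply the three exclusion
#' stages, label epochs from the annotated leg movements (grouped into
#' Coleman-compliant series); then pool patients, balance classes and
#' subsample per patient.
#'
#' @param config A [pipeline_config()].
#' @param recordings Either a manifest data frame from [cmd_simulate()]
#'   (EDF/XML paths) or `NULL` to generate in memory from
#'   `config$sim_configs`.
#' @return List: `features` (balanced [extract_feature_table()] result),
#'   `provenance` (per-patient exclusion counts).
#' @export
cmd_extract <- function(config, recordings = NULL) {
  tables <- list(); prov <- list()
  inputs <- if (is.null(recordings)) config$sim_configs else
    split(recordings, seq_len(nrow(recordings)))
  for (inp in inputs) {
    if (inherits(inp, "sim_config")) {
      gen <- generate_recording(inp)
      rec <- gen$recording; ann <- gen$annotations
    } else {
      rec <- read_recording(inp$edf, patient_id = inp$patient_id)
      ann <- read_annotations(inp$annotations)
    }
    es <- label_retained_epochs(rec, ann, config$epoch_length,
                                config$apnea_margin)
    prov[[rec$patient_id]] <- provenance_counts(es)
    keep <- retained(es)
    tables[[rec$patient_id]] <- extract_feature_table(rec, ann, keep)
    rm(rec)
  }
  ft <- do.call(rbind, tables)
  attr(ft, "registry") <- feature_registry()
  class(ft) <- c("feature_table", "data.frame")
  rownames(ft) <- NULL
  # balance + subsample on the pooled epoch ids, then subset the table
  es <- ft[, c("patient_id", "epoch_index", "label")]
  names(es)[2] <- "index"
  es$start <- es$index * config$epoch_length
  es$end <- es$start + config$epoch_length
  class(es) <- c("epoch_set", "data.frame")
  sel <- balance_and_subsample(es, config$sample_percent, seed = config$seed)
  key <- paste(ft$patient_id, ft$epoch_index)
  out <- ft[match(paste(sel$patient_id, sel$index), key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "registry") <- feature_registry()
  class(out) <- c("feature_table", "data.frame")
  list(features = out, provenance = do.call(rbind, prov))
}

#' Rank attributes of a feature CSV or table
#'
#' @param config A [pipeline_config()].
#' @param features A feature table or path to a feature CSV.
#' @param out Optional output CSV path.
#' @return The [rank_attributes()] ranking, invisibly if written.
#' @export
cmd_rank <- function(config, features, out = NULL) {
  if (is.character(features)) features <- read_feature_csv(features)
  ranking <- rank_attributes(features, n_bins = config$n_bins)
  if (!is.null(out)) {
    utils::write.csv(ranking, out, row.names = FALSE)
    return(invisible(ranking))
  }
  ranking
}

#' Evaluate classifiers on a feature table
#'
#' @param config A [pipeline_config()].
#' @param features A feature table or path to a feature CSV.
#' @param out_dir Optional directory for `cv_folds.csv` and
#'   `cv_summary.csv`.
#' @return The [cross_validate()] report.
#' @export
cmd_evaluate <- function(config, features, out_dir = NULL) {
  if (is.character(features)) features <- read_feature_csv(features)
  report <- cross_validate(features, config$models, k = config$cv_k,
                           repeats = config$cv_repeats, seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$folds, file.path(out_dir, "cv_folds.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summary, file.path(out_dir, "cv_summary.csv"),
                     row.names = FALSE)
  }
  report
}

#' Write/read a feature table as CSV
#'
#' Column headers are the `channel.feature` registry names plus the id
#' columns `patient_id`, `epoch_index`, `label`.
#'
#' @param feature_table A feature table.
#' @param path CSV path.
#' @return `path` (write) or the feature table (read).
#' @export
write_feature_csv <- function(feature_table, path) {
  utils::write.csv(as.data.frame(feature_table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  ft <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  reg <- feature_registry()
  if (all(reg$name %in% names(ft))) attr(ft, "registry") <- reg
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Published reference cross-validation fold results
#'
#' A fixed set of forty 10-fold confusion matrices (10 folds x 4
#' classifier types, two-class PLM / non-PLM problem, fold sizes 929 or
#' 928) with their reported per-fold accuracy and RMSE, shipped as a
#' plain-text fixture. Used to validate the package's metric
#' recomputation: accuracy recomputed from each matrix must reproduce
#' the reported value to 4 decimals, as must the per-model means.
#'
#' @return Data frame with columns `model`, `fold`, `pred1_act1`,
#'   `pred1_act2`, `pred2_act1`, `pred2_act2`, `accuracy`, `rmse`.
#' @export
reference_cv_folds <- function() {
  path <- system.file("extdata", "reference_cv_folds.csv",
                      package = "plmdetect", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reported per-model mean accuracy and RMSE for the reference folds
#'
#' @return Data frame with columns `model`, `mean_accuracy`,
#'   `mean_rmse`.
#' @export
reference_cv_means <- function() {
  data.frame(model = c("mlp", "knn", "random_forest", "logistic_regression"),
             mean_accuracy = c(0.8329, 0.9187, 0.9098, 0.8437),
             mean_rmse = c(0.3705, 0.2850, 0.2740, 0.3515),
             stringsAsFactors = FALSE)
}

#' Run the synthetic end-to-end benchmark
#'
#' Generates `n_patients` synthetic nights, runs the epoch pipeline with
#' balancing (no further subsampling by default, so all balanced epochs
#' are used), and evaluates 1-NN under stratified k-fold
#' cross-validation. This is the scaled-down synthetic analogue of the
#' clinical classification experiment: with strong coupling the 1-NN
#' accuracy should be high; with zero coupling it must sit at chance.
#'
#' @param seed Integer seed driving generation, balancing and folds.
#' @param coupling `"strong"` (the [coupling_spec()] defaults) or
#'   `"none"`, or a [coupling_spec()].
#' @param n_patients Number of simulated patients.
#' @param duration Seconds per recording.
#' @param sample_percent Per-class percentage kept after balancing.
#' @param models List of [model_spec()]s (default 1-NN only).
#' @param cv_k,cv_repeats Folds / repeats.
#' @return List: `report` (the [cross_validate()] result), `n_epochs`
#'   (balanced table size), `accuracy` (mean accuracy of the first
#'   model).
#' @export
run_synthetic_experiment <- function(seed = 1, coupling = "strong",
                                     n_patients = 3, duration = 21600,
                                     sample_percent = 100,
                                     models = list(model_spec("knn")),
                                     cv_k = 10, cv_repeats = 1) {
  cpl <- if (inherits(coupling, "coupling_spec")) coupling
  else switch(coupling, strong = coupling_spec(), none = coupling_none(),
              stop("coupling must be 'strong', 'none' or a coupling_spec"))
  sims <- lapply(seq_len(n_patients), function(i)
    sim_config(patient_id = sprintf("P%03d", i), duration = duration,
               seed = as.integer((abs(seed) * 1009 + i) %% 2147483647),
               coupling = cpl))
  cfg <- pipeline_config(sim_configs = sims, sample_percent = sample_percent,
                         cv_k = cv_k, cv_repeats = cv_repeats,
                         models = models, seed = seed)
  ext <- cmd_extract(cfg)
  report <- cmd_evaluate(cfg, ext$features)
  list(report = report, n_epochs = nrow(ext$features),
       provenance = ext$provenance,
       accuracy = report$summary$mean_accuracy[1])
}
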
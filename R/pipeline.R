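#' Extract features for a whole cohort
#'
#' Streams over subjects: each recording is (re)generated from its seed if
#' the bundle does not hold recordings, features are extracted, and the
#' recording is discarded — keeping memory flat even for the full default
#' cohort.
#'
#' @param cohort A `cohort_bundle` (recordings optional) from
#'   [generate_cohort()].
#' @param eeg_cfg,emg_cfg,cop_include Passed to [extract_subject_features()].
#' @param keep_channel_powers Keep per-electrode band powers for the
#'   electrode-wise statistics.
#' @param progress Print one line per subject.
#' @return List with `features` (tidy, all subjects), `eeg_channel_powers`
#'   (or NULL), and `metadata`.
#' @export
extract_cohort_features <- function(cohort,
                                    eeg_cfg = eeg_config(),
                                    emg_cfg = emg_config(),
                                    cop_include = c("geometric", "velocity",
                                                    "ellipse", "heading",
                                                    "spectral", "entropy"),
                                    keep_channel_powers = TRUE,
                                    progress = FALSE) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  meta <- cohort$metadata
  res <- lapply(seq_len(nrow(meta)), function(i) {
    if (progress) message(sprintf("features: %s (%d/%d)", meta$subject_id[i],
                                  i, nrow(meta)))
    if (!is.null(cohort$recordings)) {
      extract_subject_features(cohort$recordings[[meta$subject_id[i]]],
                               eeg_cfg, emg_cfg, cop_include,
                               keep_channel_powers = keep_channel_powers)
    } else {
      stream_subject_features(meta$subject_id[i], meta$group[i], meta$bp[i],
                              meta$seed[i], cohort$config, eeg_cfg, emg_cfg,
                              cop_include,
                              keep_channel_powers = keep_channel_powers)
    }
  })
  if (keep_channel_powers) {
    list(features = dplyr::bind_rows(lapply(res, `[[`, "features")),
         eeg_channel_powers = dplyr::bind_rows(lapply(res, `[[`, "eeg_channel_powers")),
         metadata = meta)
  } else {
    list(features = dplyr::bind_rows(res), eeg_channel_powers = NULL,
         metadata = meta)
  }
}

#' Electrode-wise statistics for every band and group
#'
#' Runs [electrode_band_test()] for each band within each group, the
#' correction family being the electrode set per band per group.
#'
#' @param channel_powers Per-electrode band powers (from
#'   [extract_cohort_features()]).
#' @param metadata Cohort metadata.
#' @param bands Bands to test.
#' @param alpha Significance level.
#' @return Tibble with `group` prepended to the [electrode_band_test()]
#'   columns.
#' @export
cohort_electrode_stats <- function(channel_powers, metadata,
                                   bands = c("delta", "theta", "alpha",
                                             "beta", "low_gamma"),
                                   alpha = 0.05) {
  cp <- dplyr::inner_join(channel_powers,
                          metadata[, c("subject_id", "group")],
                          by = "subject_id")
  purrr::map_dfr(unique(cp$group), function(g) {
    purrr::map_dfr(bands, function(b) {
      dplyr::mutate(
        electrode_band_test(dplyr::filter(cp, .data$group == g), b, alpha),
        group = g, .before = 1)
    })
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End to end: generate (or reuse) the cohort, extract every modality's
#' features, run the PRE-vs-POST statistical battery per group and the
#' electrode-wise EEG maps, assemble the 51-column biosignal table and the
#' SCAT5 items, and evaluate the five classifiers on the three feature
#' selections (9 principal components, 22 SCAT5 items, 31 combined).
#'
#' @param config A [cohort_config()].
#' @param k,seeds Cross-validation folds and seeds.
#' @param models Classifier subset.
#' @param pca_before_cv Apply PCA to the full table before cross-validation
#'   (the original workflow ordering) instead of refitting it inside each
#'   training fold (the default, which avoids test-fold leakage).
#' @param cop_include Stabilogram feature groups to extract.
#' @param progress Print progress lines.
#' @return List of class `swaylab_pipeline`: `metadata`, `features` (tidy),
#'   `biosig` (wide 51-column table), `battery` (PRE-vs-POST tests),
#'   `electrode_stats`, `metrics` (selection x model), and `config`.
#' @export
run_full_pipeline <- function(config = cohort_config(), k = 10, seeds = 1:10,
                              models = c("rf", "svm", "adab", "mlp", "gb"),
                              pca_before_cv = FALSE,
                              cop_include = c("geometric", "velocity",
                                              "ellipse", "heading",
                                              "spectral", "entropy"),
                              progress = FALSE) {
  cohort <- generate_cohort(config, keep_recordings = FALSE)
  ext <- extract_cohort_features(cohort, cop_include = cop_include,
                                 progress = progress)
  meta <- ext$metadata
  battery <- pre_post_battery(
    dplyr::inner_join(ext$features, meta[, c("subject_id", "group")],
                      by = "subject_id")
  )
  estats <- cohort_electrode_stats(ext$eeg_channel_powers, meta)
  biosig <- assemble_features(ext$features, meta)
  sc5 <- scat5_table(meta)
  labels <- meta$group[match(biosig$subject_id, meta$subject_id)]
  bio_cols <- biovr_feature_columns()
  metrics <- purrr::map_dfr(c("pca9", "scat5", "combined"), function(sel) {
    if (progress) message("classifiers: ", sel)
    m <- if (sel == "scat5") {
      evaluate_classifiers(build_selection(biosig, sc5, "scat5"), labels,
                           k = k, seeds = seeds, models = models)
    } else if (pca_before_cv) {
      evaluate_classifiers(build_selection(biosig, sc5, sel), labels,
                           k = k, seeds = seeds, models = models)
    } else {
      feats <- if (sel == "pca9") biosig else
        dplyr::inner_join(biosig, sc5, by = "subject_id")
      evaluate_classifiers(feats, labels, k = k, seeds = seeds,
                           models = models, pca_cols = bio_cols)
    }
    dplyr::mutate(m, selection = sel, .before = 1)
  })
  structure(list(metadata = meta, features = ext$features, biosig = biosig,
                 battery = battery, electrode_stats = estats,
                 metrics = metrics, config = config,
                 pca_before_cv = pca_before_cv),
            class = "swaylab_pipeline")
}

#' @export
print.swaylab_pipeline <- function(x, ...) {
  cat(sprintf("<swaylab_pipeline> %d subjects, %d features, %d test rows, %d metric rows\n",
              nrow(x$metadata), ncol(x$biosig) - 2, nrow(x$battery),
              nrow(x$metrics)))
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  cat(sprintf("  best accuracy: %.1f%% (%s, %s selection)\n",
              best$accuracy, best$model, best$selection))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' One directory per subject with `cop.csv` (time_s, ap_cm, ml_cm),
#' `eeg.csv` (time_s + 64 electrode columns), `emg.csv` (time_s + 6 muscle
#' columns), `hr.csv` (time_s, bpm), and `meta.json` (group, SCAT5 items,
#' flags, seed). Times are seconds from baseline start.
#'
#' @param cohort A `cohort_bundle` with recordings, or one will be generated
#'   per subject from the metadata.
#' @param dir Output directory.
#' @param modalities Subset of modalities to write (the full EEG CSV of one
#'   subject is ~300 MB of text; restrict when only part is needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir,
                         modalities = c("cop", "eeg", "emg", "hr")) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_cohort requires the jsonlite package", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  for (i in seq_len(nrow(meta))) {
    rec <- if (!is.null(cohort$recordings)) cohort$recordings[[meta$subject_id[i]]]
    else generate_recording(meta$subject_id[i], meta$group[i], meta$bp[i],
                            cohort$config, meta$seed[i])
    sdir <- file.path(dir, meta$subject_id[i])
    dir.create(sdir, showWarnings = FALSE)
    t_of <- function(n, fs) (seq_len(n) - 1) / fs
    if ("cop" %in% modalities)
      utils::write.csv(
        data.frame(time_s = t_of(length(rec$cop_ap$samples), rec$cop_ap$fs),
                   ap_cm = rec$cop_ap$samples, ml_cm = rec$cop_ml$samples),
        file.path(sdir, "cop.csv"), row.names = FALSE)
    if ("eeg" %in% modalities)
      utils::write.csv(
        cbind(data.frame(time_s = t_of(nrow(rec$eeg$samples), rec$eeg$fs)),
              as.data.frame(rec$eeg$samples)),
        file.path(sdir, "eeg.csv"), row.names = FALSE)
    if ("emg" %in% modalities)
      utils::write.csv(
        cbind(data.frame(time_s = t_of(nrow(rec$emg$samples), rec$emg$fs)),
              as.data.frame(rec$emg$samples)),
        file.path(sdir, "emg.csv"), row.names = FALSE)
    if ("hr" %in% modalities)
      utils::write.csv(
        data.frame(time_s = t_of(length(rec$hr$samples), rec$hr$fs),
                   bpm = rec$hr$samples),
        file.path(sdir, "hr.csv"), row.names = FALSE)
    items <- as.integer(meta[i, sprintf("scat5_%02d", 1:22)])
    jsonlite::write_json(
      list(subject_id = meta$subject_id[i], group = meta$group[i],
           bp = meta$bp[i], seed = meta$seed[i], scat5 = items,
           symptom_flags = items > 0),
      file.path(sdir, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
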
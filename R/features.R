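#' SCAT5 severity score
#'
#' Sum of the 22 item scores (each 0..6), range 0--132.
#'
#' @param items Integer vector of 22 item scores.
#' @return Integer severity.
#' @export
scat5_severity <- function(items) {
  if (length(items) != 22) stop("SCAT5 has exactly 22 items", call. = FALSE)
  if (any(items < 0 | items > 6 | items != round(items)))
    stop("SCAT5 items must be integers in 0..6", call. = FALSE)
  as.integer(sum(items))
}

#' Extract all per-subject features from a recording
#'
#' Runs every modality pipeline on one subject: CoP stabilogram battery on
#' PRE and POST, electrode-averaged EEG relative band powers on PRE and POST,
#' per-muscle EMG area and spectral descriptors on PRE and POST, and the
#' heart-rate means for the five non-baseline phases. Feature names are
#' prefixed by modality (`cop_`, `eeg_`, `emg_`, `hr_`).
#'
#' @param recording A `multimodal_recording`.
#' @param eeg_cfg,emg_cfg Module configurations.
#' @param cop_include Stabilogram feature groups to compute (see
#'   [cop_features()]).
#' @param keep_channel_powers Also return the per-electrode band powers
#'   (needed for electrode-wise statistics).
#' @return A tibble `subject_id`, `modality`, `feature`, `phase`, `value`;
#'   with `keep_channel_powers = TRUE`, a list with `features` and
#'   `eeg_channel_powers`.
#' @export
extract_subject_features <- function(recording,
                                     eeg_cfg = eeg_config(),
                                     emg_cfg = emg_config(),
                                     cop_include = c("geometric", "velocity",
                                                     "ellipse", "heading",
                                                     "spectral", "entropy"),
                                     keep_channel_powers = FALSE) {
  stopifnot(inherits(recording, "multimodal_recording"))
  tl <- recording$timeline
  cop <- purrr::map_dfr(c("pre", "post"), function(ph) {
    ap <- extract_phase(recording$cop_ap, tl, ph)
    ml <- extract_phase(recording$cop_ml, tl, ph)
    stab <- make_stabilogram(ap$samples, ml$samples, ap$fs)
    dplyr::mutate(cop_features(stab, include = cop_include),
                  modality = "cop", phase = ph,
                  feature = paste0("cop_", .data$feature))
  })
  chan_powers <- purrr::map_dfr(c("pre", "post"), function(ph) {
    eeg_band_powers(recording, ph, eeg_cfg)
  })
  eeg <- chan_powers |>
    dplyr::group_by(.data$band, .data$phase) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::transmute(modality = "eeg", feature = paste0("eeg_", .data$band),
                     phase = .data$phase, value = .data$value)
  emg <- purrr::map_dfr(c("pre", "post"), function(ph) {
    emg_phase_features(recording, ph, emg_cfg)
  }) |>
    dplyr::transmute(modality = "emg",
                     feature = paste0("emg_", .data$feature, "_", .data$muscle),
                     phase = .data$phase, value = .data$value)
  hr <- hr_summary(recording) |>
    dplyr::transmute(modality = "hr", feature = "hr_mean",
                     phase = .data$phase, value = .data$mean_bpm)
  feats <- dplyr::bind_rows(
    cop[, c("modality", "feature", "phase", "value")], eeg, emg, hr
  )
  feats <- dplyr::mutate(feats, subject_id = recording$subject_id,
                         .before = 1)
  if (!keep_channel_powers) return(feats)
  list(features = feats,
       eeg_channel_powers = dplyr::mutate(chan_powers,
                                          subject_id = recording$subject_id,
                                          .before = 1))
}

#' Extract a subject's features without materializing the recording
#'
#' Generates only the segments the feature battery uses — CoP, EEG, and EMG
#' for PRE and POST, heart rate for the five non-baseline phases — using the
#' per-segment seeds of [segment_seed()], so the result is identical to
#' running [extract_subject_features()] on the full
#' [generate_recording()] output while never holding a full recording in
#' memory.
#'
#' @param subject_id,group,bp,seed Subject attributes (one metadata row).
#' @param config A [cohort_config()].
#' @inheritParams extract_subject_features
#' @return As [extract_subject_features()].
#' @export
stream_subject_features <- function(subject_id, group, bp, seed,
                                    config = cohort_config(),
                                    eeg_cfg = eeg_config(),
                                    emg_cfg = emg_config(),
                                    cop_include = c("geometric", "velocity",
                                                    "ellipse", "heading",
                                                    "spectral", "entropy"),
                                    keep_channel_powers = FALSE) {
  cop <- purrr::map_dfr(c("pre", "post"), function(ph) {
    set.seed(segment_seed(seed, "cop", ph))
    xy <- generate_cop(group, ph, config)
    stab <- make_stabilogram(xy$ap$samples, xy$ml$samples, xy$ap$fs)
    dplyr::mutate(cop_features(stab, include = cop_include),
                  modality = "cop", phase = ph,
                  feature = paste0("cop_", .data$feature))
  })
  chan_powers <- purrr::map_dfr(c("pre", "post"), function(ph) {
    set.seed(segment_seed(seed, "eeg", ph))
    seg <- generate_eeg(group, ph, config)
    dplyr::mutate(eeg_segment_band_powers(seg, eeg_cfg), phase = ph,
                  .after = "band")
  })
  eeg <- chan_powers |>
    dplyr::group_by(.data$band, .data$phase) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::transmute(modality = "eeg", feature = paste0("eeg_", .data$band),
                     phase = .data$phase, value = .data$value)
  emg <- purrr::map_dfr(c("pre", "post"), function(ph) {
    set.seed(segment_seed(seed, "emg", ph))
    seg <- generate_emg(group, ph, config, bp = bp)
    dplyr::mutate(emg_segment_features(seg, emg_cfg), phase = ph)
  }) |>
    dplyr::transmute(modality = "emg",
                     feature = paste0("emg_", .data$feature, "_", .data$muscle),
                     phase = .data$phase, value = .data$value)
  hr <- purrr::map_dfr(c("pre", "p25", "p50", "p75", "post"), function(ph) {
    set.seed(segment_seed(seed, "hr", ph))
    seg <- generate_hr(group, ph, config)
    tibble::tibble(modality = "hr", feature = "hr_mean", phase = ph,
                   value = mean(seg$samples))
  })
  feats <- dplyr::bind_rows(
    cop[, c("modality", "feature", "phase", "value")], eeg, emg, hr
  )
  feats <- dplyr::mutate(feats, subject_id = subject_id, .before = 1)
  if (!keep_channel_powers) return(feats)
  list(features = feats,
       eeg_channel_powers = dplyr::mutate(chan_powers, subject_id = subject_id,
                                          .before = 1))
}

# Table layout of the biosignal feature block: 51 columns.
biovr_feature_columns <- function() {
  cop6 <- c("cop_TOTEX", "cop_MDIST_AP", "cop_MVELO", "cop_ELLIPSE_MAIN_AXIS",
            "cop_SD_AP", "cop_POSTERO_MAGNITUDE")
  c(paste0("hr_mean_", c("pre", "p25", "p50", "p75", "post")),
    paste0(rep(paste0("emg_area_", emg_muscles), each = 2), "_", c("pre", "post")),
    paste0(rep(paste0("emg_median_frequency_", emg_muscles), each = 2), "_",
           c("pre", "post")),
    paste0(rep(paste0("eeg_", c("delta", "theta", "alpha", "beta", "low_gamma")),
               each = 2), "_", c("pre", "post")),
    paste0(rep(cop6, each = 2), "_", c("pre", "post")))
}

#' Assemble the 51-column biosignal feature table
#'
#' One row per subject, 51 named columns: the 5 heart-rate phase means, 12
#' EMG areas and 12 EMG median frequencies (6 muscles x PRE/POST), 10 EEG
#' relative band powers (5 bands x PRE/POST), and the 6 most discriminative
#' CoP features x PRE/POST (total excursion, AP mean distance, mean velocity,
#' ellipse main axis, AP standard deviation, posterior extreme magnitude).
#' Missing (undefined) values are imputed by the group median, with the
#' imputation count attached as an attribute.
#'
#' @param features Tidy per-subject feature table from
#'   [extract_subject_features()] (stacked over subjects).
#' @param metadata Cohort metadata (for group labels; used for imputation and
#'   carried into the result).
#' @return Tibble: `subject_id`, `group`, then the 51 feature columns.
#' @export
assemble_features <- function(features, metadata) {
  cols <- biovr_feature_columns()
  wide <- features |>
    dplyr::mutate(column = paste0(.data$feature, "_", .data$phase)) |>
    dplyr::filter(.data$column %in% cols) |>
    dplyr::select("subject_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  missing_cols <- setdiff(cols, names(wide))
  if (length(missing_cols) > 0)
    stop("feature table is missing columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  out <- dplyr::inner_join(metadata[, c("subject_id", "group")], wide,
                           by = "subject_id")
  if (nrow(out) < nrow(metadata)) {
    lost <- setdiff(metadata$subject_id, out$subject_id)
    stop("no features for subject(s): ", paste(lost, collapse = ", "),
         call. = FALSE)
  }
  out <- out[, c("subject_id", "group", cols)]
  # a whole modality absent for a subject is a pipeline failure, not a value
  # to impute
  for (pref in c("hr_", "emg_", "eeg_", "cop_")) {
    pc <- cols[startsWith(cols, pref)]
    all_na <- rowSums(!is.na(as.matrix(out[, pc]))) == 0
    if (any(all_na))
      stop(sprintf("subject(s) %s missing all '%s' features",
                   paste(out$subject_id[all_na], collapse = ", "), pref),
           call. = FALSE)
  }
  n_imputed <- 0L
  for (cl in cols) {
    nas <- is.na(out[[cl]])
    if (any(nas)) {
      n_imputed <- n_imputed + sum(nas)
      med <- stats::ave(out[[cl]], out$group,
                        FUN = function(v) stats::median(v, na.rm = TRUE))
      out[[cl]][nas] <- med[nas]
    }
  }
  attr(out, "n_imputed") <- n_imputed
  out
}

#' SCAT5 item table
#'
#' The 22 raw item columns keyed by subject, as used for classification.
#'
#' @param metadata Cohort metadata.
#' @return Tibble: `subject_id` plus `scat5_01` .. `scat5_22`.
#' @export
scat5_table <- function(metadata) {
  metadata[, c("subject_id", sprintf("scat5_%02d", 1:22))]
}
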
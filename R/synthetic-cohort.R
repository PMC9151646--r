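# 64-channel 10-10 montage (ANT waveguard layout, mastoids M1/M2 included).
eeg_montage_64 <- c(
  "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz",
  "C4", "T8", "M2", "CP5", "CP1", "CP2", "CP6", "P7",
  "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
  "FC3", "FCz", "FC4", "C5", "C1", "C2", "C6", "CP3",
  "CPz", "CP4", "P5", "P1", "P2", "P6", "PO5", "PO3",
  "PO4", "PO6", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8"
)

emg_muscles <- c("TA_L", "TA_R", "GL_L", "GL_R", "S_L", "S_R")

#' Synthetic cohort configuration
#'
#' All knobs of the synthetic study: group sizes, the planted group effects in
#' each modality, and the master seed. Defaults emulate the study conditions:
#' 26 concussion / 28 non-concussion athletes, SCAT5 severity means 36.47 vs
#' 3.71, a balance-problem (BP) subgroup of 14 of the 26 concussed subjects,
#' larger and smoother POST sway in the concussion group, a POST theta/delta
#' amplitude gain on ten frontal electrodes for concussed subjects, a POST
#' soleus power gain for concussed subjects, and a right-soleus
#' median-frequency shift for the BP subgroup.
#'
#' @param n_concussion,n_non_concussion Group sizes.
#' @param master_seed Integer master seed; per-subject seeds are derived from
#'   it deterministically.
#' @param scat5_target_means Named vector (`concussion`, `non_concussion`) of
#'   expected SCAT5 severity sums (0--132).
#' @param bp_n Number of concussion subjects carrying the balance-problem
#'   flag (and the associated EMG effect); default 14/26 of the concussion
#'   group, rounded.
#' @param balance_item SCAT5 item index encoding balance problems.
#' @param eeg_fs EEG sampling rate; data are generated at 1024 Hz by default
#'   (the rate the preprocessing resamples to); set 4096 to exercise the
#'   resampling step.
#' @param cop,eeg,emg,hr Optional lists overriding individual modality
#'   parameters (see the returned object for the full set).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_concussion = 26, n_non_concussion = 28,
                          master_seed = 1,
                          scat5_target_means = c(concussion = 36.47,
                                                 non_concussion = 3.71),
                          bp_n = NULL, balance_item = 5, eeg_fs = 1024,
                          cop = list(), eeg = list(), emg = list(), hr = list()) {
  if (is.null(bp_n)) bp_n <- round(n_concussion * 14 / 26)
  stopifnot(n_concussion >= 1, n_non_concussion >= 1,
            bp_n >= 0, bp_n <= n_concussion,
            all(scat5_target_means >= 0), all(scat5_target_means <= 132))
  cop_def <- list(
    fs = 90,
    alpha_pre = 1.2,
    # POST sway of concussed subjects is larger and smoother (steeper
    # spectrum); the amplitude gain is set so path-length features still rise
    # clearly despite the reduced high-frequency content
    alpha_post = c(concussion = 1.4, non_concussion = 1.2),
    sway_scale = list(   # RMS sway amplitude (cm) per phase
      concussion     = c(baseline = 0.35, pre = 0.40, p25 = 0.80, p50 = 0.80,
                         p75 = 0.80, post = 0.75),
      non_concussion = c(baseline = 0.35, pre = 0.40, p25 = 0.80, p50 = 0.80,
                         p75 = 0.80, post = 0.45)
    ),
    osc_freq = 0.08,     # slow postural drift component, below the power-law fit band
    osc_amp = 0.05       # cm
  )
  eeg_def <- list(
    fs = eeg_fs, n_channels = 64, labels = eeg_montage_64,
    band_amplitudes = c(delta = 3, theta = 2, alpha = 2, beta = 1,
                        low_gamma = 0.5),   # uV / sqrt(Hz)
    theta_delta_post_gain = 1.3,            # amplitude multiplier, concussion POST
    affected_channels = c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4",
                          "AF3", "AF4", "FC1", "FC2"),
    amp_jitter_sd = 0.05                    # lognormal per-phase band jitter
  )
  emg_def <- list(
    fs = 1600,
    center_freq = c(TA_L = 120, TA_R = 120, GL_L = 110, GL_R = 110,
                    S_L = 100, S_R = 100),  # Hz
    bandwidth = 80,                          # Hz (Gaussian band shape)
    noise_amp = 1,                           # arbitrary EMG units
    soleus_post_power_gain = 1.5,            # power multiplier, concussion POST
    bp_right_soleus_mdf_shift = 15,          # Hz, BP subgroup, POST
    amp_jitter_sd = 0.05
  )
  hr_def <- list(
    baseline_bpm = 75,
    phase_offsets = c(baseline = 0, pre = 5, p25 = -2, p50 = -2, p75 = -2,
                      post = 8),
    noise_sd = c(concussion = 3, non_concussion = 1.5)
  )
  cfg <- list(
    n_concussion = n_concussion, n_non_concussion = n_non_concussion,
    master_seed = as.integer(master_seed),
    scat5_target_means = scat5_target_means,
    bp_n = bp_n, balance_item = balance_item,
    timeline = default_timeline(),
    cop = utils::modifyList(cop_def, cop),
    eeg = utils::modifyList(eeg_def, eeg),
    emg = utils::modifyList(emg_def, emg),
    hr = utils::modifyList(hr_def, hr)
  )
  structure(cfg, class = "cohort_config")
}

#' Colored (power-law) noise
#'
#' Gaussian noise with power spectral density proportional to `1/f^alpha`,
#' synthesized by frequency-domain shaping of white noise (amplitude
#' proportional to `f^(-alpha/2)`, DC removed), normalized to unit SD. This
#' gives direct control over the spectral exponent the stabilogram analysis
#' recovers.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (>= 0); `alpha = 0` is white noise.
#' @return Numeric series of length `n` with `sd == 1`.
#' @export
colored_noise <- function(n, alpha) {
  stopifnot(n >= 4, alpha >= 0)
  w <- stats::rnorm(n)
  if (alpha == 0) return((w - mean(w)) / stats::sd(w))
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)              # symmetric frequency index
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Band-shaped multichannel Gaussian noise, synthesized in the frequency
# domain: complex Gaussian coefficients are drawn only at bins where the
# amplitude profile is nonzero (distributionally identical to shaping white
# noise, but far cheaper for narrow profiles), mirrored Hermitian, and
# inverse-transformed in one call for all channels.
# Two real channels per complex column: with independent circularly symmetric
# coefficients at positive and negative bins (no Hermitian symmetry), the real
# and imaginary parts of the inverse transform are independent real Gaussian
# processes with the target spectrum. Coefficients are drawn only where the
# profile is nonzero; the synthesis itself is compiled.
shaped_noise_matrix <- function(n, fs, n_channels, profile_fun) {
  nh <- floor((n - 1) / 2)           # strictly positive, non-Nyquist bins
  f_pos <- (1:nh) * fs / n
  amp <- profile_fun(f_pos)
  shaped_noise_cpp(as.integer(n), as.integer(n_channels), amp)
}

phase_duration <- function(config, phase) {
  tl <- config$timeline
  row <- tl[tl$phase == phase, ]
  if (nrow(row) != 1) stop(sprintf("unknown phase '%s'", phase), call. = FALSE)
  row$end_s - row$start_s
}

#' Generate SCAT5 item scores
#'
#' Draws 22 item scores, each in 0..6, from independent binomial(6, p)
#' distributions with `p` calibrated so the expected severity sum equals the
#' configured group target. Symptom flags downstream are defined as
#' `item > 0`.
#'
#' @param group `"concussion"` or `"non_concussion"`.
#' @param config A [cohort_config()].
#' @return Integer vector of 22 item scores.
#' @export
generate_scat5 <- function(group, config = cohort_config()) {
  group <- match.arg(group, c("concussion", "non_concussion"))
  target <- config$scat5_target_means[[group]]
  p <- target / (22 * 6)
  stats::rbinom(22, size = 6, prob = p)
}

#' Generate a CoP sway segment
#'
#' Power-law (colored) noise sway plus a slow oscillatory drift, scaled to
#' the configured per-group, per-phase RMS amplitude. The spectral exponent is
#' `alpha_pre` in all phases except POST, where it is group-dependent
#' (concussed subjects sway with a steeper, smoother spectrum after the
#' perturbation).
#'
#' @param group Group label.
#' @param phase Protocol phase name.
#' @param config A [cohort_config()].
#' @return List with `ap` and `ml` [channel_series()] in cm at the CoP rate.
#' @export
generate_cop <- function(group, phase, config = cohort_config()) {
  group <- match.arg(group, c("concussion", "non_concussion"))
  p <- config$cop
  dur <- phase_duration(config, phase)
  n <- round(dur * p$fs)
  alpha <- if (phase == "post") p$alpha_post[[group]] else p$alpha_pre
  scale <- p$sway_scale[[group]][[phase]]
  t <- (0:(n - 1)) / p$fs
  gen_axis <- function(label) {
    x <- scale * colored_noise(n, alpha) +
      p$osc_amp * sin(2 * pi * p$osc_freq * t + stats::runif(1, 0, 2 * pi))
    channel_series(x, p$fs, label, "cm")
  }
  list(ap = gen_axis("cop_ap"), ml = gen_axis("cop_ml"))
}

eeg_band_edges <- c(delta = 1, theta = 4, alpha = 8, beta = 13,
                    low_gamma = 30, upper = 45)

eeg_profile_fun <- function(amps) {
  force(amps)
  function(f) {
    a <- numeric(length(f))
    a[f >= 1 & f < 4]   <- amps[["delta"]]
    a[f >= 4 & f < 8]   <- amps[["theta"]]
    a[f >= 8 & f < 13]  <- amps[["alpha"]]
    a[f >= 13 & f < 30] <- amps[["beta"]]
    a[f >= 30 & f <= 45] <- amps[["low_gamma"]]
    a
  }
}

#' Generate an EEG segment
#'
#' Each channel is band-limited Gaussian noise whose amplitude spectrum is
#' piecewise-constant over the five canonical bands (delta 1--4, theta 4--8,
#' alpha 8--13, beta 13--30, low gamma 30--45 Hz). Band amplitudes receive a
#' small lognormal per-phase jitter (shared across channels) so POST-minus-PRE
#' relative-power differences carry realistic between-phase variability. For
#' concussed subjects in POST, theta and delta amplitudes on the configured
#' affected channels are multiplied by the planted gain.
#'
#' @inheritParams generate_cop
#' @return A [signal_matrix()] with 64 channels.
#' @export
generate_eeg <- function(group, phase, config = cohort_config()) {
  group <- match.arg(group, c("concussion", "non_concussion"))
  e <- config$eeg
  dur <- phase_duration(config, phase)
  n <- round(dur * e$fs)
  amps <- e$band_amplitudes *
    exp(stats::rnorm(length(e$band_amplitudes), 0, e$amp_jitter_sd))
  idx_aff <- integer(0)
  if (group == "concussion" && phase == "post" && e$theta_delta_post_gain != 1)
    idx_aff <- which(e$labels %in% e$affected_channels)
  X <- matrix(0, n, e$n_channels)
  if (length(idx_aff) < e$n_channels) {
    plain <- setdiff(seq_len(e$n_channels), idx_aff)
    X[, plain] <- shaped_noise_matrix(n, e$fs, length(plain),
                                      eeg_profile_fun(amps))
  }
  if (length(idx_aff) > 0) {
    amps2 <- amps
    amps2[["theta"]] <- amps[["theta"]] * e$theta_delta_post_gain
    amps2[["delta"]] <- amps[["delta"]] * e$theta_delta_post_gain
    X[, idx_aff] <- shaped_noise_matrix(n, e$fs, length(idx_aff),
                                        eeg_profile_fun(amps2))
  }
  colnames(X) <- e$labels
  signal_matrix(X, e$fs, e$labels, "uV")
}

#' Generate an EMG segment
#'
#' Per-muscle Gaussian noise with a Gaussian-shaped amplitude spectrum centered
#' at the muscle's configured frequency, truncated to 40--500 Hz. Concussed
#' subjects get the configured soleus power gain in POST; subjects flagged with
#' balance problems additionally have their right-soleus spectrum center
#' shifted by the configured amount in POST (a median-frequency shift).
#'
#' @inheritParams generate_cop
#' @param bp Logical: does the subject carry the balance-problem flag?
#' @return A [signal_matrix()] with the six muscle channels.
#' @export
generate_emg <- function(group, phase, config = cohort_config(), bp = FALSE) {
  group <- match.arg(group, c("concussion", "non_concussion"))
  m <- config$emg
  dur <- phase_duration(config, phase)
  n <- round(dur * m$fs)
  sigma <- m$bandwidth / 2
  X <- matrix(0, n, length(emg_muscles))
  for (j in seq_along(emg_muscles)) {
    mus <- emg_muscles[j]
    fc <- m$center_freq[[mus]]
    amp <- m$noise_amp * exp(stats::rnorm(1, 0, m$amp_jitter_sd))
    if (group == "concussion" && phase == "post" && mus %in% c("S_L", "S_R"))
      amp <- amp * sqrt(m$soleus_post_power_gain)
    if (bp && phase == "post" && mus == "S_R")
      fc <- fc + m$bp_right_soleus_mdf_shift
    X[, j] <- shaped_noise_matrix(n, m$fs, 1, function(f) {
      amp * exp(-(f - fc)^2 / (2 * sigma^2)) * (f >= 40 & f <= 500)
    })
  }
  signal_matrix(X, m$fs, emg_muscles, "a.u.")
}

#' Generate a heart-rate segment
#'
#' Per-second bpm equal to the subject baseline plus a phase offset (heart
#' rate rises in the hands-off quiet-stance phases and drops while holding the
#' bars) plus Gaussian noise with a group-dependent SD, clamped to stay
#' physiologically positive.
#'
#' @inheritParams generate_cop
#' @return A [channel_series()] at 1 Hz in bpm.
#' @export
generate_hr <- function(group, phase, config = cohort_config()) {
  group <- match.arg(group, c("concussion", "non_concussion"))
  h <- config$hr
  dur <- phase_duration(config, phase)
  n <- round(dur * 1)
  bpm <- h$baseline_bpm + h$phase_offsets[[phase]] +
    stats::rnorm(n, 0, h$noise_sd[[group]])
  channel_series(pmax(bpm, 30), 1, "hr", "bpm")
}

concat_series <- function(parts) {
  channel_series(unlist(lapply(parts, function(p) p$samples)),
                 parts[[1]]$fs, parts[[1]]$label, parts[[1]]$units)
}

concat_matrix <- function(parts) {
  signal_matrix(do.call(rbind, lapply(parts, function(p) p$samples)),
                parts[[1]]$fs, parts[[1]]$labels, parts[[1]]$units)
}

#' Per-segment RNG seed
#'
#' Every (modality, phase) segment of a subject draws from its own seed
#' derived from the subject seed, so any subset of segments regenerates
#' bit-identically to the corresponding slices of the full recording —
#' feature pipelines can stream exactly the segments they need.
#'
#' @param subject_seed The subject's integer seed.
#' @param modality One of `"cop"`, `"eeg"`, `"emg"`, `"hr"`.
#' @param phase Phase name.
#' @return An integer seed.
#' @export
segment_seed <- function(subject_seed, modality, phase) {
  mb <- c(cop = 1, eeg = 2, emg = 3, hr = 4)[[modality]]
  pi_ <- match(phase, c("baseline", "pre", "p25", "p50", "p75", "post"))
  if (is.na(pi_)) stop(sprintf("unknown phase '%s'", phase), call. = FALSE)
  as.integer((as.numeric(subject_seed) + mb * 1009 + pi_ * 131071) %%
               .Machine$integer.max)
}

#' Generate one subject's full multimodal recording
#'
#' Assembles the 320-s recording segment by segment following the protocol
#' timeline; each (modality, phase) segment draws from its own seed derived
#' via [segment_seed()] from the subject seed.
#'
#' @param subject_id Identifier string.
#' @param group Group label.
#' @param bp Balance-problem flag.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this subject's stream.
#' @return A list of class `multimodal_recording` with elements `subject_id`,
#'   `eeg`, `emg` ([signal_matrix()]), `cop_ap`, `cop_ml`, `hr`
#'   ([channel_series()]), and `timeline`.
#' @export
generate_recording <- function(subject_id, group, bp = FALSE,
                               config = cohort_config(), seed = 1L) {
  phases <- config$timeline$phase
  seeded <- function(modality, ph, expr) {
    set.seed(segment_seed(seed, modality, ph))
    expr(ph)
  }
  cop <- lapply(phases, function(ph) seeded("cop", ph, function(p) generate_cop(group, p, config)))
  eeg <- lapply(phases, function(ph) seeded("eeg", ph, function(p) generate_eeg(group, p, config)))
  emg <- lapply(phases, function(ph) seeded("emg", ph, function(p) generate_emg(group, p, config, bp = bp)))
  hr  <- lapply(phases, function(ph) seeded("hr", ph, function(p) generate_hr(group, p, config)))
  structure(
    list(subject_id = subject_id,
         eeg = concat_matrix(eeg),
         emg = concat_matrix(emg),
         cop_ap = concat_series(lapply(cop, `[[`, "ap")),
         cop_ml = concat_series(lapply(cop, `[[`, "ml")),
         hr = concat_series(hr),
         timeline = config$timeline),
    class = "multimodal_recording"
  )
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf("<multimodal_recording> %s: EEG %dch @%g Hz, EMG %dch @%g Hz, CoP @%g Hz, HR @%g Hz\n",
              x$subject_id, ncol(x$eeg$samples), x$eeg$fs,
              ncol(x$emg$samples), x$emg$fs, x$cop_ap$fs, x$hr$fs))
  invisible(x)
}

subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + i * 7919) %% .Machine$integer.max)
}

#' Cohort metadata (groups, seeds, SCAT5)
#'
#' Lays out the cohort deterministically from the master seed: subject ids,
#' group labels, balance-problem flags (the first `bp_n` concussed subjects),
#' per-subject seeds, and SCAT5 item scores. The balance-problem item score is
#' forced consistent with the flag (positive iff flagged) for concussed
#' subjects.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `subject_id`, `group`, `bp`, `seed`, and
#'   `scat5_01` .. `scat5_22`.
#' @export
generate_metadata <- function(config = cohort_config()) {
  n <- config$n_concussion + config$n_non_concussion
  meta <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("concussion", "non_concussion"),
                c(config$n_concussion, config$n_non_concussion)),
    bp = c(seq_len(config$n_concussion) <= config$bp_n,
           rep(FALSE, config$n_non_concussion)),
    seed = vapply(seq_len(n), subject_seed,
                  master_seed = config$master_seed, integer(1))
  )
  items <- matrix(NA_integer_, n, 22,
                  dimnames = list(NULL, sprintf("scat5_%02d", 1:22)))
  for (i in seq_len(n)) {
    set.seed(meta$seed[i])
    sc <- generate_scat5(meta$group[i], config)
    if (meta$group[i] == "concussion") {
      bi <- config$balance_item
      if (meta$bp[i] && sc[bi] == 0) sc[bi] <- 1L
      if (!meta$bp[i]) sc[bi] <- 0L
    }
    items[i, ] <- sc
  }
  dplyr::bind_cols(meta, tibble::as_tibble(items))
}

#' Generate a full synthetic cohort
#'
#' Metadata plus (optionally) the full multimodal recordings for every
#' subject. Regeneration with the same configuration is bit-identical; each
#' subject draws from an independent seed derived from the master seed. With
#' the default EEG rate a full recording is large (about 170 MB), so pipelines
#' that only need features can set `keep_recordings = FALSE` and regenerate
#' recordings one subject at a time from the metadata (see
#' [run_full_pipeline()]).
#'
#' @param config A [cohort_config()].
#' @param keep_recordings Materialize recordings in the returned bundle?
#' @return List of class `cohort_bundle` with `metadata`, `recordings` (named
#'   list or NULL), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), keep_recordings = TRUE) {
  meta <- generate_metadata(config)
  recs <- NULL
  if (keep_recordings) {
    recs <- lapply(seq_len(nrow(meta)), function(i) {
      generate_recording(meta$subject_id[i], meta$group[i], meta$bp[i],
                         config, meta$seed[i])
    })
    names(recs) <- meta$subject_id
  }
  structure(list(metadata = meta, recordings = recs, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d subjects (%d concussion / %d non-concussion)%s\n",
              nrow(x$metadata), sum(x$metadata$group == "concussion"),
              sum(x$metadata$group == "non_concussion"),
              if (is.null(x$recordings)) ", metadata only" else ", recordings attached"))
  invisible(x)
}
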
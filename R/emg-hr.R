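#' EMG analysis configuration
#'
#' A 50th-order (51-tap) linear-phase FIR band-pass at 40--500 Hz applied to
#' the raw 1600 Hz EMG, rectified-area integration over the full 40-s phase,
#' and spectral descriptors computed on the central 30-s window of each phase
#' (5 s dropped at each end to exclude phase-transition effects).
#'
#' @param fir_order FIR order (taps = order + 1).
#' @param band Pass-band corner frequencies, Hz.
#' @param central_window_s Central-window length for spectral analysis, s.
#' @return List of class `emg_config`.
#' @export
emg_config <- function(fir_order = 50, band = c(40, 500), central_window_s = 30) {
  structure(list(fir_order = fir_order, band = band,
                 central_window_s = central_window_s),
            class = "emg_config")
}

#' FIR band-pass filter for EMG
#'
#' Windowed-sinc (Hamming) linear-phase FIR of the configured order, applied
#' causally (forward only). The constant group delay is irrelevant to area and
#' spectral features.
#'
#' @param x Numeric vector or matrix (one column per channel).
#' @param fs Sampling rate, Hz.
#' @param config An [emg_config()].
#' @return Filtered signal, same shape as the input.
#' @export
fir_bandpass <- function(x, fs, config = emg_config()) {
  X <- as.matrix(x)
  if (nrow(X) <= config$fir_order)
    stop("signal shorter than the filter", call. = FALSE)
  h <- signal::fir1(config$fir_order, config$band / (fs / 2), type = "pass")
  Y <- stats::filter(X, h, method = "convolution", sides = 1)
  Y[seq_len(config$fir_order), ] <- 0   # start-up transient (no past samples)
  Y <- unclass(Y)
  if (is.vector(x)) as.numeric(Y) else Y
}

#' Rectified-signal area
#'
#' Trapezoidal integral of the rectified signal over time, the standard
#' measure of cumulative muscle activation (signal-units x seconds).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @return The area.
#' @export
rectified_area <- function(x, fs) {
  stopifnot(length(x) >= 1)
  if (length(x) == 1) return(0)
  a <- abs(x)
  sum((a[-1] + a[-length(a)]) / 2) / fs
}

#' Central time window
#'
#' The centered slice of the given duration; for a 40-s phase and a 30-s
#' window, 5 s are dropped at each end. With an odd number of leftover
#' samples the head keeps one sample fewer than the tail.
#'
#' @param x Numeric vector or matrix.
#' @param fs Sampling rate, Hz.
#' @param window_s Window duration, s.
#' @return The sliced signal, same type as the input.
#' @export
central_window <- function(x, fs, window_s = 30) {
  X <- as.matrix(x)
  n <- nrow(X)
  nw <- round(window_s * fs)
  if (n < nw) stop("signal shorter than the central window", call. = FALSE)
  head_drop <- (n - nw) %/% 2
  Y <- X[(head_drop + 1):(head_drop + nw), , drop = FALSE]
  if (is.vector(x)) as.numeric(Y) else Y
}

#' One-sided FFT power spectrum
#'
#' Magnitude-squared FFT of the mean-removed signal, one-sided, normalized so
#' the spectrum sums to the signal variance (Parseval).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @return List with `freq` (Hz, DC excluded) and `power`.
#' @export
power_spectrum <- function(x, fs) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  X <- stats::fft(x - mean(x))
  nh <- floor(n / 2)
  pw <- 2 * Mod(X[2:(nh + 1)])^2 / n^2
  if (n %% 2 == 0) pw[nh] <- pw[nh] / 2
  list(freq = (1:nh) * fs / n, power = pw)
}

#' EMG spectral descriptors
#'
#' Restricted to the analyzed band (40--500 Hz): total power (the sum of the
#' spectrum, which grows with contraction force), the biased kurtosis
#' (normal = 3 convention) and biased skewness of the vector of spectral
#' power values (descriptors of spectrum shape: a more symmetric,
#' Gaussian-like spectrum lowers both), and the median frequency (the
#' smallest frequency at which cumulative power reaches half the total, the
#' classic fatigue marker).
#'
#' @param freq Frequency vector, Hz.
#' @param power Power spectrum values.
#' @param config An [emg_config()] (for the band limits).
#' @return Tibble with `total_power`, `kurtosis`, `skewness`,
#'   `median_frequency`. An all-zero spectrum returns `total_power = 0` and
#'   `NA` descriptors (median frequency undefined).
#' @export
spectral_descriptors <- function(freq, power, config = emg_config()) {
  sel <- freq >= config$band[1] & freq <= config$band[2]
  if (!any(sel)) stop("no spectral bins inside the analyzed band", call. = FALSE)
  p <- power[sel]; f <- freq[sel]
  tp <- sum(p)
  if (tp <= 0) {
    return(tibble::tibble(total_power = 0, kurtosis = NA_real_,
                          skewness = NA_real_, median_frequency = NA_real_))
  }
  kur <- e1071::kurtosis(p, type = 1) + 3   # biased, normal = 3 convention
  ske <- e1071::skewness(p, type = 1)       # biased
  mdf <- f[which(cumsum(p) >= tp / 2)[1]]
  tibble::tibble(total_power = tp, kurtosis = kur, skewness = ske,
                 median_frequency = mdf)
}

#' Per-muscle EMG features for one phase
#'
#' For each muscle: FIR band-pass over the full phase, then (a) the rectified
#' area over the whole phase and (b) the spectral descriptors on the central
#' 30-s window.
#'
#' @param recording A `multimodal_recording`.
#' @param phase Phase name.
#' @param config An [emg_config()].
#' @return Tibble with `muscle`, `phase`, `feature`, `value` (five features
#'   per muscle: area, total_power, kurtosis, skewness, median_frequency).
#' @export
emg_phase_features <- function(recording, phase, config = emg_config()) {
  seg <- extract_phase(recording$emg, recording$timeline, phase)
  dplyr::mutate(emg_segment_features(seg, config), phase = phase,
                .after = "muscle")
}

#' @rdname emg_phase_features
#' @param segment A [signal_matrix()] EMG segment (one phase, six muscles).
#' @export
emg_segment_features <- function(segment, config = emg_config()) {
  if (!setequal(segment$labels, emg_muscles))
    stop("EMG block must carry exactly the six muscle channels", call. = FALSE)
  filt <- fir_bandpass(segment$samples, segment$fs, config)
  cw <- central_window(filt, segment$fs, config$central_window_s)
  purrr::map_dfr(seq_along(segment$labels), function(j) {
    area <- rectified_area(filt[, j], segment$fs)
    ps <- power_spectrum(cw[, j], segment$fs)
    sd_row <- spectral_descriptors(ps$freq, ps$power, config)
    tibble::tibble(
      muscle = segment$labels[j],
      feature = c("area", names(sd_row)),
      value = c(area, as.numeric(sd_row[1, ]))
    )
  })
}

#' Heart-rate phase summaries
#'
#' Mean and SD of the bpm trace per protocol phase. The five non-baseline
#' phase means are the heart-rate block of the subject feature table.
#'
#' @param recording A `multimodal_recording` (or a [channel_series()] plus
#'   `timeline`).
#' @param phases Phases to summarize.
#' @param timeline Protocol timeline (taken from the recording if present).
#' @return Tibble with `phase`, `mean_bpm`, `sd_bpm`.
#' @export
hr_summary <- function(recording, phases = c("pre", "p25", "p50", "p75", "post"),
                       timeline = NULL) {
  if (inherits(recording, "multimodal_recording")) {
    hr <- recording$hr
    timeline <- recording$timeline
  } else {
    hr <- recording
    if (is.null(timeline)) timeline <- default_timeline()
  }
  purrr::map_dfr(phases, function(ph) {
    seg <- extract_phase(hr, timeline, ph)
    tibble::tibble(phase = ph, mean_bpm = mean(seg$samples),
                   sd_bpm = stats::sd(seg$samples))
  })
}
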
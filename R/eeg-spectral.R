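#' EEG analysis configuration
#'
#' Preprocessing and spectral parameters for the EEG pipeline: trim 5 s from
#' each end of a segment, resample to 1024 Hz, notch at the 50 Hz mains
#' frequency, band-pass 1--45 Hz, then Welch PSD with 2-s Hann windows at 50%
#' overlap, integrated over the five canonical bands (delta 1--4, theta 4--8,
#' alpha 8--13, beta 13--30, low gamma 30--45 Hz).
#'
#' @param resample_to Target rate, Hz.
#' @param trim_s Seconds removed from each end of the segment.
#' @param notch_hz Mains frequency, Hz (`NA` to skip).
#' @param notch_q Notch quality factor.
#' @param bandpass Band-pass corner frequencies, Hz.
#' @param welch_window_s Welch window length, s.
#' @param welch_overlap Welch window overlap fraction.
#' @return List of class `eeg_config`; `$bands` holds the band edges
#'   (half-open intervals, the last closed).
#' @export
eeg_config <- function(resample_to = 1024, trim_s = 5, notch_hz = 50,
                       notch_q = 30, bandpass = c(1, 45),
                       welch_window_s = 2, welch_overlap = 0.5) {
  structure(list(
    resample_to = resample_to, trim_s = trim_s, notch_hz = notch_hz,
    notch_q = notch_q, bandpass = bandpass,
    bands = list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                 beta = c(13, 30), low_gamma = c(30, 45)),
    welch_window_s = welch_window_s, welch_overlap = welch_overlap
  ), class = "eeg_config")
}

# FFT-domain resampling to an integer-sample target length: retains the
# spectral content below the new Nyquist exactly (zero-phase).
fft_resample_matrix <- function(X, fs_in, fs_out) {
  if (fs_in == fs_out) return(X)
  n <- nrow(X)
  n_new <- n * fs_out / fs_in
  if (abs(n_new - round(n_new)) > 1e-9)
    stop("resampling requires an integer output length", call. = FALSE)
  n_new <- as.integer(round(n_new))
  F_in <- stats::mvfft(X)
  F_out <- matrix(0 + 0i, n_new, ncol(X))
  nh <- floor(min(n, n_new) / 2)
  F_out[1:(nh + 1), ] <- F_in[1:(nh + 1), ]
  if (nh >= 1) F_out[(n_new - nh + 1):n_new, ] <- F_in[(n - nh + 1):n, ]
  Re(stats::mvfft(F_out, inverse = TRUE)) / n  # 1/n keeps tone amplitudes
}

# biquad notch (standard audio-EQ design)
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Preprocess an EEG segment
#'
#' In order: trim `trim_s` seconds from each end (guarding the segment
#' transitions), resample to the target rate, zero-phase mains notch, and
#' zero-phase 4th-order Butterworth band-pass. Zero-phase (forward-backward)
#' filtering is used so band-power estimates carry no phase distortion. A
#' 40-s segment comes out as 30 s at 1024 Hz.
#'
#' @param segment A [signal_matrix()] EEG segment.
#' @param config An [eeg_config()].
#' @return A [signal_matrix()] at `config$resample_to` Hz.
#' @export
preprocess_eeg <- function(segment, config = eeg_config()) {
  stopifnot(inherits(segment, "signal_matrix"))
  n <- nrow(segment$samples)
  fs <- segment$fs
  if (n / fs <= 2 * config$trim_s)
    stop("segment shorter than twice the trim duration", call. = FALSE)
  keep <- (floor(config$trim_s * fs) + 1):(n - floor(config$trim_s * fs))
  X <- segment$samples[keep, , drop = FALSE]
  # resample (FFT-domain; exact below the new Nyquist)
  if (fs != config$resample_to) {
    X <- fft_resample_matrix(X, fs, config$resample_to)
    fs <- config$resample_to
  }
  if (!is.na(config$notch_hz)) {
    nc <- notch_coefs(config$notch_hz, fs, config$notch_q)
    X <- iir_filtfilt_mat(nc$b, nc$a, X)
  }
  bw <- signal::butter(4, config$bandpass / (fs / 2), type = "pass")
  X <- iir_filtfilt_mat(bw$b, bw$a, X)
  signal_matrix(X, fs, segment$labels, segment$units)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed, mean-removed segments with
#' configurable overlap, scaled as power / Hz so the integral over frequency
#' approximates the signal variance.
#'
#' @param x Numeric vector, matrix (one column per channel), or
#'   [signal_matrix()].
#' @param fs Sampling rate (ignored when `x` is a `signal_matrix`).
#' @param window_s Window length in seconds.
#' @param overlap Overlap fraction in \[0, 1).
#' @return List with `freq` (Hz, DC excluded) and `psd` (matrix, bins x
#'   channels).
#' @export
welch_psd <- function(x, fs = NULL, window_s = 2, overlap = 0.5) {
  if (inherits(x, "signal_matrix")) { fs <- x$fs; x <- x$samples }
  if (inherits(x, "channel_series")) { fs <- x$fs; x <- x$samples }
  X <- as.matrix(x)
  n <- nrow(X)
  nw <- round(window_s * fs)
  if (n < nw) stop("input shorter than one Welch window", call. = FALSE)
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))  # Hann
  U <- sum(w^2)
  nh <- floor(nw / 2)
  p <- ncol(X)
  nwin <- length(starts)
  # all (window x channel) segments as columns of one matrix -> single FFT
  B <- X[as.vector(outer(seq_len(nw), starts - 1, "+")), , drop = FALSE]
  dim(B) <- c(nw, nwin * p)          # columns: window-major within channel
  B <- (B - rep(colMeans(B), each = nw)) * w
  Fw <- stats::mvfft(B)
  P <- Mod(Fw[2:(nh + 1), , drop = FALSE])^2
  dim(P) <- c(nh, nwin, p)
  acc <- vapply(seq_len(p), function(ch) rowSums(P[, , ch]), numeric(nh))
  psd <- 2 * acc / (nwin * fs * U)
  if (nw %% 2 == 0) psd[nh, ] <- psd[nh, ] / 2
  colnames(psd) <- colnames(X)
  list(freq = (1:nh) * fs / nw, psd = psd)
}

#' Relative band powers
#'
#' Band power is the PSD integrated over each band (half-open bins
#' `[lo, hi)`, the last band closed at 45 Hz); relative power divides by the
#' total over the full analyzed range, so the five values sum to one per
#' channel.
#'
#' @param freq Frequency vector from [welch_psd()].
#' @param psd PSD matrix (bins x channels) or vector.
#' @param bands Named list of band edges (default the five canonical bands).
#' @return Matrix (bands x channels) of relative powers; a vector input gives
#'   a named vector.
#' @export
relative_band_powers <- function(freq, psd, bands = eeg_config()$bands) {
  P <- as.matrix(psd)
  nb <- names(bands)
  upper <- max(vapply(bands, `[`, numeric(1), 2))
  bp <- matrix(NA_real_, length(bands), ncol(P), dimnames = list(nb, colnames(P)))
  for (i in seq_along(bands)) {
    lo <- bands[[i]][1]; hi <- bands[[i]][2]
    sel <- if (hi >= upper) freq >= lo & freq <= hi else freq >= lo & freq < hi
    if (!any(sel)) stop(sprintf("band '%s' contains no frequency bins", nb[i]), call. = FALSE)
    bp[i, ] <- colSums(P[sel, , drop = FALSE])
  }
  rel <- sweep(bp, 2, colSums(bp), "/")
  if (is.vector(psd) || ncol(P) == 1) rel[, 1] else rel
}

#' Per-channel relative band powers for one phase
#'
#' Extracts the phase from a recording's EEG block, preprocesses it, and
#' returns a tidy table of relative band powers per electrode.
#'
#' @param recording A `multimodal_recording`.
#' @param phase Phase name.
#' @param config An [eeg_config()].
#' @return Tibble with `channel`, `band`, `phase`, `value`.
#' @export
eeg_band_powers <- function(recording, phase, config = eeg_config()) {
  seg <- extract_phase(recording$eeg, recording$timeline, phase)
  dplyr::mutate(eeg_segment_band_powers(seg, config), phase = phase,
                .after = "band")
}

#' @rdname eeg_band_powers
#' @param segment A [signal_matrix()] EEG segment (one phase).
#' @details `eeg_segment_band_powers()` runs the trim/resample steps in R and
#'   delegates the zero-phase filter cascade plus Welch accumulation to one
#'   compiled pass (numerically identical to composing [preprocess_eeg()] and
#'   [welch_psd()], which remain the reference implementations).
#' @export
eeg_segment_band_powers <- function(segment, config = eeg_config()) {
  stopifnot(inherits(segment, "signal_matrix"))
  n <- nrow(segment$samples)
  fs <- segment$fs
  if (n / fs <= 2 * config$trim_s)
    stop("segment shorter than twice the trim duration", call. = FALSE)
  keep <- (floor(config$trim_s * fs) + 1):(n - floor(config$trim_s * fs))
  X <- segment$samples[keep, , drop = FALSE]
  if (fs != config$resample_to) {
    X <- fft_resample_matrix(X, fs, config$resample_to)
    fs <- config$resample_to
  }
  nc <- if (is.na(config$notch_hz)) list(b = 1, a = 1)
        else notch_coefs(config$notch_hz, fs, config$notch_q)
  bw <- signal::butter(4, config$bandpass / (fs / 2), type = "pass")
  nw <- round(config$welch_window_s * fs)
  step <- max(1, round(nw * (1 - config$welch_overlap)))
  acc <- filter_welch(X, nc$b, nc$a, bw$b, bw$a, nw, step)
  nwin <- (nrow(X) - nw) %/% step + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  psd <- 2 * acc / (nwin * fs * sum(w^2))
  nh <- floor(nw / 2)
  if (nw %% 2 == 0) psd[nh, ] <- psd[nh, ] / 2
  colnames(psd) <- segment$labels
  rel <- relative_band_powers((1:nh) * fs / nw, psd, config$bands)
  tibble::tibble(
    channel = rep(colnames(rel), each = nrow(rel)),
    band = rep(rownames(rel), ncol(rel)),
    value = as.vector(rel)
  )
}

#' Electrode-averaged band-power features
#'
#' The EEG contribution to the subject feature table: for PRE and POST, the
#' five relative band powers averaged across the 64 electrodes (10 features).
#'
#' @inheritParams eeg_band_powers
#' @param phases Phases to summarize.
#' @return Tibble with `modality`, `feature`, `phase`, `value`.
#' @export
eeg_phase_features <- function(recording, phases = c("pre", "post"),
                               config = eeg_config()) {
  purrr::map_dfr(phases, function(ph) {
    bp <- eeg_band_powers(recording, ph, config)
    dplyr::summarise(dplyr::group_by(bp, .data$band), value = mean(.data$value),
                     .groups = "drop") |>
      dplyr::transmute(modality = "eeg",
                       feature = paste0("eeg_", .data$band),
                       phase = ph, value = .data$value)
  })
}

#' Electrode-wise POST-vs-PRE test with FDR correction
#'
#' For one band and one group: a paired two-tailed t-test of POST vs PRE
#' relative power per electrode across the group's subjects, with
#' Benjamini-Hochberg FDR correction across the electrodes (the family is the
#' electrode set within one band within one group).
#'
#' @param band_powers Tidy tibble with columns `subject_id`, `channel`,
#'   `band`, `phase`, `value` covering phases `pre` and `post`.
#' @param band Band name to test.
#' @param alpha Significance level on the adjusted p-values.
#' @return Tibble of class `electrode_stats`: `channel`, `band`, `mean_diff`,
#'   `t`, `p`, `p_adj`, `significant`.
#' @export
electrode_band_test <- function(band_powers, band, alpha = 0.05) {
  bp <- dplyr::filter(band_powers, .data$band == !!band,
                      .data$phase %in% c("pre", "post"))
  wide <- tidyr::pivot_wider(bp, names_from = "phase", values_from = "value")
  if (anyNA(wide$pre) || anyNA(wide$post))
    stop("every subject needs both phases for every electrode", call. = FALSE)
  res <- dplyr::summarise(
    dplyr::group_by(wide, .data$channel),
    n = dplyr::n(),
    mean_diff = mean(.data$post - .data$pre),
    t = tryCatch(stats::t.test(.data$post, .data$pre, paired = TRUE)$statistic,
                 error = function(e) NA_real_),
    p = tryCatch(stats::t.test(.data$post, .data$pre, paired = TRUE)$p.value,
                 error = function(e) NA_real_),
    .groups = "drop"
  )
  if (any(res$n < 3)) stop("need at least 3 subjects per electrode", call. = FALSE)
  res$band <- band
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj <= alpha
  out <- res[, c("channel", "band", "n", "mean_diff", "t", "p", "p_adj", "significant")]
  class(out) <- c("electrode_stats", class(out))
  out
}
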
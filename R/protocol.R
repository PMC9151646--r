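#' Default experiment timeline
#'
#' The 320-s postural-control protocol: a 2-min quiet-stance baseline, a 40-s
#' quiet-stance PRE phase, three 40-s platform-motion segments at 25/50/75% of
#' maximal wave amplitude, and a 40-s quiet-stance POST phase. PRE and POST are
#' performed identically (hands by side, platform stationary) so that their
#' difference isolates the adaptation triggered by the perturbation.
#'
#' @return A tibble with columns `phase`, `start_s`, `end_s` (half-open
#'   `[start_s, end_s)` intervals, contiguous, spanning 0--320 s).
#' @export
#' @examples
#' default_timeline()
default_timeline <- function() {
  tibble::tibble(
    phase   = c("baseline", "pre", "p25", "p50", "p75", "post"),
    start_s = c(0, 120, 160, 200, 240, 280),
    end_s   = c(120, 160, 200, 240, 280, 320)
  )
}

validate_timeline <- function(timeline) {
  stopifnot(all(c("phase", "start_s", "end_s") %in% names(timeline)))
  if (any(timeline$start_s >= timeline$end_s))
    stop("timeline segments must have start_s < end_s", call. = FALSE)
  if (nrow(timeline) > 1) {
    gaps <- timeline$start_s[-1] - timeline$end_s[-nrow(timeline)]
    if (any(abs(gaps) > 1e-9))
      stop("timeline segments must be contiguous and non-overlapping", call. = FALSE)
  }
  invisible(timeline)
}

#' Construct a single-channel signal
#'
#' A light container for one uniformly sampled channel: the samples, its
#' sampling rate, a label, and physical units. All recordings in the package
#' (EEG in microvolts, EMG in arbitrary units, CoP displacement in cm, heart
#' rate in bpm) are carried as channel series.
#'
#' @param samples Numeric vector, no missing values.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name.
#' @param units Physical units string.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(samples, fs, label = "", units = "") {
  stopifnot(is.numeric(samples), length(samples) >= 1, is.numeric(fs), fs > 0)
  if (anyNA(samples)) stop("channel series must not contain missing values", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         label = as.character(label), units = as.character(units)),
    class = "channel_series"
  )
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s: %d samples @ %g Hz (%.3f s)%s\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$samples)

duration_s <- function(x) length(x$samples) / x$fs

#' Construct a multichannel signal block
#'
#' Matrix-backed container for synchronously sampled channels (one column per
#' channel), used for the 64-channel EEG and the 6-muscle EMG. Keeping the
#' channels in one matrix lets the spectral pipeline process all channels with
#' single FFT/filter calls.
#'
#' @param samples Numeric matrix, one column per channel.
#' @param fs Sampling rate in Hz.
#' @param labels Channel names (length `ncol(samples)`).
#' @param units Physical units string.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(samples, fs, labels, units = "") {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), nrow(samples) >= 1, fs > 0,
            length(labels) == ncol(samples))
  if (anyNA(samples)) stop("signal matrix must not contain missing values", call. = FALSE)
  colnames(samples) <- labels
  structure(list(samples = samples, fs = as.numeric(fs),
                 labels = as.character(labels), units = as.character(units)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d channels x %d samples @ %g Hz (%.3f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Extract one protocol phase from a signal
#'
#' Slices the half-open interval `[start_s, end_s)` of the named phase using
#' sample indices `[floor(start_s * fs), floor(end_s * fs))`, so contiguous
#' phases never share a sample. Time origin is the start of the baseline
#' (t = 0 at the first sample).
#'
#' @param x A [channel_series()] or [signal_matrix()].
#' @param timeline A timeline tibble as from [default_timeline()].
#' @param phase Phase name, one of `timeline$phase`.
#' @return An object of the same class covering the phase.
#' @export
extract_phase <- function(x, timeline = default_timeline(), phase) {
  UseMethod("extract_phase")
}

phase_index_range <- function(n, fs, timeline, phase) {
  validate_timeline(timeline)
  row <- timeline[timeline$phase == phase, ]
  if (nrow(row) != 1)
    stop(sprintf("unknown phase '%s'", phase), call. = FALSE)
  i0 <- floor(row$start_s * fs)   # 0-based
  i1 <- floor(row$end_s * fs)
  if (i1 > n)
    stop(sprintf("series (%.1f s) does not cover phase '%s' ending at %g s",
                 n / fs, phase, row$end_s), call. = FALSE)
  (i0 + 1):i1
}

#' @export
extract_phase.channel_series <- function(x, timeline = default_timeline(), phase) {
  idx <- phase_index_range(length(x$samples), x$fs, timeline, phase)
  channel_series(x$samples[idx], x$fs, x$label, x$units)
}

#' @export
extract_phase.signal_matrix <- function(x, timeline = default_timeline(), phase) {
  idx <- phase_index_range(nrow(x$samples), x$fs, timeline, phase)
  signal_matrix(x$samples[idx, , drop = FALSE], x$fs, x$labels, x$units)
}

#' POST minus PRE differencing
#'
#' The analysis paradigm: every feature measured in the POST quiet-stance
#' phase minus the same feature in PRE. Operates on a tidy feature table and
#' returns one row per feature with `value = post - pre`; any grouping columns
#' beyond `phase` and `value` (subject, modality, ...) are preserved.
#'
#' @param features Tibble with at least `feature`, `phase`, `value` columns;
#'   `phase` must contain `"pre"` and `"post"` for every feature (within every
#'   combination of the other id columns).
#' @return Tibble with the `phase` column removed and `value = post - pre`.
#' @export
post_minus_pre <- function(features) {
  stopifnot(all(c("feature", "phase", "value") %in% names(features)))
  keys <- setdiff(names(features), c("phase", "value"))
  wide <- tidyr::pivot_wider(
    dplyr::filter(features, .data$phase %in% c("pre", "post")),
    names_from = "phase", values_from = "value"
  )
  if (!all(c("pre", "post") %in% names(wide)) ||
      anyNA(wide$pre) || anyNA(wide$post))
    stop("every feature needs both a 'pre' and a 'post' value", call. = FALSE)
  dplyr::mutate(wide[, keys, drop = FALSE], value = wide$post - wide$pre)
}
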
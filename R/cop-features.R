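#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with an odd window, the standard
#' pre-filter for centre-of-pressure trajectories (window 7 here by default).
#' Polynomials of degree up to `polyorder` pass through unchanged.
#'
#' @param x Numeric series, length >= `window`.
#' @param window Odd window length in samples (default 7).
#' @param polyorder Polynomial order (< `window`, default 3).
#' @return Smoothed series, same length as the input.
#' @export
smooth_savgol <- function(x, window = 7, polyorder = 3) {
  stopifnot(window %% 2 == 1, polyorder < window)
  if (length(x) < window)
    stop("series shorter than the smoothing window", call. = FALSE)
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' Convert a normalized board reading to displacement in cm
#'
#' Force-plate output is a dimensionless position in \[-1, 1\] expressed as a
#' fraction of the board dimension; displacement in cm is
#' `board_size * normalized / 2` (half the board spans readings 0 to 1).
#'
#' @param normalized Reading(s) in \[-1, 1\].
#' @param board_size Board dimension along the axis, cm.
#' @return Displacement in cm.
#' @export
to_displacement_cm <- function(normalized, board_size) {
  stopifnot(board_size > 0)
  if (any(abs(normalized) > 1))
    stop("normalized readings must lie in [-1, 1]", call. = FALSE)
  board_size * normalized / 2
}

#' Build a centered, smoothed stabilogram
#'
#' Applies Savitzky-Golay smoothing (window 7) to the raw anteroposterior (AP)
#' and mediolateral (ML) CoP displacement and subtracts each axis mean, so
#' distance features are measured from the mean CoP position.
#'
#' @param ap_raw,ml_raw Raw displacement series in cm, equal length >= 7.
#' @param fs Sampling rate, Hz.
#' @param window,polyorder Savitzky-Golay parameters, see [smooth_savgol()].
#' @return An object of class `stabilogram`: list with `ap`, `ml` (centered
#'   cm), `fs`, `duration` (s).
#' @export
make_stabilogram <- function(ap_raw, ml_raw, fs, window = 7, polyorder = 3) {
  if (length(ap_raw) != length(ml_raw))
    stop("AP and ML series must have equal length", call. = FALSE)
  stopifnot(length(ap_raw) >= 2, fs > 0)
  ap <- smooth_savgol(ap_raw, window, polyorder)
  ml <- smooth_savgol(ml_raw, window, polyorder)
  structure(
    list(ap = ap - mean(ap), ml = ml - mean(ml),
         fs = fs, duration = length(ap) / fs),
    class = "stabilogram"
  )
}

#' @export
print.stabilogram <- function(x, ...) {
  cat(sprintf("<stabilogram> %d samples @ %g Hz (%.2f s), RMS AP %.3f / ML %.3f cm\n",
              length(x$ap), x$fs, x$duration,
              sqrt(mean(x$ap^2)), sqrt(mean(x$ml^2))))
  invisible(x)
}

#' Geometric stabilogram features
#'
#' Path-length and distance descriptors of the centered sway trajectory:
#' total excursion on the support plane and per axis (TOTEX,
#' `sum(sqrt(dAP^2 + dML^2))` resp. `sum(|d|)`), mean distance from the mean
#' CoP (MDIST families), RMS resultant distance (RDIST), and the four
#' extreme-point magnitudes (anterior = `max(ap)`, posterior = `|min(ap)|`,
#' right = `max(ml)`, left = `|min(ml)|`; anterior displacement is positive
#' AP).
#'
#' @param stab A [make_stabilogram()] object (>= 2 samples).
#' @return Named list of features, all in cm.
#' @export
geometric_features <- function(stab) {
  stopifnot(inherits(stab, "stabilogram"), length(stab$ap) >= 2)
  dap <- diff(stab$ap); dml <- diff(stab$ml)
  list(
    TOTEX    = sum(sqrt(dap^2 + dml^2)),
    TOTEX_AP = sum(abs(dap)),
    TOTEX_ML = sum(abs(dml)),
    MDIST    = mean(sqrt(stab$ap^2 + stab$ml^2)),
    MDIST_AP = mean(abs(stab$ap)),
    MDIST_ML = mean(abs(stab$ml)),
    RDIST    = sqrt(mean(stab$ap^2 + stab$ml^2)),
    SD_AP    = stats::sd(stab$ap),
    SD_ML    = stats::sd(stab$ml),
    ANTERO_MAGNITUDE  = max(stab$ap),
    POSTERO_MAGNITUDE = abs(min(stab$ap)),
    RIGHT_MAGNITUDE   = max(stab$ml),
    LEFT_MAGNITUDE    = abs(min(stab$ml))
  )
}

#' Mean-velocity features
#'
#' Total excursion divided by the segment duration, on the support plane and
#' per axis.
#'
#' @inheritParams geometric_features
#' @return List with `MVELO`, `MVELO_AP`, `MVELO_ML` in cm/s.
#' @export
velocity_features <- function(stab) {
  stopifnot(inherits(stab, "stabilogram"), stab$duration > 0)
  g <- geometric_features(stab)
  list(MVELO    = g$TOTEX / stab$duration,
       MVELO_AP = g$TOTEX_AP / stab$duration,
       MVELO_ML = g$TOTEX_ML / stab$duration)
}

#' 95% confidence ellipse of the sway cloud
#'
#' Eigen-decomposition of the 2x2 AP/ML covariance (population divisor `n`;
#' with thousands of points per phase the small-sample correction is
#' negligible). Axis half-lengths are `sqrt(lambda_i * q)` with `q` the 0.95
#' chi-square quantile on 2 df; reported axes are full lengths. Orientation is
#' the principal-eigenvector angle measured from the ML axis towards AP, in
#' `(-pi/2, pi/2]`.
#'
#' @inheritParams geometric_features
#' @return List with `ELLIPSE_MAIN_AXIS`, `ELLIPSE_MINOR_AXIS` (cm),
#'   `ELLIPSE_ORIENTATION` (radians), `ELLIPSE_AREA` (cm^2). Identical points
#'   give a zero-axes ellipse.
#' @export
confidence_ellipse <- function(stab) {
  stopifnot(inherits(stab, "stabilogram"))
  n <- length(stab$ap)
  if (n < 3) stop("confidence ellipse needs at least 3 samples", call. = FALSE)
  # population covariance of the centered trajectory
  S <- crossprod(cbind(stab$ml, stab$ap)) / n
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  q <- stats::qchisq(0.95, df = 2)
  half <- sqrt(lam * q)
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1])                       # from ML axis towards AP
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  list(ELLIPSE_MAIN_AXIS  = 2 * half[1],
       ELLIPSE_MINOR_AXIS = 2 * half[2],
       ELLIPSE_ORIENTATION = ang,
       ELLIPSE_AREA = pi * half[1] * half[2])
}

#' Mean absolute heading change
#'
#' Heading of each displacement step is `atan2(dML, dAP)`; successive heading
#' differences are wrapped to `(-pi, pi]` and their absolute values averaged.
#' Zero-length steps carry no heading and are skipped.
#'
#' @inheritParams geometric_features
#' @return Mean absolute heading change in radians.
#' @export
heading_change <- function(stab) {
  stopifnot(inherits(stab, "stabilogram"), length(stab$ap) >= 3)
  dap <- diff(stab$ap); dml <- diff(stab$ml)
  keep <- dap != 0 | dml != 0
  if (!any(keep)) stop("all steps are zero-length; heading undefined", call. = FALSE)
  theta <- atan2(dml[keep], dap[keep])
  if (length(theta) < 2) return(0)
  dtheta <- diff(theta)
  dtheta <- ((dtheta + pi) %% (2 * pi)) - pi     # wrap to (-pi, pi]
  dtheta[dtheta == -pi] <- pi
  mean(abs(dtheta))
}

#' One-sided periodogram
#'
#' FFT magnitude-squared spectrum of the mean-removed signal, scaled as a
#' power spectral density (power / Hz) so that the integral over frequency
#' recovers the signal variance.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @return List with `freq` (Hz, excluding DC) and `psd`.
#' @export
periodogram_psd <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  nh <- floor(n / 2)
  psd <- 2 * Mod(X[2:(nh + 1)])^2 / (n * fs)
  if (n %% 2 == 0) psd[nh] <- psd[nh] / 2   # Nyquist bin is not mirrored
  list(freq = (1:nh) * fs / n, psd = psd)
}

#' Spectral power-law exponent
#'
#' Ordinary least-squares slope of `log10(PSD)` against `log10(f)` over a fit
#' band, with the PSD taken from the one-sided periodogram. Characterizes the
#' colored-noise structure of sway: an exponent of `-alpha` corresponds to
#' `1/f^alpha` power scaling.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param fit_band Frequency interval (Hz) used for the fit; default
#'   0.1--5 Hz, the sway-relevant range.
#' @return The fitted slope (dimensionless).
#' @export
psd_powerlaw_exponent <- function(x, fs, fit_band = c(0.1, 5)) {
  pg <- periodogram_psd(x, fs)
  sel <- pg$freq >= fit_band[1] & pg$freq <= fit_band[2] & pg$psd > 0
  if (sum(sel) < 5)
    stop("fewer than 5 frequency bins in the fit band", call. = FALSE)
  lf <- log10(pg$freq[sel]); lp <- log10(pg$psd[sel])
  unname(stats::coef(stats::lm(lp ~ lf))[2])
}

cop_feature_names <- c(
  "TOTEX", "TOTEX_AP", "TOTEX_ML", "MDIST", "MDIST_AP", "MDIST_ML", "RDIST",
  "MVELO", "MVELO_AP", "MVELO_ML", "SD_AP", "SD_ML",
  "ELLIPSE_MAIN_AXIS", "ELLIPSE_MINOR_AXIS", "ELLIPSE_ORIENTATION",
  "ELLIPSE_AREA", "ANTERO_MAGNITUDE", "POSTERO_MAGNITUDE", "LEFT_MAGNITUDE",
  "RIGHT_MAGNITUDE", "SAMPEN_AP", "SAMPEN_ML", "CI_AP", "CI_ML", "CI_MULTI",
  "HEADING_CHANGE", "PSD_EXP_AP", "PSD_EXP_ML"
)

#' Full stabilogram feature battery
#'
#' Computes every stabilogram feature for one phase: geometric and
#' extreme-point distances, mean velocities, the 95% confidence ellipse,
#' sample entropy per axis, multiscale complexity indices (per axis and
#' multivariate across AP/ML), mean heading change, and the per-axis spectral
#' power-law exponents. Entropy values that are undefined (no template
#' matches) come back as `NA` and are excluded (with a count) from group
#' statistics downstream.
#'
#' @inheritParams geometric_features
#' @param entropy_m,entropy_r_factor,entropy_scales Sample-entropy parameters
#'   (embedding dimension, tolerance as a fraction of SD, multiscale scales).
#' @param fit_band Power-law fit band in Hz.
#' @param include Feature groups to compute; any of `"geometric"`,
#'   `"velocity"`, `"ellipse"`, `"heading"`, `"spectral"`, `"entropy"`.
#'   Restricting the set (e.g. dropping `"entropy"` in large simulation
#'   studies that do not use it) skips the corresponding computations.
#' @return A tibble with `feature`, `value` columns (long format).
#' @export
cop_features <- function(stab,
                         entropy_m = 2, entropy_r_factor = 0.2,
                         entropy_scales = 1:6, fit_band = c(0.1, 5),
                         include = c("geometric", "velocity", "ellipse",
                                     "heading", "spectral", "entropy")) {
  stopifnot(inherits(stab, "stabilogram"))
  include <- match.arg(include, several.ok = TRUE)
  # numerically static: smoothing a constant input can leave ~1e-16 residue
  static <- stats::sd(stab$ap) < 1e-12 && stats::sd(stab$ml) < 1e-12
  out <- list()
  if ("geometric" %in% include) out <- c(out, geometric_features(stab))
  if ("velocity" %in% include) out <- c(out, velocity_features(stab))
  if ("ellipse" %in% include) out <- c(out, confidence_ellipse(stab))
  if ("heading" %in% include)
    out$HEADING_CHANGE <- if (static) 0 else heading_change(stab)
  if ("spectral" %in% include) {
    out$PSD_EXP_AP <- if (static) 0 else psd_powerlaw_exponent(stab$ap, stab$fs, fit_band)
    out$PSD_EXP_ML <- if (static) 0 else psd_powerlaw_exponent(stab$ml, stab$fs, fit_band)
  }
  if ("entropy" %in% include) {
    if (static) {
      out[c("SAMPEN_AP", "SAMPEN_ML", "CI_AP", "CI_ML", "CI_MULTI")] <- 0
    } else {
      out$SAMPEN_AP <- sample_entropy(stab$ap, entropy_m, entropy_r_factor)
      out$SAMPEN_ML <- sample_entropy(stab$ml, entropy_m, entropy_r_factor)
      out$CI_AP <- complexity_index(stab$ap, entropy_m, entropy_r_factor, entropy_scales)$ci
      out$CI_ML <- complexity_index(stab$ml, entropy_m, entropy_r_factor, entropy_scales)$ci
      out$CI_MULTI <- mv_complexity_index(cbind(stab$ap, stab$ml), entropy_m,
                                          entropy_r_factor, entropy_scales)$ci
    }
  }
  tibble::tibble(feature = names(out), value = unlist(out, use.names = FALSE))
}

#' @rdname cop_features
#' @param ... Passed on to [cop_features()].
#' @export
extract_all <- function(stab, ...) cop_features(stab, ...)
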
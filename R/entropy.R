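#' Sample entropy
#'
#' SampEn(m, r): the negative log conditional probability that two template
#' sequences matching for `m` points (Chebyshev distance at most `r`) still
#' match at length `m + 1`, self-matches excluded. Quantifies signal
#' irregularity: larger values mean less regular dynamics. The tolerance is
#' `r_factor` times the series SD, so the measure is invariant under affine
#' scaling of the input.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of `sd(x)` (default 0.2).
#' @param r Absolute tolerance; overrides `r_factor` when supplied (used for
#'   coarse-grained scales of multiscale entropy, where the tolerance stays
#'   fixed at the scale-1 value).
#' @return Entropy in nats; `NA` (with class note) if no template pairs match
#'   at length `m + 1` so the conditional probability is undefined. A constant
#'   series returns 0 (every template matches at both lengths).
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  stopifnot(is.numeric(x), m >= 1, length(x) > m + 1)
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) return(0)        # constant series: A = B, -log(1) = 0
    r <- r_factor * s
  }
  counts <- sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  B <- counts[1]; A <- counts[2]
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Coarse-grain a series for multiscale entropy
#'
#' Non-overlapping averaging: at scale `s` each output point is the mean of
#' `s` consecutive input points; trailing remainder samples are dropped.
#'
#' @param x Numeric series.
#' @param scale Integer scale factor (>= 1).
#' @return The coarse-grained series of length `floor(length(x) / scale)`.
#' @export
coarse_grain <- function(x, scale) {
  stopifnot(scale >= 1)
  scale <- as.integer(scale)
  if (scale == 1L) return(as.numeric(x))
  n <- (length(x) %/% scale) * scale
  colMeans(matrix(x[seq_len(n)], nrow = scale))
}

#' Multiscale-entropy complexity index
#'
#' Coarse-grains the series at scales 1..max(scales) by non-overlapping
#' averaging and sums the sample entropy across scales (the complexity
#' index, CI). The tolerance is fixed from the original series
#' (`r_factor * sd(x)`) across all scales, the usual multiscale-entropy
#' convention.
#'
#' @inheritParams sample_entropy
#' @param scales Integer scales (default 1:6).
#' @return List with `ci` (sum over scales; `NA` if any scale is undefined)
#'   and `per_scale` (the individual entropies).
#' @export
complexity_index <- function(x, m = 2, r_factor = 0.2, scales = 1:6) {
  stopifnot(length(x) >= max(scales) * (m + 2))
  s0 <- stats::sd(x)
  r <- if (s0 == 0) 0 else r_factor * s0
  per_scale <- vapply(scales, function(s) {
    xs <- coarse_grain(x, s)
    if (s0 == 0) return(0)
    sample_entropy(xs, m = m, r = r)
  }, numeric(1))
  list(ci = if (anyNA(per_scale)) NA_real_ else sum(per_scale), per_scale = per_scale)
}

#' Multivariate sample entropy
#'
#' Sample entropy of a multichannel series using composite delay vectors:
#' the level-m embedding stacks `m` consecutive samples from every channel;
#' the level-(m+1) set extends each vector by one further sample in each
#' channel in turn. Chebyshev distance across all components; tolerance
#' relative to the pooled (per-channel averaged) SD. Extended-level pairs
#' sharing a time index are excluded (the generalization of self-match
#' exclusion), which keeps the estimate a proper conditional probability.
#'
#' @param X Numeric matrix, one column per channel.
#' @inheritParams sample_entropy
#' @return Entropy in nats, or `NA` when undefined.
#' @export
mv_sample_entropy <- function(X, m = 2, r_factor = 0.2, r = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) > m + 1, ncol(X) >= 1)
  if (is.null(r)) {
    s <- mean(apply(X, 2, stats::sd))
    if (s == 0) return(0)
    r <- r_factor * s
  }
  cnt <- msampen_counts(X, as.integer(m), as.numeric(r))
  B <- cnt[1]; A <- cnt[2]; nB <- cnt[3]
  if (B == 0 || A == 0) return(NA_real_)
  p <- ncol(X)
  # match densities: B over pairs of composite vectors, A over pairs of
  # extended vectors with distinct time indices (p^2 extension combinations
  # per base pair)
  phiB <- B / (nB * (nB - 1) / 2)
  phiA <- A / (p^2 * nB * (nB - 1) / 2)
  -log(phiA / phiB)
}

#' Multivariate multiscale complexity index
#'
#' The multivariate analogue of [complexity_index()]: channels are
#' coarse-grained jointly at each scale and [mv_sample_entropy()] summed
#' across scales, with the tolerance fixed from the original pooled SD.
#'
#' @inheritParams mv_sample_entropy
#' @param scales Integer scales (default 1:6).
#' @return List with `ci` and `per_scale`.
#' @export
mv_complexity_index <- function(X, m = 2, r_factor = 0.2, scales = 1:6) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= max(scales) * (m + 2))
  s0 <- mean(apply(X, 2, stats::sd))
  r <- if (s0 == 0) 0 else r_factor * s0
  per_scale <- vapply(scales, function(s) {
    Xs <- apply(X, 2, coarse_grain, scale = s)
    if (s0 == 0) return(0)
    mv_sample_entropy(Xs, m = m, r = r)
  }, numeric(1))
  list(ci = if (anyNA(per_scale)) NA_real_ else sum(per_scale), per_scale = per_scale)
}
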
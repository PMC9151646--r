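test_result <- function(statistic, p_value, n, test_name) {
  tibble::tibble(test = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n)
}

#' Two-tailed Wilcoxon matched-pairs signed-rank test
#'
#' The paired nonparametric test used for all PRE-vs-POST comparisons. Zero
#' differences are dropped (their count is reported); the p-value is exact
#' for up to 25 nonzero untied differences and uses the tie-corrected normal
#' approximation otherwise.
#'
#' @param x_pre,x_post Paired samples.
#' @return One-row tibble: `test`, `statistic` (V, the positive-rank sum),
#'   `p_value`, `n` (nonzero differences), `n_zero`.
#' @export
wilcoxon_signed_rank <- function(x_pre, x_post) {
  stopifnot(length(x_pre) == length(x_post))
  d <- x_post - x_pre
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero; test undefined", call. = FALSE)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = !exact))
  out <- test_result(wt$statistic, wt$p.value, length(d), "wilcoxon_signed_rank")
  out$n_zero <- n_zero
  out
}

#' Two-tailed Mann-Whitney U test
#'
#' Independent two-sample rank test (used for between-subgroup comparisons,
#' e.g. balance-problem vs no-balance-problem POST values). Exact p for small
#' samples without ties, normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param a,b Samples.
#' @return One-row tibble with the U statistic for `a`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- length(a) <= 50 && length(b) <= 50 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  out <- test_result(wt$statistic, wt$p.value, length(a) + length(b), "mann_whitney")
  out$n1 <- length(a); out$n2 <- length(b)
  out
}

#' Shapiro-Wilk normality test
#'
#' The normality gate reported alongside the rank tests (the analysis always
#' reports the nonparametric outcome regardless, avoiding data-dependent test
#' switching).
#'
#' @param x Sample, 3 <= n <= 5000, non-constant.
#' @return One-row tibble with the W statistic.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample; W undefined", call. = FALSE)
  st <- stats::shapiro.test(x)
  test_result(st$statistic, st$p.value, length(x), "shapiro_wilk")
}

#' Pooled two-sample t-test from printed summaries
#'
#' Student's pooled-variance t computed directly from group sizes, means, and
#' SDs, for reproducing tests reported only as summary rows:
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, df `n1 + n2 - 2`,
#' two-tailed p.
#'
#' @param n1,m1,s1 First group's size, mean, SD.
#' @param n2,m2,s2 Second group's size, mean, SD.
#' @return One-row tibble with `statistic`, `p_value`, `df`.
#' @export
two_sample_t_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  out <- test_result(t, 2 * stats::pt(-abs(t), df), n1 + n2, "pooled_t")
  out$df <- df
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (monotone-enforced) with rejection flags at
#' level `q`.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param q FDR level.
#' @return Tibble with `p`, `p_adj`, `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adj = adj, reject = adj <= q)
}

#' Symptom-based subgroup of the concussion group
#'
#' Concussed subjects whose named SCAT5 item is scored above zero (symptom
#' present). Subgroups such as "balance problems" are formed this way.
#'
#' @param metadata Metadata tibble as from [generate_metadata()] (columns
#'   `subject_id`, `group`, `scat5_01` .. `scat5_22`).
#' @param item SCAT5 item index (1..22).
#' @return Character vector of subject ids.
#' @export
symptom_subgroup <- function(metadata, item) {
  if (item < 1 || item > 22) stop("SCAT5 item index must be in 1..22", call. = FALSE)
  col <- sprintf("scat5_%02d", item)
  stopifnot(col %in% names(metadata))
  metadata$subject_id[metadata$group == "concussion" & metadata[[col]] > 0]
}

#' PRE-vs-POST feature battery
#'
#' One Wilcoxon matched-pairs signed-rank test per feature per group on a
#' tidy per-subject feature table, flagged at `alpha`. Results are invariant
#' to subject ordering.
#'
#' @param features Tibble with columns `subject_id`, `group`, `phase`,
#'   `feature`, `value`, phases `pre` and `post` present for every subject
#'   and feature. `NA` feature values (undefined entropies) drop the subject
#'   for that feature, with the count reported in `n_dropped`.
#' @param alpha Significance level.
#' @return Tibble with one row per (feature, group): statistic, p, flag.
#' @export
pre_post_battery <- function(features, alpha = 0.05) {
  stopifnot(all(c("subject_id", "group", "phase", "feature", "value")
                %in% names(features)))
  wide <- tidyr::pivot_wider(
    dplyr::filter(features, .data$phase %in% c("pre", "post")),
    names_from = "phase", values_from = "value"
  )
  dplyr::summarise(
    dplyr::group_by(wide, .data$feature, .data$group),
    n_dropped = sum(is.na(.data$pre) | is.na(.data$post)),
    res = {
      ok <- !is.na(.data$pre) & !is.na(.data$post)
      wilcoxon_signed_rank(.data$pre[ok], .data$post[ok])[, c("statistic", "p_value", "n")]
    },
    .groups = "drop"
  ) |>
    tidyr::unpack("res") |>
    dplyr::mutate(significant = .data$p_value < alpha)
}
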
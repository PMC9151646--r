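#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the PCA loadings
#'
#' @param x A `pca_features` object from [pca_reduce()].
#' @param ... Unused.
#' @return Tibble with `column`, `component`, `loading` for the retained
#'   components.
#' @export
tidy.pca_features <- function(x, ...) {
  rot <- x$rotation[, seq_len(x$n_components), drop = FALSE]
  tibble::tibble(
    column = rep(rownames(rot), ncol(rot)),
    component = rep(colnames(rot), each = nrow(rot)),
    loading = as.vector(rot)
  )
}

#' One-row PCA summary
#'
#' @inheritParams tidy.pca_features
#' @return Tibble with the number of components, input columns, and the
#'   variance fraction the retained components explain.
#' @export
glance.pca_features <- function(x, ...) {
  ve <- x$sdev^2 / sum(x$sdev^2)
  tibble::tibble(n_components = x$n_components,
                 n_columns = nrow(x$rotation),
                 prop_variance = sum(ve[seq_len(x$n_components)]))
}

#' Tidy classifier metrics into long form
#'
#' @param x A `classifier_metrics` table from [evaluate_classifiers()].
#' @param ... Unused.
#' @return Tibble with `model` (and `selection` if present), `metric`,
#'   `value` (percent).
#' @export
tidy.classifier_metrics <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      c("accuracy", "sensitivity", "specificity"),
                      names_to = "metric", values_to = "value")
}

#' One-row classifier summary
#'
#' @inheritParams tidy.classifier_metrics
#' @return Tibble with the number of models, seeds, and the best model and
#'   its accuracy.
#' @export
glance.classifier_metrics <- function(x, ...) {
  best <- x[which.max(x$accuracy), ]
  tibble::tibble(n_models = nrow(x),
                 n_seeds = length(attr(x, "seeds") %||% NA),
                 best_model = best$model,
                 best_accuracy = best$accuracy)
}

#' Significant-electrode counts per band
#'
#' @param x An `electrode_stats` table from [electrode_band_test()] or
#'   [cohort_electrode_stats()].
#' @param ... Unused.
#' @return Tibble with one row per (group, ) band: electrodes tested and
#'   flagged.
#' @export
glance.electrode_stats <- function(x, ...) {
  keys <- intersect(c("group", "band"), names(x))
  dplyr::summarise(dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))),
                   n_electrodes = dplyr::n(),
                   n_significant = sum(.data$significant),
                   min_p_adj = min(.data$p_adj),
                   .groups = "drop")
}
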
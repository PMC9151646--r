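#' PCA reduction of the feature table
#'
#' Columns are z-scored (mean 0, SD 1) and projected onto the leading
#' principal components (9 by default, the dimensionality used for the
#' classification stage).
#'
#' @param table Tibble whose numeric columns are features; a `subject_id`
#'   column, if present, is carried through.
#' @param n_components Number of components retained.
#' @return Object of class `pca_features`: the score tibble plus the fitted
#'   rotation, singular values, centers and scales (accessible via [tidy()]
#'   and [glance()] methods).
#' @export
pca_reduce <- function(table, n_components = 9) {
  id <- NULL
  if ("subject_id" %in% names(table)) {
    id <- table$subject_id
    table <- dplyr::select(table, -dplyr::any_of(c("subject_id", "group")))
  }
  X <- as.matrix(table)
  stopifnot(is.numeric(X))
  if (nrow(X) < n_components || ncol(X) < n_components)
    stop("fewer rows or columns than requested components", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate (constant) feature columns: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  if (!is.null(id)) scores <- dplyr::bind_cols(tibble::tibble(subject_id = id), scores)
  structure(list(scores = scores, rotation = pc$rotation, sdev = pc$sdev,
                 center = pc$center, scale = pc$scale,
                 n_components = n_components),
            class = "pca_features")
}

#' @export
print.pca_features <- function(x, ...) {
  ve <- x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("<pca_features> %d components, %.1f%% variance explained\n",
              x$n_components, 100 * sum(ve[seq_len(x$n_components)])))
  invisible(x)
}

#' Build one of the three classification feature selections
#'
#' The three inputs compared in the classification stage: the 9 principal
#' components of the 51 biosignal features (`"pca9"`), the 22 raw SCAT5 items
#' (`"scat5"`), or their 31-column concatenation (`"combined"`). This applies
#' PCA to the full table before cross-validation (the workflow's original
#' ordering); [evaluate_classifiers()] can instead refit the PCA inside each
#' training fold.
#'
#' @param biosig Feature table from [assemble_features()].
#' @param scat5 SCAT5 item table from [scat5_table()].
#' @param which `"pca9"`, `"scat5"`, or `"combined"`.
#' @param n_components Components for the PCA block.
#' @return Tibble: `subject_id` plus the selected feature columns
#'   (9 / 22 / 31).
#' @export
build_selection <- function(biosig, scat5, which = c("pca9", "scat5", "combined"),
                            n_components = 9) {
  which <- match.arg(which)
  if (!identical(sort(biosig$subject_id), sort(scat5$subject_id)))
    stop("biosignal and SCAT5 tables cover different subjects", call. = FALSE)
  scat5 <- scat5[match(biosig$subject_id, scat5$subject_id), ]
  if (which == "scat5") return(scat5)
  pcs <- pca_reduce(biosig, n_components)$scores
  if (which == "pca9") return(pcs)
  dplyr::inner_join(pcs, scat5, by = "subject_id")
}

# --- classifiers ------------------------------------------------------------
# All take a numeric train matrix, a binary factor, and a test matrix, and
# return predicted factor labels. Levels: (negative, positive).

fit_predict_rf <- function(x_train, y_train, x_test) {
  fit <- randomForest::randomForest(x_train, y_train, ntree = 300)
  stats::predict(fit, x_test)
}

fit_predict_gb <- function(x_train, y_train, x_test) {
  yb <- as.integer(y_train == levels(y_train)[2])
  dtrain <- xgboost::xgb.DMatrix(x_train, label = yb, nthread = 1)
  fit <- xgboost::xgb.train(params = list(eta = 0.1, max_depth = 3,
                                          objective = "binary:logistic",
                                          nthread = 1),
                            data = dtrain, nrounds = 100, verbose = 0)
  pr <- stats::predict(fit, xgboost::xgb.DMatrix(x_test, nthread = 1))
  factor(levels(y_train)[1 + (pr >= 0.5)], levels = levels(y_train))
}

# AdaBoost (SAMME for two classes) over depth-1 rpart stumps.
fit_predict_adaboost <- function(x_train, y_train, x_test, n_rounds = 100) {
  n <- nrow(x_train)
  y <- ifelse(y_train == levels(y_train)[2], 1, -1)
  df_train <- data.frame(x_train); df_test <- data.frame(x_test)
  colnames(df_test) <- colnames(df_train)
  w <- rep(1 / n, n)
  score <- rep(0, nrow(x_test))
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (b in seq_len(n_rounds)) {
    df_train$.y <- factor(y)
    fit <- rpart::rpart(.y ~ ., data = df_train, weights = w, method = "class",
                        control = ctrl)
    pred_tr <- as.numeric(as.character(stats::predict(fit, df_train, type = "class")))
    err <- sum(w * (pred_tr != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * y * pred_tr)
    w <- w / sum(w)
    pred_te <- as.numeric(as.character(stats::predict(fit, df_test, type = "class")))
    score <- score + alpha * pred_te
    if (err <= 1e-10) break
  }
  factor(levels(y_train)[1 + (score >= 0)], levels = levels(y_train))
}

fit_predict_svm <- function(x_train, y_train, x_test) {
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = 1, scale = FALSE)
  stats::predict(fit, x_test)
}

fit_predict_mlp <- function(x_train, y_train, x_test) {
  yb <- as.integer(y_train == levels(y_train)[2])
  fit <- nnet::nnet(x_train, yb, size = 16, maxit = 1000, decay = 0,
                    trace = FALSE, entropy = TRUE, MaxNWts = 5000)
  pr <- as.numeric(stats::predict(fit, x_test))
  factor(levels(y_train)[1 + (pr >= 0.5)], levels = levels(y_train))
}

classifier_registry <- function() {
  list(rf = fit_predict_rf, svm = fit_predict_svm, adab = fit_predict_adaboost,
       mlp = fit_predict_mlp, gb = fit_predict_gb)
}

# z-score needed by the scale-sensitive models (SVM, MLP); fit on train only
scale_pair <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sd, "/"))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Cross-validated evaluation of the five classifiers
#'
#' Random forest (300 trees), linear-kernel SVM (C = 1, in-fold
#' standardization), AdaBoost over decision stumps (100 rounds), a
#' single-hidden-layer MLP (16 units, in-fold standardization), and gradient
#' boosting (100 rounds), each evaluated with stratified k-fold
#' cross-validation repeated over several seeds. Per seed the fold confusion
#' matrices are pooled; reported metrics are the across-seed means of pooled
#' accuracy, sensitivity (recall of the positive class, concussion), and
#' specificity, in percent.
#'
#' @param features Tibble of predictor columns (plus optional `subject_id`,
#'   dropped), or a numeric matrix.
#' @param labels Factor or character group labels; `positive` names the
#'   positive class.
#' @param k Folds.
#' @param seeds Integer vector of CV seeds.
#' @param models Subset of `c("rf", "svm", "adab", "mlp", "gb")`.
#' @param positive Positive class label.
#' @param pca_cols Optional character vector naming columns to replace, inside
#'   each training fold, by their leading principal components (leakage-free
#'   variant of the PCA selection); remaining columns pass through.
#' @param pca_ncomp Components used when `pca_cols` is given.
#' @return Tibble of class `classifier_metrics`: one row per model with
#'   `accuracy`, `sensitivity`, `specificity` (percent); pooled confusion
#'   counts per seed are attached as attribute `confusions`.
#' @export
evaluate_classifiers <- function(features, labels, k = 10, seeds = 1:10,
                                 models = c("rf", "svm", "adab", "mlp", "gb"),
                                 positive = "concussion",
                                 pca_cols = NULL, pca_ncomp = 9) {
  X_all <- if (is.matrix(features)) features else {
    as.matrix(dplyr::select(tibble::as_tibble(features),
                            -dplyr::any_of(c("subject_id", "group"))))
  }
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  if (!positive %in% levels(y)) positive <- levels(y)[2]
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))  # (neg, pos)
  if (nrow(X_all) < k) stop("fewer subjects than folds", call. = FALSE)
  registry <- classifier_registry()[models]
  conf <- array(0, dim = c(length(models), length(seeds), 4),
                dimnames = list(models, NULL, c("tp", "tn", "fp", "fn")))
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    fold <- stratified_folds(y, k)
    for (fi in seq_len(k)) {
      tr <- fold != fi; te <- !tr
      if (!any(te)) next
      x_tr <- X_all[tr, , drop = FALSE]; x_te <- X_all[te, , drop = FALSE]
      if (!is.null(pca_cols)) {
        pc_idx <- colnames(X_all) %in% pca_cols
        sp <- scale_pair(x_tr[, pc_idx, drop = FALSE], x_te[, pc_idx, drop = FALSE])
        rot <- stats::prcomp(sp$train, center = FALSE, scale. = FALSE)$rotation
        rot <- rot[, seq_len(min(pca_ncomp, ncol(rot))), drop = FALSE]
        x_tr <- cbind(sp$train %*% rot, x_tr[, !pc_idx, drop = FALSE])
        x_te <- cbind(sp$test %*% rot, x_te[, !pc_idx, drop = FALSE])
      }
      sc <- scale_pair(x_tr, x_te)
      for (m in models) {
        xm_tr <- if (m %in% c("svm", "mlp")) sc$train else x_tr
        xm_te <- if (m %in% c("svm", "mlp")) sc$test else x_te
        pred <- registry[[m]](xm_tr, y[tr], xm_te)
        truth <- y[te]
        pos <- levels(y)[2]
        conf[m, si, "tp"] <- conf[m, si, "tp"] + sum(pred == pos & truth == pos)
        conf[m, si, "tn"] <- conf[m, si, "tn"] + sum(pred != pos & truth != pos)
        conf[m, si, "fp"] <- conf[m, si, "fp"] + sum(pred == pos & truth != pos)
        conf[m, si, "fn"] <- conf[m, si, "fn"] + sum(pred != pos & truth == pos)
      }
    }
  }
  metrics <- purrr::map_dfr(models, function(m) {
    cm <- conf[m, , , drop = FALSE]
    acc <- (cm[1, , "tp"] + cm[1, , "tn"]) /
      (cm[1, , "tp"] + cm[1, , "tn"] + cm[1, , "fp"] + cm[1, , "fn"])
    sens <- cm[1, , "tp"] / pmax(cm[1, , "tp"] + cm[1, , "fn"], 1)
    spec <- cm[1, , "tn"] / pmax(cm[1, , "tn"] + cm[1, , "fp"], 1)
    tibble::tibble(model = m, accuracy = 100 * mean(acc),
                   sensitivity = 100 * mean(sens),
                   specificity = 100 * mean(spec))
  })
  attr(metrics, "confusions") <- conf
  attr(metrics, "seeds") <- seeds
  class(metrics) <- c("classifier_metrics", class(metrics))
  metrics
}
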
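# A fabricated tidy feature table covering the full 51-column inventory.
mock_long_features <- function(ids, seed = 1) {
  set.seed(seed)
  cols <- swaylab:::biovr_feature_columns()
  purrr::map_dfr(ids, function(s) {
    tibble::tibble(
      subject_id = s,
      feature = sub("_(pre|post|p25|p50|p75)$", "", cols),
      phase = sub("^.*_(pre|post|p25|p50|p75)$", "\\1", cols),
      value = rnorm(length(cols))
    )
  })
}

mock_metadata <- function(ids, groups) {
  meta <- tibble::tibble(subject_id = ids, group = groups)
  items <- matrix(sample(0:6, length(ids) * 22, replace = TRUE),
                  nrow = length(ids),
                  dimnames = list(NULL, sprintf("scat5_%02d", 1:22)))
  dplyr::bind_cols(meta, tibble::as_tibble(items))
}

test_that("SCAT5 severity is the item sum with strict validation", {
  expect_equal(scat5_severity(rep(0L, 22)), 0L)
  expect_equal(scat5_severity(rep(6L, 22)), 132L)
  set.seed(81)
  items <- sample(0:6, 22, replace = TRUE)
  expect_equal(scat5_severity(items), sum(items))
  expect_error(scat5_severity(rep(1, 21)), "22 items")
  expect_error(scat5_severity(c(rep(1, 21), 7)), "0..6")
})

test_that("the assembled biosignal table has exactly the 51-column inventory", {
  ids <- sprintf("S%02d", 1:10)
  meta <- mock_metadata(ids, rep(c("concussion", "non_concussion"), 5))
  wide <- assemble_features(mock_long_features(ids), meta)
  cols <- setdiff(names(wide), c("subject_id", "group"))
  expect_length(cols, 51)
  expect_equal(sum(startsWith(cols, "emg_")), 24)
  expect_equal(sum(startsWith(cols, "eeg_")), 10)
  expect_equal(sum(startsWith(cols, "hr_")), 5)
  expect_equal(sum(startsWith(cols, "cop_")), 12)
  expect_false(anyNA(wide))
})

test_that("assembly errors name subjects with missing modalities", {
  ids <- sprintf("S%02d", 1:4)
  meta <- mock_metadata(ids, rep("concussion", 4))
  long <- mock_long_features(ids)
  # drop one subject's HR rows entirely
  long2 <- dplyr::filter(long, !(subject_id == "S03" & startsWith(feature, "hr_")))
  expect_error(assemble_features(long2, meta), "S03")
  # an NA entropy-like value is imputed by the group median, with a count
  long$value[5] <- NA
  wide <- assemble_features(long, meta)
  expect_false(anyNA(wide))
  expect_equal(attr(wide, "n_imputed"), 1L)
})

test_that("PCA reduction z-scores, projects, and round-trips", {
  set.seed(82)
  X <- tibble::as_tibble(matrix(rnorm(54 * 51), 54, 51,
                                dimnames = list(NULL, paste0("f", 1:51))))
  pc <- pca_reduce(X, 9)
  expect_equal(ncol(pc$scores), 9)
  # orthonormal loadings
  expect_equal(crossprod(pc$rotation), diag(51), tolerance = 1e-9,
               ignore_attr = TRUE)
  # non-increasing explained variance
  expect_true(all(diff(pc$sdev) <= 1e-12))
  # full-rank reconstruction of the z-scored table
  full <- stats::prcomp(as.matrix(X), center = TRUE, scale. = TRUE)
  rec <- full$x %*% t(full$rotation)
  expect_equal(rec, scale(as.matrix(X)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pca_reduce(X[1:5, ], 9), "fewer rows")
  # tidy/glance methods
  td <- tidy(pc)
  expect_equal(nrow(td), 51 * 9)
  expect_equal(glance(pc)$n_components, 9)
})

test_that("feature selections have the documented cardinalities", {
  ids <- sprintf("S%02d", 1:12)
  meta <- mock_metadata(ids, rep(c("concussion", "non_concussion"), 6))
  biosig <- assemble_features(mock_long_features(ids), meta)
  sc5 <- scat5_table(meta)
  s9 <- build_selection(biosig, sc5, "pca9")
  s22 <- build_selection(biosig, sc5, "scat5")
  s31 <- build_selection(biosig, sc5, "combined")
  expect_equal(ncol(s9) - 1, 9)
  expect_equal(ncol(s22) - 1, 22)
  expect_equal(ncol(s31) - 1, 31)
  # SCAT5 columns pass through untouched
  expect_identical(s22[, -1], sc5[, -1])
  # combined = concatenation, column-disjoint
  expect_setequal(names(s31), union(names(s9), names(s22)))
  bad <- sc5; bad$subject_id[1] <- "OTHER"
  expect_error(build_selection(biosig, bad, "pca9"), "different subjects")
})

test_that("well-separated classes reach ceiling accuracy with a linear SVM", {
  set.seed(83)
  n <- 54
  y <- rep(c("concussion", "non_concussion"), c(26, 28))
  X <- matrix(rnorm(n * 9), n, 9)
  X[y == "concussion", 1] <- X[y == "concussion", 1] + 12
  colnames(X) <- paste0("f", 1:9)
  m <- evaluate_classifiers(X, y, models = "svm", seeds = 1:3)
  expect_gte(m$accuracy, 99)
  expect_gte(m$sensitivity, 99)
})

test_that("classifier metrics have the declared schema and pooled identity", {
  set.seed(84)
  n <- 40
  y <- rep(c("concussion", "non_concussion"), each = 20)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[y == "concussion", ] <- X[y == "concussion", ] + 1.2
  m <- evaluate_classifiers(X, y, seeds = 1:2, k = 5)
  expect_equal(nrow(m), 5)
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 100))
  expect_true(all(m$sensitivity >= 0 & m$sensitivity <= 100))
  conf <- attr(m, "confusions")
  # accuracy recomputed from the stored pooled confusion counts
  for (mod in m$model) {
    acc <- mean((conf[mod, , "tp"] + conf[mod, , "tn"]) /
                  rowSums(conf[mod, , ]))
    expect_equal(m$accuracy[m$model == mod], 100 * acc)
    # every fold classified every subject once per seed
    expect_equal(unname(rowSums(conf[mod, , ])), rep(n, 2))
  }
  expect_error(evaluate_classifiers(X, rep("concussion", n), seeds = 1),
               "two classes")
})

test_that("in-fold PCA evaluation uses only the named columns for the PCA", {
  set.seed(85)
  n <- 30
  y <- rep(c("concussion", "non_concussion"), each = 15)
  X <- cbind(matrix(rnorm(n * 6), n, 6), matrix(rnorm(n * 3), n, 3))
  colnames(X) <- c(paste0("bio", 1:6), paste0("q", 1:3))
  X[y == "concussion", 7:9] <- X[y == "concussion", 7:9] + 3
  m <- evaluate_classifiers(X, y, models = "svm", seeds = 1, k = 5,
                            pca_cols = paste0("bio", 1:6), pca_ncomp = 2)
  # the passthrough questionnaire columns carry the signal
  expect_gte(m$accuracy, 90)
})
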
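cfg <- cohort_config()

test_that("SCAT5 draws respect the item range and group severity targets", {
  set.seed(41)
  draws <- replicate(400, generate_scat5("concussion", cfg))
  expect_true(all(draws >= 0 & draws <= 6))
  expect_lt(abs(mean(colSums(draws)) - 36.47), 2)
  draws0 <- replicate(400, generate_scat5("non_concussion", cfg))
  expect_lt(abs(mean(colSums(draws0)) - 3.71), 1)
  expect_equal(cfg$scat5_target_means[["non_concussion"]], 3.71)
})

test_that("CoP generation is deterministic and spectrally calibrated", {
  set.seed(42); a <- generate_cop("concussion", "pre", cfg)
  set.seed(42); b <- generate_cop("concussion", "pre", cfg)
  expect_identical(a$ap$samples, b$ap$samples)
  expect_length(a$ap$samples, 3600)
  expect_equal(a$ap$fs, 90)
  # log-log PSD slope of a single 40-s series near the configured exponent
  set.seed(43)
  sl <- mean(replicate(8, {
    x <- generate_cop("non_concussion", "pre", cfg)
    psd_powerlaw_exponent(x$ap$samples, 90)
  }))
  expect_lt(abs(sl + cfg$cop$alpha_pre), 0.2)
})

test_that("planted sway effect raises POST total excursion for concussion", {
  set.seed(44)
  d <- replicate(40, {
    pre <- generate_cop("concussion", "pre", cfg)
    post <- generate_cop("concussion", "post", cfg)
    tot <- function(s) geometric_features(
      make_stabilogram(s$ap$samples, s$ml$samples, 90))$TOTEX
    tot(post) - tot(pre)
  })
  expect_gt(mean(d), 0)
  expect_gt(mean(d > 0), 0.9)
})

test_that("EEG segments have the declared shape and planted theta gain", {
  set.seed(45)
  e <- generate_eeg("concussion", "post", cfg)
  expect_equal(ncol(e$samples), 64)
  expect_equal(nrow(e$samples), 40 * 1024)
  expect_identical(e$labels, swaylab:::eeg_montage_64)
  # planted theta: POST - PRE relative theta positive on an affected channel
  set.seed(46)
  dtheta <- replicate(25, {
    pre <- generate_eeg("concussion", "pre", cfg)
    post <- generate_eeg("concussion", "post", cfg)
    rel <- function(seg, ch) {
      wp <- welch_psd(seg$samples[1:10240, ch, drop = FALSE], fs = 1024)
      relative_band_powers(wp$freq, wp$psd)[["theta"]]
    }
    c(rel(post, "Fz") - rel(pre, "Fz"), rel(post, "Oz") - rel(pre, "Oz"))
  })
  expect_gt(mean(dtheta[1, ]), 0.02)           # affected channel
  expect_lt(abs(mean(dtheta[2, ])), 0.02)      # unaffected channel ~ null
})

test_that("EMG planted soleus effects are recoverable", {
  set.seed(47)
  e <- generate_emg("non_concussion", "pre", cfg)
  expect_identical(e$labels, c("TA_L", "TA_R", "GL_L", "GL_R", "S_L", "S_R"))
  expect_equal(nrow(e$samples), 40 * 1600)
  # soleus POST/PRE power ratio ~ configured gain
  ratios <- replicate(30, {
    pre <- generate_emg("concussion", "pre", cfg)
    post <- generate_emg("concussion", "post", cfg)
    var(post$samples[, "S_L"]) / var(pre$samples[, "S_L"])
  })
  expect_lt(abs(mean(ratios) - cfg$emg$soleus_post_power_gain),
            0.2 * cfg$emg$soleus_post_power_gain)
  # balance-problem flag shifts right-soleus median frequency in POST
  set.seed(48)
  mdf <- function(x) {
    ps <- power_spectrum(x, 1600)
    spectral_descriptors(ps$freq, ps$power)$median_frequency
  }
  shift <- mean(replicate(15, {
    bp <- generate_emg("concussion", "post", cfg, bp = TRUE)
    nobp <- generate_emg("concussion", "post", cfg, bp = FALSE)
    mdf(bp$samples[, "S_R"]) - mdf(nobp$samples[, "S_R"])
  }))
  expect_lt(abs(shift - cfg$emg$bp_right_soleus_mdf_shift), 4)
})

test_that("heart-rate segments track baseline plus phase offsets", {
  set.seed(49)
  h <- generate_hr("concussion", "post", cfg)
  expect_length(h$samples, 40)
  expect_true(all(h$samples > 0))
  m <- mean(replicate(100, mean(generate_hr("concussion", "post", cfg)$samples)))
  expect_lt(abs(m - (cfg$hr$baseline_bpm + cfg$hr$phase_offsets[["post"]])), 0.5)
  expect_gt(cfg$hr$noise_sd[["concussion"]], cfg$hr$noise_sd[["non_concussion"]])
})

test_that("cohort metadata is deterministic with distinct subject seeds", {
  m1 <- generate_metadata(cfg)
  m2 <- generate_metadata(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 54)
  expect_equal(sum(m1$group == "concussion"), 26)
  expect_equal(sum(m1$group == "non_concussion"), 28)
  expect_equal(sum(m1$bp), 14)
  expect_false(any(duplicated(m1$seed)))
  # balance-problem item consistent with the flag in the concussion group
  bal <- m1[[sprintf("scat5_%02d", cfg$balance_item)]]
  conc <- m1$group == "concussion"
  expect_true(all((bal[conc] > 0) == m1$bp[conc]))
})

test_that("small cohorts regenerate bit-identically, recordings included", {
  small <- cohort_config(n_concussion = 2, n_non_concussion = 2,
                         master_seed = 7)
  b1 <- generate_cohort(small)
  b2 <- generate_cohort(small)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(b1$recordings[["S001"]]$eeg$samples,
                   b2$recordings[["S001"]]$eeg$samples)
  expect_identical(b1$recordings[["S003"]]$cop_ap$samples,
                   b2$recordings[["S003"]]$cop_ap$samples)
  rec <- b1$recordings[["S001"]]
  expect_equal(nrow(rec$eeg$samples), 320 * 1024)
  expect_equal(length(rec$hr$samples), 320)
})

test_that("streamed features equal full-recording features", {
  small <- cohort_config(n_concussion = 1, n_non_concussion = 1,
                         master_seed = 3)
  meta <- generate_metadata(small)[1, ]
  rec <- generate_recording(meta$subject_id, meta$group, meta$bp, small,
                            meta$seed)
  f_full <- extract_subject_features(rec)
  f_str <- stream_subject_features(meta$subject_id, meta$group, meta$bp,
                                   meta$seed, small)
  key <- function(d) dplyr::arrange(d, feature, phase)
  expect_equal(key(f_full), key(f_str))
})
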
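test_that("the FIR band-pass matches its designed frequency response", {
  cfg <- emg_config()
  expect_equal(fir_bandpass(rep(0, 1000), 1600, cfg), rep(0, 1000))
  h <- signal::fir1(50, c(40, 500) / 800, type = "pass")
  gain_at <- function(f) abs(sum(h * exp(-1i * 2 * pi * f / 1600 * (0:50))))
  t <- (0:15999) / 1600
  measured_gain <- function(f) {
    y <- fir_bandpass(sin(2 * pi * f * t), 1600, cfg)
    # steady-state sinusoid amplitude via least squares (transient dropped)
    idx <- 200:15000
    b <- coef(lm(y[idx] ~ sin(2 * pi * f * t[idx]) + cos(2 * pi * f * t[idx]) - 1))
    sqrt(sum(b^2))
  }
  for (f in c(10, 100, 200, 600)) {
    expect_equal(measured_gain(f), gain_at(f), tolerance = 1e-6)
  }
  # 10 Hz stop-band tone at least 10 dB below a 200 Hz pass-band tone
  expect_gt(20 * log10(gain_at(200) / gain_at(10)), 10)
  expect_error(fir_bandpass(rnorm(30), 1600, cfg), "shorter")
})

test_that("band-pass filtering never increases power", {
  set.seed(61)
  cfg <- emg_config()
  for (i in 1:5) {
    x <- rnorm(4000)
    y <- fir_bandpass(x, 1600, cfg)
    expect_lte(sum(y^2), sum(x^2))
  }
})

test_that("rectified area integrates |signal| over time", {
  expect_equal(rectified_area(rep(0, 100), 100), 0)
  t <- (0:1599) / 1600
  expect_equal(rectified_area(sin(2 * pi * 10 * t), 1600), 2 / pi,
               tolerance = 1e-3)
  set.seed(62)
  x <- rnorm(500)
  expect_equal(rectified_area(2 * x, 100), 2 * rectified_area(x, 100))
})

test_that("central window drops symmetric head and tail", {
  x <- seq_len(40 * 1600)
  cw <- central_window(x, 1600, 30)
  expect_length(cw, 48000)
  expect_equal(cw[1], 5 * 1600 + 1)          # 5 s dropped at the head
  expect_equal(cw[48000], 35 * 1600)          # and at the tail
  # odd remainder: head keeps one fewer
  y <- seq_len(11)
  cwy <- central_window(y, 1, 10)
  expect_equal(cwy, 1:10)
  expect_error(central_window(seq_len(100), 1600, 30), "shorter")
})

test_that("the power spectrum is Parseval-consistent and locates tones", {
  t <- (0:7999) / 1600
  ps <- power_spectrum(sin(2 * pi * 100 * t), 1600)
  expect_equal(ps$freq[which.max(ps$power)], 100, tolerance = 0.3)
  set.seed(63)
  x <- rnorm(4096)
  ps2 <- power_spectrum(x, 1600)
  expect_equal(sum(ps2$power), mean((x - mean(x))^2), tolerance = 1e-6)
})

test_that("spectral descriptors use biased moments and cumulative median", {
  # hand-computed: power values 1..5 -> m2 = 2, m3 = 0, m4 = 6.8
  freq <- c(100, 150, 200, 250, 300)
  sd_row <- spectral_descriptors(freq, c(1, 2, 3, 4, 5))
  expect_equal(sd_row$skewness, 0)
  expect_equal(sd_row$kurtosis, 1.7)
  expect_equal(sd_row$total_power, 15)
  # cumulative crossing: 1+2+3+4 = 10 >= 7.5 at 250 Hz
  expect_equal(sd_row$median_frequency, 250)
  # random spectra vs cumulative-sum oracle
  set.seed(64)
  for (i in 1:10) {
    f <- seq(40, 500, by = 2)
    p <- runif(length(f))
    mdf <- spectral_descriptors(f, p)$median_frequency
    expect_equal(mdf, f[which(cumsum(p) >= sum(p) / 2)[1]])
  }
  # mirror symmetry about the band centre
  f <- seq(40, 500, by = 1)
  p <- dnorm(f, 270, 60)
  expect_lt(abs(spectral_descriptors(f, p)$median_frequency - 270), 1.5)
})

test_that("biased moment conventions recover Gaussian reference values", {
  # a large positive Gaussian sample treated as spectrum values: kurtosis
  # (normal = 3 convention) near 3, skewness near 0
  set.seed(65)
  n <- 1e5
  vals <- rnorm(n, mean = 50, sd = 3)
  f <- seq(40, 500, length.out = n)
  sd_row <- spectral_descriptors(f, vals)
  expect_lt(abs(sd_row$kurtosis - 3), 0.2)
  expect_lt(abs(sd_row$skewness), 0.05)
})

test_that("narrowband noise yields a median frequency at its centre", {
  set.seed(66)
  cfg <- cohort_config()
  seg <- generate_emg("non_concussion", "pre", cfg)
  ps <- power_spectrum(central_window(seg$samples[, "GL_L"], 1600, 30), 1600)
  mdf <- spectral_descriptors(ps$freq, ps$power)$median_frequency
  expect_lt(abs(mdf - cfg$emg$center_freq[["GL_L"]]), 5)
})

test_that("per-muscle phase features have the full schema", {
  set.seed(67)
  cfg <- cohort_config()
  rec <- generate_recording("S001", "concussion", FALSE, cfg, 123)
  f <- emg_phase_features(rec, "post")
  expect_equal(nrow(f), 6 * 5)
  expect_setequal(unique(f$feature),
                  c("area", "total_power", "kurtosis", "skewness",
                    "median_frequency"))
  expect_setequal(unique(f$muscle), swaylab:::emg_muscles)
  # degenerate zero channel
  zseg <- signal_matrix(matrix(0, 64000, 6), 1600, swaylab:::emg_muscles)
  fz <- emg_segment_features(zseg)
  expect_equal(fz$value[fz$feature == "area"], rep(0, 6))
  expect_true(all(is.na(fz$value[fz$feature == "median_frequency"])))
})

test_that("heart-rate summaries match a slice-and-average oracle", {
  hr <- channel_series(rep(60, 320), 1, "hr", "bpm")
  hs <- hr_summary(hr)
  expect_equal(nrow(hs), 5)
  expect_equal(hs$mean_bpm, rep(60, 5))
  expect_equal(hs$sd_bpm, rep(0, 5))
  set.seed(68)
  hr2 <- channel_series(rnorm(320, 75, 3), 1, "hr", "bpm")
  hs2 <- hr_summary(hr2)
  expect_equal(hs2$mean_bpm[hs2$phase == "p50"],
               mean(hr2$samples[(200 + 1):240]))
  expect_equal(hs2$sd_bpm[hs2$phase == "post"],
               sd(hr2$samples[(280 + 1):320]))
})
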
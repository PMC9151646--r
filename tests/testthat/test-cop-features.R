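test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  expect_equal(smooth_savgol(rep(5, 30)), rep(5, 30))
  t <- seq_len(50)
  quad <- 0.3 * t^2 - 2 * t + 7
  expect_equal(smooth_savgol(quad, 7, 3), quad, tolerance = 1e-10)
  expect_error(smooth_savgol(rnorm(20), window = 6))
  expect_error(smooth_savgol(rnorm(3), window = 7))
})

test_that("Savitzky-Golay equals the per-window least-squares oracle", {
  set.seed(21)
  x <- rnorm(60)
  sg <- smooth_savgol(x, 7, 3)
  for (i in c(4, 17, 30, 57)) {   # interior points
    expect_equal(sg[i], oracle_savgol_point(x, i, 7, 3), tolerance = 1e-10)
  }
})

test_that("board readings convert to displacement linearly", {
  expect_equal(to_displacement_cm(0.5, 40), 10)
  expect_equal(to_displacement_cm(0, 37), 0)
  expect_equal(to_displacement_cm(0.8, 25), 2 * to_displacement_cm(0.4, 25))
  expect_error(to_displacement_cm(1.2, 40), "\\[-1, 1\\]")
})

test_that("stabilograms are smoothed, centered, and length-preserving", {
  set.seed(22)
  ap <- rnorm(100); ml <- rnorm(100)
  st <- make_stabilogram(ap, ml, fs = 10)
  expect_length(st$ap, 100)
  expect_lt(abs(mean(st$ap)), 1e-9 * sd(st$ap))
  expect_lt(abs(mean(st$ml)), 1e-9 * sd(st$ml))
  expect_equal(st$duration, 10)
  cst <- make_stabilogram(rep(2, 50), rep(-1, 50), fs = 10)
  expect_equal(cst$ap, rep(0, 50))
  expect_error(make_stabilogram(rnorm(10), rnorm(9), 10), "equal length")
})

test_that("geometric features match hand computations", {
  # static point
  g0 <- geometric_features(raw_stab(rep(0, 10), rep(0, 10)))
  expect_true(all(unlist(g0) == 0))
  # closed unit square traversed corner to corner
  sq <- raw_stab(c(0, 0, 1, 1, 0), c(0, 1, 1, 0, 0))
  expect_equal(geometric_features(sq)$TOTEX, 4)
  # two-point AP series {+1, -1}
  two <- raw_stab(c(1, -1), c(0, 0))
  g2 <- geometric_features(two)
  expect_equal(g2$MDIST_AP, 1)
  expect_equal(g2$RDIST, 1)
  expect_equal(g2$ANTERO_MAGNITUDE, 1)
  expect_equal(g2$POSTERO_MAGNITUDE, 1)
  expect_equal(g2$TOTEX_AP, 2)
})

test_that("path-length inequalities hold on random paths", {
  set.seed(23)
  for (i in 1:10) {
    st <- raw_stab(cumsum(rnorm(80)), cumsum(rnorm(80)))
    g <- geometric_features(st)
    straight <- sqrt((st$ap[80] - st$ap[1])^2 + (st$ml[80] - st$ml[1])^2)
    expect_gte(g$TOTEX, straight)
    expect_gte(g$TOTEX, g$TOTEX_AP)
    expect_gte(g$TOTEX, g$TOTEX_ML)
  }
})

test_that("mean velocity is excursion over duration", {
  expect_equal(velocity_features(raw_stab(rep(0, 5), rep(0, 5)))$MVELO, 0)
  # straight 3-cm AP path over 30 s
  st <- raw_stab(seq(0, 3, length.out = 31), rep(0, 31), fs = 1)
  expect_equal(velocity_features(st)$MVELO, 3 / 31)  # 31 samples at 1 Hz
  st30 <- raw_stab(seq(0, 3, length.out = 30), rep(0, 30), fs = 1)
  expect_equal(velocity_features(st30)$MVELO, 0.1)
  set.seed(24)
  rndm <- raw_stab(rnorm(50), rnorm(50), fs = 2)
  v <- velocity_features(rndm)
  expect_equal(v$MVELO * rndm$duration, geometric_features(rndm)$TOTEX)
})

test_that("confidence ellipse recovers planted covariance structure", {
  set.seed(25)
  n <- 10000
  iso <- raw_stab(rnorm(n), rnorm(n))
  ei <- confidence_ellipse(iso)
  expect_lt(abs(ei$ELLIPSE_MAIN_AXIS / ei$ELLIPSE_MINOR_AXIS - 1), 0.05)
  anis <- raw_stab(rnorm(n, sd = 2), rnorm(n, sd = 1))
  ea <- confidence_ellipse(anis)
  expect_lt(abs(ea$ELLIPSE_MAIN_AXIS / ea$ELLIPSE_MINOR_AXIS - 2), 0.1)
  # main axis aligned with AP: orientation near +-pi/2 (angle from ML axis)
  expect_lt(abs(abs(ea$ELLIPSE_ORIENTATION) - pi / 2), 0.1)
  # empirical coverage ~95%
  q <- mahal_cover <- {
    S <- cbind(anis$ml, anis$ap)
    Sig <- crossprod(S) / n
    d2 <- rowSums((S %*% solve(Sig)) * S)
    mean(d2 <= qchisq(0.95, 2))
  }
  expect_lt(abs(q - 0.95), 0.01)
  # internal consistency: area from axes equals pi*sqrt(l1 l2)*chisq quantile
  lam <- eigen(crossprod(cbind(anis$ml, anis$ap)) / n)$values
  expect_equal(ea$ELLIPSE_AREA, pi * sqrt(prod(lam)) * qchisq(0.95, 2),
               tolerance = 1e-9)
})

test_that("degenerate ellipses are handled", {
  col <- raw_stab(seq(0, 1, length.out = 20), 2 * seq(0, 1, length.out = 20))
  ec <- confidence_ellipse(col)
  expect_equal(ec$ELLIPSE_MINOR_AXIS, 0, tolerance = 1e-9)
  expect_equal(ec$ELLIPSE_ORIENTATION, atan2(1, 2), tolerance = 1e-9)
  ez <- confidence_ellipse(raw_stab(rep(0, 5), rep(0, 5)))
  expect_equal(ez$ELLIPSE_MAIN_AXIS, 0)
  expect_error(confidence_ellipse(raw_stab(c(0, 1), c(0, 1))), "3 samples")
})

test_that("heading change measures mean absolute turning", {
  straight <- raw_stab(seq_len(10), 2 * seq_len(10))
  expect_equal(heading_change(straight), 0)
  # right-angle staircase: 90 degrees at every step
  stair <- raw_stab(c(0, 1, 1, 2, 2, 3), c(0, 0, 1, 1, 2, 2))
  expect_equal(heading_change(stair), pi / 2)
  # direct oracle on a random path
  set.seed(26)
  st <- raw_stab(cumsum(rnorm(60)), cumsum(rnorm(60)))
  th <- atan2(diff(st$ml), diff(st$ap))
  dth <- diff(th)
  dth <- ((dth + pi) %% (2 * pi)) - pi
  dth[dth == -pi] <- pi
  expect_equal(heading_change(st), mean(abs(dth)))
})

test_that("spectral power-law exponent recovers planted slopes", {
  set.seed(27)
  sl_white <- mean(replicate(5, psd_powerlaw_exponent(rnorm(3600), 90)))
  expect_lt(abs(sl_white), 0.2)
  sl_15 <- mean(replicate(5, psd_powerlaw_exponent(colored_noise(3600, 1.5), 90)))
  expect_lt(abs(sl_15 + 1.5), 0.2)
})

test_that("power-law fit equals an independent log-log regression", {
  set.seed(28)
  x <- colored_noise(1800, 1)
  pg <- periodogram_psd(x, 90)
  sel <- pg$freq >= 0.1 & pg$freq <= 5
  fit <- unname(coef(lm(log10(pg$psd[sel]) ~ log10(pg$freq[sel])))[2])
  expect_equal(psd_powerlaw_exponent(x, 90), fit)
  expect_error(psd_powerlaw_exponent(rnorm(20), 90, fit_band = c(0.1, 0.2)),
               "fewer than 5")
})

test_that("periodogram integrates to the signal variance", {
  set.seed(29)
  x <- rnorm(4096)
  pg <- periodogram_psd(x, 128)
  df <- pg$freq[2] - pg$freq[1]
  expect_equal(sum(pg$psd) * df, var(x) * (4095 / 4096), tolerance = 0.01)
})

test_that("the full battery matches individually called operations", {
  set.seed(30)
  ap <- cumsum(rnorm(720)); ml <- cumsum(rnorm(720))
  st <- make_stabilogram(ap, ml, fs = 90)
  f <- cop_features(st)
  expect_setequal(f$feature, swaylab:::cop_feature_names)
  expect_equal(nrow(f), 28)
  v <- function(nm) f$value[f$feature == nm]
  expect_equal(v("TOTEX"), geometric_features(st)$TOTEX)
  expect_equal(v("MVELO"), velocity_features(st)$MVELO)
  expect_equal(v("ELLIPSE_AREA"), confidence_ellipse(st)$ELLIPSE_AREA)
  expect_equal(v("HEADING_CHANGE"), heading_change(st))
  expect_equal(v("SAMPEN_AP"), sample_entropy(st$ap))
  expect_equal(v("CI_ML"), complexity_index(st$ml)$ci)
  expect_equal(v("PSD_EXP_AP"), psd_powerlaw_exponent(st$ap, 90))
})

test_that("a static recording yields the degenerate battery", {
  st <- make_stabilogram(rep(1, 200), rep(1, 200), fs = 10)
  f <- cop_features(st)
  v <- function(nm) f$value[f$feature == nm]
  expect_equal(v("TOTEX"), 0)
  expect_equal(v("MVELO"), 0)
  expect_equal(v("ELLIPSE_MAIN_AXIS"), 0)
  expect_equal(v("SAMPEN_AP"), 0)
  expect_equal(v("CI_MULTI"), 0)
  expect_true(all(is.finite(f$value)))
})

test_that("features are invariant under mean translation", {
  set.seed(31)
  ap <- cumsum(rnorm(300)); ml <- cumsum(rnorm(300))
  f1 <- cop_features(make_stabilogram(ap, ml, 30),
                     include = c("geometric", "velocity", "ellipse"))
  f2 <- cop_features(make_stabilogram(ap + 100, ml - 12, 30),
                     include = c("geometric", "velocity", "ellipse"))
  expect_equal(f1$value, f2$value)
})
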
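test_that("sample entropy matches a brute-force template-counting oracle", {
  x <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2, 3, 2)
  expect_equal(sample_entropy(x, m = 2, r = 0.5),
               sampen_oracle(x, m = 2, r = 0.5), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:10) {
    y <- stats::rnorm(60)
    expect_equal(sample_entropy(y), sampen_oracle(y), tolerance = 1e-10)
  }
})

test_that("sample entropy handles degenerate inputs", {
  expect_equal(sample_entropy(rep(3, 50)), 0)
  expect_error(sample_entropy(c(1, 2)), "short")
})

test_that("Shannon entropy equals the direct histogram computation", {
  expect_equal(shannon_entropy(rep(1, 100)), 0)
  # exactly uniform over 16 bins -> 4 bits
  x <- rep(seq(0.5, 15.5), each = 10) / 16
  expect_equal(shannon_entropy(x, n_bins = 16), 4)
  set.seed(2)
  y <- stats::rnorm(100)
  cuts <- seq(min(y), max(y), length.out = 65)
  cnt <- table(cut(y, cuts, include.lowest = TRUE))
  p <- cnt[cnt > 0] / 100
  expect_equal(shannon_entropy(y), -sum(p * log2(p)), tolerance = 1e-10)
  expect_error(shannon_entropy(1:10, n_bins = 64), "shorter")
})

test_that("spectral entropy separates tones, noise and mixtures", {
  tone <- fixture_signals("sinusoid", list(freq = 100, dur_s = 2.5))
  se_tone <- spectral_entropy(tone)
  expect_lt(se_tone, 0.25)
  noise <- fixture_signals("white-noise", list(dur_s = 2^15 / 2000), seed = 3)
  se_noise <- spectral_entropy(noise)
  expect_gt(se_noise, 0.9)
  mix <- tone + fixture_signals("white-noise",
                                list(sd = sqrt(mean(tone^2)), dur_s = 2.5),
                                seed = 4)
  se_mix <- spectral_entropy(mix)
  expect_true(se_tone < se_mix && se_mix < se_noise)
  expect_true(is.na(spectral_entropy(rep(0, 300))))
})

test_that("LZ76 parsing matches the manual exhaustive-history oracle", {
  bits <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(lz76_phrases(bits), lz76_oracle(bits))
  expect_equal(lz76_phrases(bits), 6L)
  expect_equal(lz76_phrases(rep(0, 64)), lz76_oracle(rep(0, 64)))
  set.seed(5)
  for (i in 1:10) {
    b <- stats::rbinom(40, 1, 0.5)
    expect_equal(lz76_phrases(b), lz76_oracle(b))
  }
})

test_that("normalized LZ complexity of random sequences is near 1", {
  set.seed(6)
  x <- sample(c(-1, 1), 10000, replace = TRUE)
  expect_gt(lz_complexity(x), 0.8)
  expect_lt(lz_complexity(x), 1.2)
  expect_error(lz_complexity(1:8), "short")
})

test_that("Higuchi dimension recovers the smooth and white-noise limits", {
  expect_lt(abs(fractal_dimension(seq(0, 1, length.out = 2000)) - 1), 0.1)
  set.seed(7)
  expect_lt(abs(fractal_dimension(stats::rnorm(10000)) - 2), 0.15)
  expect_true(is.na(fractal_dimension(rep(1, 500))))
})

test_that("time-reversal and scaling invariances hold where required", {
  set.seed(8)
  for (i in 1:5) {
    x <- stats::rnorm(400)
    xr <- rev(x)
    # boundary templates make sample entropy only asymptotically symmetric
    expect_equal(sample_entropy(x), sample_entropy(xr), tolerance = 5e-3)
    expect_equal(shannon_entropy(x), shannon_entropy(xr), tolerance = 1e-10)
    expect_equal(lz_complexity(x), lz_complexity(xr), tolerance = 0.15)
    expect_equal(spectral_entropy(x), spectral_entropy(rev(x)),
                 tolerance = 0.05)
    # amplitude-scaling invariance
    expect_equal(shannon_entropy(3 * x), shannon_entropy(x),
                 tolerance = 1e-10)
    expect_equal(spectral_entropy(3 * x), spectral_entropy(x),
                 tolerance = 1e-10)
  }
})

test_that("welch PSD of white noise is flat at the right level", {
  set.seed(9)
  x <- stats::rnorm(2^15)
  ps <- welch_psd(x, fs = 2000)
  # total power integrates to the variance
  expect_equal(sum(ps$psd) * (2000 / 256), var(x), tolerance = 0.05)
})

test_that("feature extraction averages per segment and spans clusters", {
  x <- fixture_signals("biphasic-train",
                       list(onsets_ms = c(500, 1700), noise_sd = 0.005),
                       seed = 10)
  segs <- detect_activity(x)
  f <- extract_features(x, segs)
  expect_s3_class(f, "data.frame")
  expect_named(f, feature_names())
  expect_true(all(is.finite(unlist(f))))
  # one segment passes through unchanged
  one <- segs[1, , drop = FALSE]
  f1 <- extract_features(x, one)
  expect_equal(f1$p2p, peak_to_peak(x, one))
  expect_equal(f1$duration, one$duration_ms)
  # p2p is homogeneous of degree 1
  f2 <- extract_features(2 * x, detect_activity(2 * x))
  expect_equal(f2$p2p, 2 * f$p2p, tolerance = 1e-6)
  # no segments -> unusable
  expect_null(extract_features(x, segs[0, ]))
})
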
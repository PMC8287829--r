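test_that("blanking returns the complement of guarded activity windows", {
  x <- seq_len(5000) / 5000
  segs <- data.frame(start = c(600, 1600, 2600, 3600),
                     end = c(700, 1700, 2700, 3700))
  runs <- blank_activity(x, segs, min_len = 100)
  expect_length(runs, 5)
  guard <- 20  # 10 ms at 2 kHz
  expect_equal(sum(lengths(runs)), 5000 - 4 * (100 + 2 * guard))
  # fully covered trace -> nothing left
  expect_length(blank_activity(x, data.frame(start = 0, end = 5000)), 0)
  # no activity -> the whole trace as one run
  all_of_it <- blank_activity(x, segs[0, ])
  expect_length(all_of_it, 1)
  expect_equal(all_of_it[[1]], x)
  expect_error(blank_activity(x, data.frame(start = 0, end = 6000)),
               "bounds")
})

test_that("per-segment AR fits recover a known model and its order", {
  truth <- ar_model(c(0.5, -0.25), 1)
  x <- generate_noise(truth, 10000, seed = 1)
  fit <- fit_ar_segment(x, max_order = 8)
  expect_equal(fit$order, 2)
  expect_lt(max(abs(fit$phi - truth$phi)), 0.05)
  # white noise: whatever order BIC picks, coefficients are near zero
  set.seed(2)
  w <- stats::rnorm(5000)
  fw <- fit_ar_segment(w, max_order = 8)
  expect_lt(max(abs(fw$phi)), 0.05)
  expect_error(fit_ar_segment(rep(1, 1000), 8), "degenerate")
  expect_error(fit_ar_segment(stats::rnorm(50), 20), "short")
})

test_that("the global model pools segments by summed AIC and averages fits", {
  truth <- ar_model(c(0.6, -0.3, 0.15), 0.5)
  segs <- lapply(1:13, function(s) generate_noise(truth, 4000, seed = s))
  gm <- build_global_model(segs, max_order = 6)
  expect_equal(gm$order, 3)
  expect_lt(max(abs(gm$phi - truth$phi)), 0.05)
  expect_false(gm$stabilized)
  expect_equal(gm$n_segments, 13)
  # two identical segments: global model = per-segment fit at the global order
  x <- generate_noise(truth, 5000, seed = 99)
  gm2 <- build_global_model(list(x, x), max_order = 6)
  per <- fibroegm:::ar_fit_order(x, gm2$order)
  expect_equal(gm2$phi, per$phi, tolerance = 1e-12)
  expect_error(build_global_model(list(x), 6), "2 usable")
})

test_that("non-stationary averages are stabilized by root shrinkage", {
  st <- fibroegm:::stabilize_ar(c(1.2, 0.1))  # root outside the unit circle
  expect_true(st$stabilized)
  expect_true(all(Mod(fibroegm:::ar_roots(st$phi)) <= 0.99 + 1e-9))
  # already-stable coefficients pass through untouched
  st2 <- fibroegm:::stabilize_ar(c(0.5, -0.25))
  expect_false(st2$stabilized)
  expect_equal(st2$phi, c(0.5, -0.25))
})

test_that("generated noise matches the AR transfer-function spectrum", {
  model <- ar_model(c(0.5, -0.25), 1)
  x <- generate_noise(model, 2^16, seed = 5)
  # zero mean within 3 standard errors
  expect_lt(abs(mean(x)), 3 * stats::sd(x) / sqrt(length(x)))
  ps <- welch_psd(x, fs = 1, nseg = 256)
  theo <- ar_spectrum(model, ps$freq)
  mid <- ps$freq > 0.05 & ps$freq < 0.45
  db_err <- 10 * abs(log10(ps$psd[mid] * 0.5) - log10(theo[mid]))
  expect_lt(mean(db_err), 1)
  expect_equal(generate_noise(ar_model(0.5, 0), 100), rep(0, 100))
  expect_identical(generate_noise(model, 500, seed = 7),
                   generate_noise(model, 500, seed = 7))
  expect_error(generate_noise(ar_model(c(1.1), 1), 100), "stationary")
})

test_that("noise injection hits the requested SNR exactly", {
  t <- (seq_len(5000) - 1) / 2000
  x <- sin(2 * pi * 80 * t)  # unit power 0.5
  model <- reference_noise_process()
  y <- add_noise(x, model, 20, seed = 1)
  expect_equal(mean((y - x)^2) / mean(x^2), 0.01, tolerance = 0.02)
  expect_lt(abs(measure_snr(x, y) - 20), 0.5)
  expect_identical(add_noise(x, model, 20, seed = 3),
                   add_noise(x, model, 20, seed = 3))
  expect_identical(add_noise(x, model, Inf), x)
  expect_error(add_noise(rep(0, 100), model, 20), "zero power")
})

test_that("AR models survive a JSON round trip", {
  gm <- ar_model(c(0.4, -0.2, 0.05), 0.123)
  path <- tempfile(fileext = ".json")
  write_ar_model(gm, path)
  back <- read_ar_model(path)
  expect_equal(back$phi, gm$phi)
  expect_equal(back$sigma2, gm$sigma2)
  expect_equal(back$order, gm$order)
})

test_that("AR parameter recovery holds across random stable models", {
  set.seed(31)
  for (i in 1:3) {
    p <- sample(2:4, 1)
    repeat {
      phi <- stats::runif(p, -0.4, 0.4)
      if (all(Mod(fibroegm:::ar_roots(phi)) < 0.9)) break
    }
    truth <- ar_model(phi, 1)
    segs <- lapply(1:10, function(s)
      generate_noise(truth, 10000, seed = i * 100 + s))
    gm <- build_global_model(segs, max_order = 6)
    expect_lt(max(abs(gm$phi[seq_len(p)] - phi)), 0.05)
  }
})
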
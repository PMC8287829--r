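test_that("dice index satisfies its identities", {
  expect_equal(dice_index(1:3, 1:3), 1)
  expect_equal(dice_index(1:3, 4:6), 0)
  expect_equal(dice_index(c(1, 2, 3), c(2, 3, 4)), 4 / 6)
  expect_equal(dice_index(integer(0), integer(0)), 1)
  expect_equal(dice_index(1:3, integer(0)), 0)
  # symmetry and bounds on random sets
  set.seed(1)
  for (i in 1:10) {
    a <- sample(20, sample(10, 1))
    b <- sample(20, sample(10, 1))
    d <- dice_index(a, b)
    expect_equal(d, dice_index(b, a))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("voltage labels follow the strict 0.5 mV rule", {
  pts <- data.frame(p2p = c(0.49, 0.51, 0.5, 0))
  lab <- voltage_labels(pts)
  expect_equal(as.character(lab$voltage), c("low", "high", "high", "low"))
  expect_true(all(voltage_labels(pts, cutoff_mv = 0)$voltage == "high"))
  expect_error(voltage_labels(data.frame(x = 1)), "p2p")
})

test_that("map specs reject overlapping patches", {
  expect_error(map_spec(patches = list(
    list(center = c(10, 10), radius = 5, density = 0.6, depth = 2),
    list(center = c(14, 10), radius = 5, density = 0.2, depth = 1))),
    "overlap")
  ok <- map_spec(patches = list(
    list(center = c(8, 8), radius = 4, density = 0.6, depth = 2),
    list(center = c(25, 25), radius = 4, density = 0.2, depth = 1)))
  expect_s3_class(ok, "map_spec")
})

test_that("fixture signals are deterministic and analytically exact", {
  s <- fixture_signals("sinusoid", list(freq = 100, amp = 2, dur_s = 2.5))
  expect_length(s, 5000)
  t <- (seq_len(5000) - 1) / 2000
  expect_equal(s, 2 * sin(2 * pi * 100 * t))
  expect_identical(fixture_signals("white-noise", seed = 5),
                   fixture_signals("white-noise", seed = 5))
  bt <- fixture_signals("biphasic-train", seed = 6)
  expect_s3_class(attr(bt, "truth"), "data.frame")
  expect_equal(nrow(attr(bt, "truth")), 4)
  expect_error(fixture_signals("nope"), "arg")
})

test_that("trace and feature files round-trip through disk", {
  m <- matrix(stats::rnorm(200), 50, 4,
              dimnames = list(NULL, c("A1", "A2", "A3", "A4")))
  p <- tempfile(fileext = ".tsv")
  write_traces(m, p)
  back <- read_traces(p)
  expect_equal(unname(back[, ]), unname(m), tolerance = 1e-8)
  expect_equal(colnames(back), colnames(m))
  expect_equal(attr(back, "fs"), 2000)

  df <- data.frame(duration = 1:3, p2p = c(0.1, 0.5, 2), samp_en = 0.2,
                   sh_en = 4, sp_en = 0.5, lz = 0.4, fd = 1.5,
                   density = c(0, 0.2, 0.6),
                   transmural_depth = c(0, 1, 2))
  df <- label_samples(df)
  pf <- tempfile(fileext = ".csv")
  write_features(df, pf)
  back2 <- read_features(pf)
  expect_equal(back2$label_density, df$label_density)
  expect_equal(back2$p2p, df$p2p)
})

test_that("segment tables pair every segment with its amplitude", {
  x <- fixture_signals("biphasic-train", seed = 2)
  segs <- detect_activity(x)
  tab <- segments_table(cbind(b1 = x), list(segs))
  expect_equal(nrow(tab), nrow(segs))
  expect_equal(tab$duration_ms, segs$duration_ms)
  expect_true(all(tab$p2p_mv > 0))
})

test_that("synthetic maps carry ground truth and support Dice scoring", {
  cfg <- study_config()
  cfg$spacing <- 0.4
  cfg$dt <- 0.1
  spec <- map_spec(extent_mm = c(30, 30), n_grid = 6, patches = list(
    list(center = c(10, 10), radius = 7, density = 0.6, depth = 2)))
  map <- generate_synthetic_map(spec, seed = 2, cfg = cfg, quiet = TRUE)
  pts <- map$points
  expect_equal(nrow(pts), 36)
  inside <- (pts$x - 10)^2 + (pts$y - 10)^2 <= 49
  expect_true(all(pts$label_binary[inside] == "fibrotic"))
  expect_true(all(pts$label_binary[!inside] == "non-fibrotic"))
  # determinism
  map2 <- generate_synthetic_map(spec, seed = 2, cfg = cfg, quiet = TRUE)
  expect_equal(map2$points$p2p, pts$p2p)
  # fibrotic points show longer activity than control points (stochastic)
  expect_gt(mean(pts$duration[inside & pts$usable]),
            mean(pts$duration[!inside & pts$usable]))
  # a tree trained on half the points recovers the rest
  train_idx <- seq(1, 36, by = 2)
  m <- train_tree(pts[train_idx, ], c("duration", "p2p", "samp_en"),
                  "binary")
  pred <- predict_map(m, map)
  expect_true(all(!is.na(pred$points$predicted[pred$points$usable])))
  expect_gt(map_dice(pred, "prediction"), 0.5)
  d_v <- map_dice(pred, "voltage")
  expect_true(d_v >= 0 && d_v <= 1)
  # round trip through the map file format
  p <- tempfile(fileext = ".tsv")
  write_map(pred, p)
  back <- read_map(p)
  expect_equal(back$points$p2p, pred$points$p2p, tolerance = 1e-6)
  expect_equal(back$points$label_density, pred$points$label_density)
  expect_error(predict_map(m, structure(list(points = pts[0, ]),
                                        class = "substrate_map")), "empty")
})

test_that("control-substitute fixtures are high-voltage by construction", {
  subs <- fixture_signals("control-substitute", list(n = 10), seed = 4)
  expect_gte(length(subs), 5)
  p2p <- vapply(subs, function(x) attr(x, "p2p"), numeric(1))
  expect_true(all(p2p > 0.5))
  expect_length(subs[[1]], 5000)
})
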
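# A synthetic labeled feature table with controllable class separation:
# each class c gets feature means c * effect on the first two features.
synthetic_features <- function(n_per_class = 40, classes = c(0, 0.4),
                               effect = 3, sd = 1, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(ci) {
    d <- as.data.frame(matrix(stats::rnorm(n_per_class * 7, sd = sd),
                              ncol = 7))
    names(d) <- feature_names()
    d$duration <- d$duration + ci * effect
    d$samp_en <- d$samp_en + ci * effect
    d$density <- classes[ci]
    d$transmural_depth <- ifelse(classes[ci] > 0, 2, 0)
    d
  })
  label_samples(do.call(rbind, rows))
}

test_that("labels are derived consistently from substrate parameters", {
  df <- synthetic_features()
  expect_true(all((df$label_binary == "fibrotic") == (df$density > 0)))
  bad <- data.frame(density = 0.2, transmural_depth = 0)
  expect_error(label_samples(bad), "inconsistent")
})

test_that("dataset assembly keeps provenance and guards labels", {
  sim <- synthetic_features(seed = 1)
  sub <- synthetic_features(n_per_class = 10, classes = 0, seed = 2)
  sub$provenance <- "control-substitute"
  ds <- assemble_dataset(sim, sub)
  expect_equal(nrow(ds), nrow(sim) + nrow(sub))
  expect_setequal(unique(ds$provenance),
                  c("simulated", "control-substitute"))
  only <- assemble_dataset(sim, NULL)
  expect_true(isTRUE(attr(only, "simulated_only")))
  bad_sub <- synthetic_features(n_per_class = 6, classes = c(0, 0.2),
                                seed = 3)
  expect_error(assemble_dataset(sim, bad_sub), "non-fibrotic")
})

test_that("stratified splits have the right sizes and determinism", {
  df <- synthetic_features(n_per_class = 50)
  sp <- split_dataset(df, "binary", seed = 4)
  expect_equal(nrow(sp$val), 14)   # floor(0.15 * 50) per class
  expect_equal(nrow(sp$test), 14)
  expect_equal(nrow(sp$train), 72)
  for (part in sp)
    expect_setequal(unique(as.character(part$label_binary)),
                    c("non-fibrotic", "fibrotic"))
  sp2 <- split_dataset(df, "binary", seed = 4)
  expect_identical(rownames(sp$train), rownames(sp2$train))
  tiny <- df[c(1:2, 51:100), ]
  expect_error(split_dataset(tiny, "binary"), "at least 3")
})

test_that("trees separate a threshold dataset with a single split", {
  df <- synthetic_features(effect = 50, sd = 0.1)
  m <- train_tree(df, "duration", "binary")
  expect_equal(nrow(m$tree$frame), 3)  # root + two leaves = depth 1
  ev <- evaluate_model(m, df)
  expect_equal(ev$accuracy, 100)
  # conflicting duplicate rows cannot reach 100%
  conf <- df[rep(1, 20), ]
  conf$label_binary <- factor(rep(c("fibrotic", "non-fibrotic"), 10),
                              levels = levels(df$label_binary))
  m2 <- train_tree(conf, "duration", "binary")
  expect_lt(evaluate_model(m2, conf)$accuracy, 100)
  expect_error(train_tree(df[df$density == 0, ], "duration", "binary"),
               "single class")
})

test_that("confusion-matrix metrics match hand-computed definitions", {
  cm <- matrix(c(8, 1, 2, 9), 2,
               dimnames = list(c("non-fibrotic", "fibrotic"),
                               c("non-fibrotic", "fibrotic")))
  met <- confusion_metrics(as.table(cm), binary = TRUE)
  expect_equal(met$accuracy, 85)
  expect_equal(met$sensitivity, 90)
  expect_equal(met$specificity, 80)
  # perfect predictions
  perfect <- as.table(diag(c(5, 7)))
  dimnames(perfect) <- list(c("a", "b"), c("a", "b"))
  expect_equal(confusion_metrics(perfect)$accuracy, 100)
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))
})

test_that("greedy selection picks the informative feature and prunes twins", {
  df <- synthetic_features(n_per_class = 60, effect = 10, sd = 0.5, seed = 5)
  # make samp_en a duplicate of duration (perfect correlation)
  df$samp_en <- df$duration
  sp <- split_dataset(df, "binary", seed = 1)
  sel <- greedy_select(sp$train, sp$val, "binary")
  expect_equal(sel[1], "duration")  # canonical order breaks the tie
  expect_false(all(c("duration", "samp_en") %in% sel))
  # pairwise correlation of the selection stays below the threshold
  if (length(sel) > 1)
    expect_lt(max(abs(stats::cor(sp$train[sel]))[
      upper.tri(diag(length(sel)))]), 0.6 + 1e-9)
})

test_that("pure-noise features stop selection near chance", {
  df <- synthetic_features(n_per_class = 60, effect = 0, seed = 6)
  sp <- split_dataset(df, "binary", seed = 2)
  sel <- greedy_select(sp$train, sp$val, "binary")
  expect_lte(length(sel), 2)
})

test_that("repeated holdout is exact on separable data and chance on permuted labels", {
  df <- synthetic_features(n_per_class = 40, effect = 50, sd = 0.1)
  rep1 <- repeated_holdout(df, "binary", n_realizations = 3, base_seed = 1)
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$accuracy_se, 0)
  # label permutation nulls the whole pipeline
  set.seed(9)
  perm <- df
  sh <- sample(nrow(perm))
  perm$label_binary <- perm$label_binary[sh]
  perm$density <- perm$density[sh]
  perm$transmural_depth <- perm$transmural_depth[sh]
  rep0 <- repeated_holdout(perm, "binary", n_realizations = 20,
                           base_seed = 2)
  expect_lt(abs(rep0$accuracy - 50),
            3 * max(stats::sd(rep0$per_realization$accuracy) /
                      sqrt(20), 2))
})

test_that("task subsets vary one substrate characteristic at a time", {
  df <- rbind(
    synthetic_features(classes = c(0, 0.1, 0.6), seed = 7),
    within(synthetic_features(classes = 0.6, seed = 8),
           transmural_depth <- 0.5))
  dsub <- task_subset(df, "density")
  expect_true(all(dsub$transmural_depth[dsub$density > 0] == 2))
  tsub <- task_subset(df, "transmurality")
  expect_true(all(tsub$density[tsub$density > 0] == 0.6))
  expect_equal(nrow(task_subset(df, "binary")), nrow(df))
})

test_that("height sweep requires samples at each height and is evaluated per height", {
  df <- synthetic_features(n_per_class = 30, effect = 20, sd = 0.5)
  df$height <- rep(c(0, 1, 2), length.out = nrow(df))
  m <- train_tree(df[df$height == 0, ], c("duration", "samp_en"), "binary")
  tab <- height_sweep(m, df, heights = c(0, 1, 2))
  expect_equal(tab$height, c(0, 1, 2))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  expect_error(height_sweep(m, df, heights = c(1, 0)), "ascending")
  expect_error(height_sweep(m, df, heights = c(0, 5)), "no sweep samples")
})
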
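task_column <- function(task = c("binary", "density", "transmurality")) {
  task <- match.arg(task)
  switch(task, binary = "label_binary", density = "label_density",
         transmurality = "label_transmurality")
}

BINARY_LEVELS <- c("non-fibrotic", "fibrotic")
DENSITY_LEVELS <- c("none", "10", "20", "40", "60")
TRANSMURALITY_LEVELS <- c("none", "0.5", "1", "2")

#' Label a feature table
#'
#' Attaches the three task labels from density/transmurality condition
#' columns and validates their consistency (density `none` if and only if
#' non-fibrotic if and only if transmurality `none`).
#'
#' @param df Feature table with numeric `density` (fraction, 0 for control)
#'   and `transmural_depth` (mm, 0 for control) columns.
#' @return The table with `label_binary`, `label_density`,
#'   `label_transmurality` factor columns.
#' @export
label_samples <- function(df) {
  fib <- df$density > 0
  if (any(fib != (df$transmural_depth > 0)))
    stop("inconsistent labels: density and transmurality must agree on control")
  df$label_binary <- factor(ifelse(fib, "fibrotic", "non-fibrotic"),
                            levels = BINARY_LEVELS)
  df$label_density <- factor(ifelse(fib, as.character(round(df$density * 100)),
                                    "none"), levels = DENSITY_LEVELS)
  df$label_transmurality <- factor(
    ifelse(fib, sub("\\.?0+$", "", formatC(df$transmural_depth, format = "fg")),
           "none"), levels = TRANSMURALITY_LEVELS)
  df
}

#' Assemble the study dataset
#'
#' Concatenates simulated fibrotic/control samples with control-substitute
#' samples (the stand-ins for clinical high-voltage non-fibrotic signals),
#' keeping provenance. Substitutes must be labeled non-fibrotic.
#'
#' @param simulated Labeled feature table from the simulator.
#' @param substitutes Labeled feature table of control substitutes (may have
#'   zero rows, in which case the dataset is simulated-only and flagged).
#' @return Combined labeled table with a `provenance` column.
#' @export
assemble_dataset <- function(simulated, substitutes = NULL) {
  need <- c(feature_names(), "label_binary", "label_density",
            "label_transmurality")
  if (!all(need %in% names(simulated))) stop("simulated table: schema mismatch")
  if (is.null(substitutes) || nrow(substitutes) == 0) {
    simulated$provenance <- simulated$provenance %||% "simulated"
    attr(simulated, "simulated_only") <- TRUE
    return(simulated)
  }
  if (!all(need %in% names(substitutes)))
    stop("substitute table: schema mismatch")
  if (any(substitutes$label_binary != "non-fibrotic"))
    stop("control substitutes must be non-fibrotic")
  simulated$provenance <- simulated$provenance %||% "simulated"
  substitutes$provenance <- substitutes$provenance %||% "control-substitute"
  common <- intersect(names(simulated), names(substitutes))
  rbind(simulated[common], substitutes[common])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/validation/test split
#'
#' Random partition at the given fractions, stratified by the task label,
#' rounding toward the training set; every class is guaranteed to appear in
#' every subset.
#'
#' @param df Labeled feature table.
#' @param task Classification task.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` data frames.
#' @export
split_dataset <- function(df, task = "binary", fractions = c(0.7, 0.15, 0.15),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  lab <- df[[task_column(task)]]
  tab <- table(lab)
  if (any(tab[tab > 0] < 3))
    stop("every class needs at least 3 samples for a 3-way split")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx_val <- integer(0); idx_test <- integer(0)
  for (cl in names(tab[tab > 0])) {
    rows <- sample(which(lab == cl))
    n <- length(rows)
    nv <- max(1L, floor(fractions[2] * n))
    nt <- max(1L, floor(fractions[3] * n))
    idx_val <- c(idx_val, rows[seq_len(nv)])
    idx_test <- c(idx_test, rows[nv + seq_len(nt)])
  }
  list(train = df[-c(idx_val, idx_test), , drop = FALSE],
       val = df[idx_val, , drop = FALSE],
       test = df[idx_test, , drop = FALSE])
}

#' Train a decision tree on selected features
#'
#' Axis-aligned binary-split classification tree (Gini impurity, no depth
#' cap, minimum leaf size 3, deterministic splits).
#'
#' @param train Labeled training table.
#' @param features Character vector of feature columns to use.
#' @param task Classification task.
#' @return An object of class `trained_model` (tree, features, task).
#' @export
train_tree <- function(train, features, task = "binary") {
  if (length(features) == 0) stop("no features supplied")
  col <- task_column(task)
  y <- droplevels(train[[col]])
  if (nlevels(y) < 2) stop("training set contains a single class")
  d <- train[, features, drop = FALSE]
  d$.y <- y
  tree <- rpart::rpart(.y ~ ., data = d, method = "class",
                       control = rpart::rpart.control(
                         minbucket = 3, cp = 0, xval = 0,
                         maxcompete = 0, maxsurrogate = 0))
  structure(list(tree = tree, features = features, task = task,
                 levels = levels(y)), class = "trained_model")
}

predict_labels <- function(model, newdata) {
  as.character(predict(model$tree,
                       newdata = newdata[, model$features, drop = FALSE],
                       type = "class"))
}

#' Evaluate a trained model on a test set
#'
#' Confusion matrix (rows = truth), accuracy, and sensitivity/specificity:
#' for the binary task with "fibrotic" as the positive class; for multiclass
#' tasks macro-averaged one-vs-rest.
#'
#' @param model A `trained_model`.
#' @param test Labeled test table.
#' @return List with `confusion`, `accuracy`, `sensitivity`, `specificity`
#'   (all percentages).
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test) == 0) stop("empty test set")
  col <- task_column(model$task)
  truth <- as.character(test[[col]])
  if (!all(truth %in% model$levels))
    stop("test set contains a class unseen in training")
  pred <- predict_labels(model, test)
  lev <- model$levels
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  confusion_metrics(cm, binary = model$task == "binary")
}

#' Metrics from a confusion matrix
#'
#' Accuracy plus sensitivity/specificity: with `binary = TRUE` the
#' "fibrotic" row is the positive class; otherwise macro-averaged
#' one-vs-rest over all classes.
#'
#' @param cm Square confusion matrix, rows = truth, columns = prediction.
#' @param binary Binary-task convention (fibrotic positive)?
#' @return List with `confusion`, `accuracy`, `sensitivity`, `specificity`
#'   (percentages).
#' @export
confusion_metrics <- function(cm, binary = FALSE) {
  acc <- 100 * sum(diag(cm)) / sum(cm)
  lev <- rownames(cm)
  if (binary) {
    tp <- cm["fibrotic", "fibrotic"]; fn <- cm["fibrotic", "non-fibrotic"]
    tn <- cm["non-fibrotic", "non-fibrotic"]
    fp <- cm["non-fibrotic", "fibrotic"]
    sens <- 100 * tp / (tp + fn)
    spec <- 100 * tn / (tn + fp)
  } else {
    per <- vapply(lev, function(cl) {
      tp <- cm[cl, cl]; fn <- sum(cm[cl, ]) - tp
      fp <- sum(cm[, cl]) - tp
      tn <- sum(cm) - tp - fn - fp
      c(sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        spec = tn / (tn + fp))
    }, numeric(2))
    sens <- 100 * mean(per["sens", ], na.rm = TRUE)
    spec <- 100 * mean(per["spec", ], na.rm = TRUE)
  }
  list(confusion = cm, accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Greedy forward feature selection with correlation pruning
#'
#' Starts from an empty set; in each round, candidates with absolute Pearson
#' correlation above `corr_threshold` (on the training set) to any selected
#' feature are dropped, and the candidate maximizing validation accuracy of
#' a tree trained on the training set is added. Selection stops when no
#' candidate strictly improves validation accuracy. Ties are broken by the
#' canonical feature order.
#'
#' @param train,val Labeled train and validation tables.
#' @param task Classification task.
#' @param corr_threshold Correlation pruning threshold (default 0.6).
#' @param features Candidate features (default the seven study features).
#' @return Ordered character vector of selected features.
#' @export
greedy_select <- function(train, val, task = "binary", corr_threshold = 0.6,
                          features = feature_names()) {
  if (length(features) == 0) stop("no candidate features")
  selected <- character(0)
  best_acc <- -Inf
  repeat {
    cands <- setdiff(features, selected)
    if (length(selected) > 0 && length(cands) > 0) {
      keep <- vapply(cands, function(f) {
        all(abs(stats::cor(train[[f]], as.data.frame(train[selected])))
            <= corr_threshold)
      }, logical(1))
      cands <- cands[keep]
    }
    if (length(cands) == 0) break
    accs <- vapply(cands, function(f) {
      m <- train_tree(train, c(selected, f), task)
      evaluate_model(m, val)$accuracy
    }, numeric(1))
    if (max(accs) <= best_acc) break
    pick <- cands[which.max(accs)]  # first max = canonical order tie-break
    selected <- c(selected, pick)
    best_acc <- max(accs)
  }
  selected
}

#' Restrict a dataset to the samples of a classification task
#'
#' The two multiclass tasks vary one substrate characteristic at a time:
#' the density task uses the fully transmural fibrotic samples (plus all
#' non-fibrotic ones) and the transmurality task the highest-density
#' samples, mirroring how the simulation series are designed. The binary
#' task uses everything.
#'
#' @param df Labeled feature table.
#' @param task Classification task.
#' @return The subset of rows belonging to the task.
#' @export
task_subset <- function(df, task = c("binary", "density", "transmurality")) {
  task <- match.arg(task)
  fib <- df$label_binary == "fibrotic"
  keep <- switch(task,
    binary = rep(TRUE, nrow(df)),
    density = !fib | df$transmural_depth == max(df$transmural_depth[fib]),
    transmurality = !fib | df$density == max(df$density[fib]))
  df[keep, , drop = FALSE]
}

#' Repeated hold-out evaluation
#'
#' Runs `n_realizations` independent split / greedy-select / train /
#' evaluate cycles with seeds `base_seed + k` and reports mean and standard
#' error of accuracy, sensitivity and specificity, the summed confusion
#' matrix, and the validation-test accuracy gap (overfitting check). The
#' dataset is first restricted to the task's samples via [task_subset()].
#'
#' @param dataset Labeled feature table.
#' @param task Classification task.
#' @param n_realizations Number of hold-out realizations (default 100).
#' @param base_seed Base seed; realization k uses `base_seed + k`.
#' @param corr_threshold Correlation pruning threshold.
#' @return An object of class `eval_report`.
#' @export
repeated_holdout <- function(dataset, task = "binary", n_realizations = 100,
                             base_seed = 1L, corr_threshold = 0.6) {
  if (n_realizations < 2) stop("need at least 2 realizations")
  dataset <- task_subset(dataset, task)
  acc <- sens <- spec <- val_acc <- numeric(n_realizations)
  sel_list <- vector("list", n_realizations)
  cm_sum <- NULL
  for (k in seq_len(n_realizations)) {
    sp <- split_dataset(dataset, task, seed = base_seed + k)
    sel <- greedy_select(sp$train, sp$val, task, corr_threshold)
    if (length(sel) == 0) sel <- feature_names()[1]
    model <- train_tree(sp$train, sel, task)
    ev <- evaluate_model(model, sp$test)
    acc[k] <- ev$accuracy; sens[k] <- ev$sensitivity
    spec[k] <- ev$specificity
    val_acc[k] <- evaluate_model(model, sp$val)$accuracy
    sel_list[[k]] <- sel
    cm_sum <- if (is.null(cm_sum)) ev$confusion else cm_sum + ev$confusion
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(task = task, n = n_realizations,
                 accuracy = mean(acc), accuracy_se = se(acc),
                 sensitivity = mean(sens), sensitivity_se = se(sens),
                 specificity = mean(spec), specificity_se = se(spec),
                 val_accuracy = mean(val_acc), val_accuracy_se = se(val_acc),
                 confusion = cm_sum, per_realization = data.frame(
                   accuracy = acc, sensitivity = sens, specificity = spec,
                   val_accuracy = val_acc),
                 selections = sel_list),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s, %d realizations)\n", x$task, x$n))
  cat(sprintf("  accuracy    %.2f +/- %.2f %%\n", x$accuracy, x$accuracy_se))
  cat(sprintf("  sensitivity %.2f +/- %.2f %%\n", x$sensitivity,
              x$sensitivity_se))
  cat(sprintf("  specificity %.2f +/- %.2f %%\n", x$specificity,
              x$specificity_se))
  cat(sprintf("  validation  %.2f +/- %.2f %% (overfitting check)\n",
              x$val_accuracy, x$val_accuracy_se))
  invisible(x)
}

#' Classifier accuracy as a function of electrode height
#'
#' Evaluates a contact-trained model on feature tables re-extracted from
#' electrograms synthesized with the electrodes raised to each height.
#'
#' @param model A `trained_model` trained at contact (height 0).
#' @param sweep_features Labeled feature table with a `height` column
#'   covering all requested heights (from [build_sweep_features()]).
#' @param heights Ascending heights (mm) starting at 0.
#' @return data.frame with `height` and `accuracy` (%).
#' @export
height_sweep <- function(model, sweep_features, heights = c(0, 0.5, 1.1, 2, 3, 4.1)) {
  if (any(heights < 0)) stop("heights must be non-negative")
  if (is.unsorted(heights)) stop("heights must be ascending")
  out <- lapply(heights, function(h) {
    rows <- sweep_features[abs(sweep_features$height - h) < 1e-9, ,
                           drop = FALSE]
    if (nrow(rows) == 0) stop(sprintf("no sweep samples at height %g", h))
    data.frame(height = h, accuracy = evaluate_model(model, rows)$accuracy)
  })
  do.call(rbind, out)
}
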
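#' Sorensen-Dice index of two point sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty sets are defined as
#' perfectly similar (index 1).
#'
#' @param set_a,set_b Vectors of point identifiers.
#' @return Value in \[0, 1\].
#' @export
dice_index <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Voltage labels from peak-to-peak amplitude
#'
#' Clinical-style low/high voltage annotation against a cutoff: `low` when
#' p2p is strictly below the cutoff, `high` otherwise (a point exactly at
#' the cutoff is `high`).
#'
#' @param points data.frame with a `p2p` column (mV).
#' @param cutoff_mv Voltage cutoff, mV (default 0.5).
#' @return The data.frame with a `voltage` factor column.
#' @export
voltage_labels <- function(points, cutoff_mv = 0.5) {
  if (is.null(points$p2p) || anyNA(points$p2p))
    stop("every point needs a p2p value")
  points$voltage <- factor(ifelse(points$p2p < cutoff_mv, "low", "high"),
                           levels = c("low", "high"))
  points
}

#' Synthetic substrate map specification
#'
#' A planar pseudo-atrium with circular fibrotic patches of known density
#' and transmural depth; everything outside the patches is non-fibrotic.
#'
#' @param extent_mm `c(x, y)` map extent.
#' @param n_grid Points per side of the sampling grid.
#' @param patches List of `list(center = c(x, y), radius, density, depth)`.
#' @return A `map_spec` object.
#' @export
map_spec <- function(extent_mm = c(40, 40), n_grid = 20, patches = list()) {
  for (i in seq_along(patches)) {
    for (j in seq_len(i - 1)) {
      d <- sqrt(sum((patches[[i]]$center - patches[[j]]$center)^2))
      if (d < patches[[i]]$radius + patches[[j]]$radius)
        stop("overlapping fibrotic patches in map spec")
    }
  }
  structure(list(extent_mm = extent_mm, n_grid = n_grid, patches = patches),
            class = "map_spec")
}

#' Generate a synthetic substrate map
#'
#' Samples a regular grid of map points on the pseudo-atrium; every point's
#' bipolar trace is synthesized from a simulation of its local substrate
#' condition (a per-condition trace bank: one tissue simulation per distinct
#' condition, with the point drawing a random bipole and a fresh noise
#' realization), features are extracted and the ground-truth labels stored.
#'
#' @param spec A [map_spec()].
#' @param seed Integer seed.
#' @param noise_model `ar_model` for injection (reference process default).
#' @param snr_db Injection SNR, dB.
#' @param cfg A [study_config()].
#' @param quiet Suppress progress messages.
#' @return A `substrate_map`: list with `points` (features, p2p, truth
#'   labels) and `spec`.
#' @export
generate_synthetic_map <- function(spec, seed = 1L, noise_model = NULL,
                                   snr_db = 20, cfg = study_config(),
                                   quiet = FALSE) {
  ionic <- ionic_model("control")
  layout <- study_layout(cfg)
  if (is.null(noise_model)) noise_model <- reference_noise_process()
  scale <- calibrate_conductivity(cfg$cv_targets[2], ionic, cfg$spacing)

  conds <- unique(do.call(rbind, c(list(data.frame(density = 0, depth = 0)),
    lapply(spec$patches, function(p)
      data.frame(density = p$density, depth = p$depth)))))
  banks <- vector("list", nrow(conds))
  k_amp <- NULL
  for (i in seq_len(nrow(conds))) {
    sim <- run_condition(cfg, ionic, scale, cfg$pacing[1], layout,
                         density = conds$density[i], depth = conds$depth[i],
                         texture_seed = seed * 100 + i)
    if (is.null(k_amp)) {
      uni0 <- sim$egm
      colnames(uni0) <- layout$electrodes$id
      bp0 <- bipolar_matrix(uni0, layout, prefilter = TRUE)
      k_amp <- cfg$target_p2p /
        mean(apply(bp0, 2, function(x) diff(range(x))))
    }
    banks[[i]] <- k_amp * sim$egm
    if (!quiet) message(sprintf("map bank condition %d / %d", i, nrow(conds)))
  }

  gx <- seq(0, spec$extent_mm[1], length.out = spec$n_grid)
  gy <- seq(0, spec$extent_mm[2], length.out = spec$n_grid)
  pts <- expand.grid(x = gx, y = gy)
  pts$id <- seq_len(nrow(pts))
  cond_of <- rep(1L, nrow(pts))
  for (pi in seq_along(spec$patches)) {
    p <- spec$patches[[pi]]
    inside <- (pts$x - p$center[1])^2 + (pts$y - p$center[2])^2 <= p$radius^2
    ci <- which(conds$density == p$density & conds$depth == p$depth)
    cond_of[inside] <- ci
  }

  bp <- layout$bipoles
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    uni <- banks[[cond_of[i]]]
    colnames(uni) <- layout$electrodes$id
    b <- ((seed + i) %% nrow(bp)) + 1L
    pair <- match(c(bp$anode[b], bp$cathode[b]), layout$electrodes$id)
    u2 <- uni[, pair]
    noisy <- vapply(1:2, function(e)
      add_noise(uni[, pair[e]], noise_model, snr_db,
                seed = seed * 3000 + i * 2 + e), numeric(nrow(uni)))
    x <- make_bipolar(filter_unipolar(noisy[, 1]), filter_unipolar(noisy[, 2]))
    segs <- detect_activity(x)
    f <- extract_features(x, segs)
    usable <- !is.null(f) && !anyNA(f)
    if (!usable) f <- as.data.frame(as.list(
      stats::setNames(rep(NA_real_, 7), feature_names())))
    rows[[i]] <- cbind(
      data.frame(id = pts$id[i], x = pts$x[i], y = pts$y[i], z = 0,
                 usable = usable,
                 density = conds$density[cond_of[i]],
                 transmural_depth = conds$depth[cond_of[i]]), f)
  }
  points <- label_samples(do.call(rbind, rows))
  points <- voltage_labels(points)
  structure(list(points = points, spec = spec, seed = seed, k_amp = k_amp),
            class = "substrate_map")
}

#' @export
print.substrate_map <- function(x, ...) {
  cat(sprintf("substrate_map: %d points, %d fibrotic patches, %d usable\n",
              nrow(x$points), length(x$spec$patches), sum(x$points$usable)))
  invisible(x)
}

#' Predict substrate labels for every map point
#'
#' @param model A `trained_model`.
#' @param map A `substrate_map`.
#' @return The map with a `predicted` column (NA for unusable points).
#' @export
predict_map <- function(model, map) {
  if (nrow(map$points) == 0) stop("empty map")
  pts <- map$points
  pred <- rep(NA_character_, nrow(pts))
  ok <- pts$usable
  if (any(ok)) pred[ok] <- predict_labels(model, pts[ok, , drop = FALSE])
  map$points$predicted <- pred
  map
}

#' Dice similarity of map fibrosis calls against ground truth
#'
#' Compares the point set called fibrotic by either the classifier
#' (`"prediction"`) or the 0.5 mV voltage cutoff (`"voltage"`) against the
#' ground-truth fibrotic points; unusable points are excluded.
#'
#' @param map A predicted `substrate_map`.
#' @param method `"prediction"` or `"voltage"`.
#' @param cutoff_mv Voltage cutoff for the voltage method.
#' @return Dice index in \[0, 1\].
#' @export
map_dice <- function(map, method = c("prediction", "voltage"),
                     cutoff_mv = 0.5) {
  method <- match.arg(method)
  pts <- map$points[map$points$usable, , drop = FALSE]
  truth <- pts$id[pts$label_binary == "fibrotic"]
  called <- switch(method,
    prediction = pts$id[!is.na(pts$predicted) & pts$predicted == "fibrotic"],
    voltage = pts$id[pts$p2p < cutoff_mv])
  dice_index(truth, called)
}
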
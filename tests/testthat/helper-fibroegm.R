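# Shared expensive objects, built once per test run.
.test_env <- new.env(parent = emptyenv())

# Small control patch + one-beat simulation used by several unit tests.
tiny_sim <- function() {
  if (is.null(.test_env$tiny)) {
    grid <- build_tissue(c(8, 8, 0.8), 0.4)
    ionic <- ionic_model("control")
    cfg <- sim_config(dt = 0.05, trace_length = 0.25,
                      scale = calibrate_conductivity(40, ionic, 0.4))
    prot <- stimulus_protocol("left-edge", n_beats = 1, t0 = 2)
    layout <- catheter_layout("hd-grid", center = c(4, 4), spacing = 1.5,
                              footprint_radius = 0.3, rotation_deg = 20)
    sim <- run_propagation(grid, ionic, prot, cfg, layout = layout,
                           record_field = TRUE, field_every_ms = 10)
    .test_env$tiny <- list(grid = grid, ionic = ionic, cfg = cfg,
                           prot = prot, layout = layout, sim = sim)
  }
  .test_env$tiny
}

# The full desk-scale study dataset (used by the acceptance tests and the
# feature-regime tests); one build per test run.
study_dataset <- function() {
  if (is.null(.test_env$dataset))
    .test_env$dataset <- build_study_dataset(seed = 1L, quiet = TRUE)
  .test_env$dataset
}

sweep_features_cached <- function(heights = c(0, 1.1, 2, 4.1)) {
  if (is.null(.test_env$sweep)) {
    ds <- study_dataset()
    .test_env$sweep <- build_sweep_features(
      seed = 1L, heights = heights, noise_model = ds$noise_model,
      k_amp = ds$k_amp, quiet = TRUE)
  }
  .test_env$sweep
}

# Brute-force sample entropy (independent O(n^2) R oracle).
sampen_oracle <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  B <- 0; A <- 0
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      dm <- max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Manual LZ76 exhaustive parsing oracle: grow the next phrase until it is no
# longer a substring of the extended history.
lz76_oracle <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  i <- 1; c <- 0
  while (i <= n) {
    k <- 1
    while (i + k - 1 <= n) {
      phrase <- substr(s, i, i + k - 1)
      history <- substr(s, 1, i + k - 2)
      if (!grepl(phrase, history, fixed = TRUE)) break
      k <- k + 1
    }
    c <- c + 1
    i <- i + k
  }
  c
}
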
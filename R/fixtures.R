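#' Reference colored-noise process
#'
#' The synthetic stand-in for catheter-lab baseline noise: a fixed, stable
#' AR(4) process with a low-pass-like spectrum. Pseudo-clinical traces are
#' built from control simulations plus this process; the noise-model module
#' then re-estimates a global AR model from activity-blanked segments of
#' those traces, mirroring how a clinical noise model would be fitted.
#'
#' @return An `ar_model`.
#' @export
reference_noise_process <- function() {
  ar_model(phi = c(0.62, -0.24, 0.14, -0.06), sigma2 = 4e-4)
}

biphasic_wavelet <- function(t_ms, t0_ms, width_ms, amp) {
  s <- width_ms / 6
  u <- (t_ms - t0_ms) / s
  amp / (2 * exp(-0.5)) * (-u) * exp(-u^2 / 2)
}

#' Deterministic test and fixture signals
#'
#' Generates the synthetic traces used throughout the test-suite and as
#' pseudo-clinical stand-ins:
#' * `sinusoid`: `params = list(freq, amp, dur_s)`.
#' * `white-noise`: `params = list(sd, dur_s)`.
#' * `ar-noise`: `params = list(model, dur_s)` (defaults to the reference
#'   process).
#' * `biphasic-train`: `params = list(onsets_ms, width_ms, amp, noise_sd,
#'   dur_s)`; the returned trace carries the true support of each wavelet in
#'   `attr(x, "truth")` (0-based half-open sample indices).
#' * `control-substitute`: `params = list(n, cfg)`; returns a list of `n`
#'   noisy bipolar traces from control simulations with jittered conduction
#'   velocity (28-42 cm/s), electrode height (0-0.5 mm) and SNR (15-25 dB),
#'   amplitude-calibrated and restricted to high-voltage signals
#'   (p2p > 0.5 mV) — the stand-ins for clinical non-fibrotic recordings.
#'
#' @param kind Fixture kind.
#' @param params Named list of parameters (see above).
#' @param seed Integer seed for the stochastic kinds.
#' @param fs Sampling rate, Hz.
#' @return Numeric trace (mV), or a list of traces for
#'   `control-substitute`.
#' @export
fixture_signals <- function(kind = c("sinusoid", "white-noise", "ar-noise",
                                     "biphasic-train", "control-substitute"),
                            params = list(), seed = 1L, fs = 2000) {
  kind <- match.arg(kind)
  if (kind == "control-substitute")
    return(control_substitute_traces(n = params$n %||% 12,
                                     cfg = params$cfg %||% study_config(),
                                     seed = seed))
  p <- params
  dur <- p$dur_s %||% 2.5
  n <- round(dur * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  switch(kind,
    "sinusoid" = (p$amp %||% 1) * sin(2 * pi * (p$freq %||% 100) * t_ms / 1000),
    "white-noise" = stats::rnorm(n, sd = p$sd %||% 1),
    "ar-noise" = generate_noise(p$model %||% reference_noise_process(), n),
    "biphasic-train" = {
      onsets <- p$onsets_ms %||% c(300, 900, 1500, 2100)
      width <- p$width_ms %||% 20
      amp <- p$amp %||% 1
      x <- stats::rnorm(n, sd = p$noise_sd %||% 0.01)
      for (t0 in onsets) x <- x + biphasic_wavelet(t_ms, t0 + width / 2, width, amp)
      truth <- data.frame(
        start = pmax(0L, as.integer(round(onsets / 1000 * fs))),
        end = pmin(n, as.integer(round((onsets + width) / 1000 * fs))))
      attr(x, "truth") <- truth
      x
    })
}

# Noisy high-voltage bipolar traces from jittered control simulations.
control_substitute_traces <- function(n, cfg, seed) {
  ionic <- ionic_model("control")
  layout <- study_layout(cfg)
  model <- reference_noise_process()
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- list()
  sim_i <- 0L
  while (length(out) < n) {
    sim_i <- sim_i + 1L
    if (sim_i > 20L) break
    cv <- stats::runif(1, 28, 42)
    height <- stats::runif(1, 0, 0.5)
    snr <- stats::runif(1, 15, 25)
    scale <- calibrate_conductivity(cv, ionic, cfg$spacing)
    lay <- study_layout(cfg, height = height)
    sim <- run_condition(cfg, ionic, scale,
                         cfg$pacing[(sim_i - 1) %% 3 + 1], lay)
    bp0 <- bipolar_matrix(sim$egm, lay, prefilter = TRUE)
    k <- cfg$target_p2p / mean(apply(bp0, 2, function(x) diff(range(x))))
    pl <- egm_pipeline(k * sim$egm, lay, model, snr,
                       noise_seed = seed * 211 + sim_i * 37)
    for (b in seq_len(ncol(pl$bipolar))) {
      x <- pl$bipolar[, b]
      segs <- pl$segments[[b]]
      if (nrow(segs) == 0) next
      p2p <- mean(vapply(seq_len(nrow(segs)), function(i)
        peak_to_peak(x, segs[i, , drop = FALSE]), numeric(1)))
      if (p2p > 0.5 && length(out) < n) {
        attr(x, "p2p") <- p2p
        out[[length(out) + 1]] <- x
      }
    }
  }
  out
}

#' Desk-scale study configuration
#'
#' The fixed geometry and conditions of the synthetic study: a reduced
#' 16 x 16 x 2 mm patch at 1/3 mm element spacing (the full 30 x 30 x 2 mm
#' patch at 0.2 mm remains available through [build_tissue()]), an HD-grid
#' catheter centred over a 6.5 mm fibrotic region that encloses all
#' electrodes, fibrosis densities 10/20/40/60% crossed with transmural
#' depths 0.5/1/2 mm, control conduction velocities 30 and 40 cm/s, three
#' pacing sites, and 20 dB additive AR noise.
#'
#' @param full_scale If `TRUE`, use the full 30 x 30 x 2 mm patch at 0.2 mm
#'   spacing with a 10 mm fibrotic region.
#' @return Named list of study parameters.
#' @export
study_config <- function(full_scale = FALSE) {
  if (full_scale)
    list(patch_mm = c(30, 30, 2), spacing = 0.2, region_radius = 10,
         densities = c(0.1, 0.2, 0.4, 0.6), depths = c(0.5, 1, 2),
         cv_targets = c(30, 40), snr_db = 20, dt = 0.02,
         pacing = c("left-edge", "bottom-edge", "top-right-corner"),
         target_p2p = 2.25)
  else
    list(patch_mm = c(16, 16, 2), spacing = 1 / 3, region_radius = 6.5,
         densities = c(0.1, 0.2, 0.4, 0.6), depths = c(0.5, 1, 2),
         cv_targets = c(30, 40), snr_db = 20, dt = 0.125,
         pacing = c("left-edge", "bottom-edge", "top-right-corner"),
         target_p2p = 2.25)
}

#' Control tissue patch of the study
#' @param cfg A [study_config()].
#' @return A `tissue_grid`.
#' @export
study_patch <- function(cfg = study_config()) {
  build_tissue(cfg$patch_mm, cfg$spacing)
}

#' Study catheter layout centred on the patch
#' @param cfg A [study_config()].
#' @param height Electrode height, mm.
#' @return A [catheter_layout()].
#' @export
study_layout <- function(cfg = study_config(), height = 0) {
  catheter_layout("hd-grid", center = cfg$patch_mm[1:2] / 2, height = height,
                  footprint_radius = 1, rotation_deg = 30)
}
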
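#' Reduced two-variable atrial ionic model
#'
#' A phenomenological excitation model with a fast inward and a slow outward
#' current gated by a single recovery variable, on a normalized membrane
#' variable u in \[0, 1\] mapped to millivolts by `Vm = v_rest + v_amp * u`.
#' Time constants are tuned so the control variant yields an atrial-like
#' action-potential duration near 200 ms and the AF-remodeled variant a
#' shortened one near 140 ms. The model honours a fixed contract: the resting
#' state (u = 0, h = 1) is a fixed point and a suprathreshold stimulus elicits
#' an action potential of finite duration, which is what the electrogram
#' forward model consumes at the wavefront level.
#'
#' @param variant `"control"` or `"af"` (electrically remodeled).
#' @return An object of class `ionic_model` with fields `tau_in`, `tau_out`,
#'   `tau_open`, `tau_close`, `u_gate` (ms / dimensionless), `v_rest`, `v_amp`
#'   (mV), and resting state `u0`, `h0`.
#' @export
ionic_model <- function(variant = c("control", "af")) {
  variant <- match.arg(variant)
  pars <- switch(variant,
    control = list(tau_in = 0.3, tau_out = 6, tau_open = 120,
                   tau_close = 102, u_gate = 0.13),
    af = list(tau_in = 0.3, tau_out = 6, tau_open = 120,
              tau_close = 68, u_gate = 0.13))
  structure(c(pars, list(variant = variant, v_rest = -80, v_amp = 110,
                         u0 = 0, h0 = 1)),
            class = "ionic_model")
}

#' @export
print.ionic_model <- function(x, ...) {
  cat(sprintf("ionic_model (%s): tau_in=%g tau_out=%g tau_open=%g tau_close=%g u_gate=%g\n",
              x$variant, x$tau_in, x$tau_out, x$tau_open, x$tau_close,
              x$u_gate))
  invisible(x)
}

#' Time derivatives of the ionic model
#'
#' Exposes the reaction terms of the model contract for direct inspection:
#' `du` is the total ionic rate (1/ms, per-capacitance convention) and `dh`
#' the gate rate.
#'
#' @param ionic An [ionic_model()].
#' @param u,h State values.
#' @return List with `du` and `dh`.
#' @export
ionic_rates <- function(ionic, u, h) {
  j_in <- h * u^2 * (1 - u) / ionic$tau_in
  j_out <- -u / ionic$tau_out
  dh <- ifelse(u < ionic$u_gate, (1 - h) / ionic$tau_open,
               -h / ionic$tau_close)
  list(du = j_in + j_out, dh = dh)
}

run_single_cell <- function(ionic, pulses_ms, pulse_dur = 2, amp = 0.5,
                            t_end = NULL, dt = 0.02, u0 = ionic$u0,
                            h0 = ionic$h0) {
  if (is.null(t_end)) t_end <- max(pulses_ms) + 500
  zero <- numeric(1)
  out_every <- max(1L, as.integer(round(0.5 / dt)))  # 2 kHz
  res <- .md_run(1L, 1L, 1L, zero, zero, zero, zero, zero, zero,
                 stim_mask = 1, pulse_starts = pulses_ms,
                 pulse_dur = pulse_dur, stim_amp = amp,
                 dt = dt, n_steps = as.integer(round(t_end / dt)),
                 out_every = out_every,
                 tau_in = ionic$tau_in, tau_out = ionic$tau_out,
                 tau_open = ionic$tau_open, tau_close = ionic$tau_close,
                 u_gate = ionic$u_gate, v_amp = ionic$v_amp,
                 u0 = u0, h0 = h0,
                 W = matrix(0, 1, 0), probes = 0L,
                 record_field = FALSE, field_every = 0L)
  list(t = seq_len(nrow(res$probe_vm)) * dt * out_every,
       u = res$probe_vm[, 1], u_end = res$u[1], h_end = res$h[1])
}

#' Action-potential duration of a single cell
#'
#' Runs an isolated cell, stimulates once, and measures the time spent above
#' a repolarization level of u = 0.1 (roughly APD90 for this model).
#'
#' @param ionic An [ionic_model()].
#' @param amp Stimulus amplitude (1/ms), default twice the diastolic threshold.
#' @return APD in ms (0 if no action potential was elicited).
#' @export
cell_apd <- function(ionic, amp = 2 * diastolic_threshold(ionic)) {
  tr <- run_single_cell(ionic, pulses_ms = 5, amp = amp, t_end = 500)
  above <- tr$u > 0.1
  if (!any(above)) return(0)
  diff(range(tr$t[above]))
}

#' Diastolic stimulation threshold
#'
#' Bisects the minimal transmembrane stimulus amplitude (for a 2 ms pulse)
#' that elicits an action potential in a resting isolated cell.
#'
#' @param ionic An [ionic_model()].
#' @param pulse_dur Pulse duration, ms.
#' @return Threshold amplitude (1/ms).
#' @export
diastolic_threshold <- function(ionic, pulse_dur = 2) {
  key <- paste0("thr_", ionic$variant, "_", pulse_dur)
  cached <- get0(key, envir = .fibroegm_cache)
  if (!is.null(cached)) return(cached)
  excites <- function(a) {
    tr <- run_single_cell(ionic, pulses_ms = 2, pulse_dur = pulse_dur,
                          amp = a, t_end = 120)
    max(tr$u) > 0.8
  }
  lo <- 0.001; hi <- 2
  if (!excites(hi)) stop("upper stimulus bound does not excite the cell")
  for (i in 1:24) {
    mid <- (lo + hi) / 2
    if (excites(mid)) hi <- mid else lo <- mid
  }
  assign(key, hi, envir = .fibroegm_cache)
  hi
}

#' Tissue stimulation threshold
#'
#' Bisects the minimal strip-stimulus amplitude (2 ms pulse into a 1 mm
#' strip) that launches a propagating wave in a short strand with the given
#' element spacing and conductivity scale. The electrotonic load of the
#' coupled tissue makes this threshold larger than the single-cell one, so
#' pacing amplitudes are referenced to it.
#'
#' @param ionic An [ionic_model()].
#' @param spacing_mm Element spacing, mm.
#' @param scale Monodomain conductivity scale.
#' @param dt Time step, ms.
#' @return Threshold amplitude (1/ms).
#' @export
tissue_threshold <- function(ionic, spacing_mm, scale, dt = 0.05) {
  key <- sprintf("tthr_%s_%g_%.4g_%g", ionic$variant, spacing_mm, scale, dt)
  cached <- get0(key, envir = .fibroegm_cache)
  if (!is.null(cached)) return(cached)
  grid <- build_tissue(c(10, spacing_mm, spacing_mm), spacing_mm)
  cfg <- sim_config(dt = dt, trace_length = 0.06, scale = scale)
  probe <- matrix(c(8, spacing_mm / 2, spacing_mm / 2), 1)
  excites <- function(a) {
    prot <- stimulus_protocol("left-edge", n_beats = 1, t0 = 2, amplitude = a)
    sim <- run_propagation(grid, ionic, prot, cfg, probes = probe)
    max(sim$probe_vm) > -30
  }
  lo <- 0.001; hi <- 0.05
  while (!excites(hi)) {
    hi <- hi * 2
    if (hi > 50) stop("no stimulus amplitude launches a wave in the strand")
  }
  for (i in 1:16) {
    mid <- (lo + hi) / 2
    if (excites(mid)) hi <- mid else lo <- mid
  }
  assign(key, hi, envir = .fibroegm_cache)
  hi
}

#' Pre-pace an isolated cell to its limit cycle
#'
#' Stimulates the cell at the given basic cycle length until the state at the
#' start of consecutive cycles converges (or a maximum of `max_cycles`), and
#' returns the diastolic state used to initialize tissue simulations.
#'
#' @param ionic An [ionic_model()].
#' @param bcl Basic cycle length, ms (default 600).
#' @param max_cycles Cap on pre-pacing cycles.
#' @param tol Convergence tolerance on the cycle-start state.
#' @return List with `u`, `h` and the number of cycles run.
#' @export
prepace_cell <- function(ionic, bcl = 600, max_cycles = 100, tol = 1e-6) {
  key <- paste0("prepace_", ionic$variant, "_", bcl)
  cached <- get0(key, envir = .fibroegm_cache)
  if (!is.null(cached)) return(cached)
  amp <- 2 * diastolic_threshold(ionic)
  u <- ionic$u0; h <- ionic$h0
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    tr <- run_single_cell(ionic, pulses_ms = 2, amp = amp, t_end = bcl,
                          u0 = u, h0 = h)
    if ((abs(tr$u_end - u) + abs(tr$h_end - h)) < tol || cycles >= max_cycles) {
      out <- list(u = tr$u_end, h = tr$h_end, cycles = cycles)
      assign(key, out, envir = .fibroegm_cache)
      return(out)
    }
    u <- tr$u_end; h <- tr$h_end
  }
}

.fibroegm_cache <- new.env(parent = emptyenv())
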
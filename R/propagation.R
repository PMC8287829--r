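#' Pacing protocol
#'
#' Transmembrane stimulation of the patch from one of three sites: a 1 mm
#' strip along the left or bottom border, or a 3 x 3 mm quadrant in the
#' top-right corner. Stimuli are trains of square pulses at a fixed basic
#' cycle length; pulse amplitude defaults to twice the diastolic threshold
#' (resolved at run time). Extracellular stimulation is not used.
#'
#' @param site `"left-edge"`, `"bottom-edge"`, or `"top-right-corner"`.
#' @param bcl Basic cycle length, ms (default 600).
#' @param n_beats Number of pulses (default 4 so that a 2.5 s trace holds
#'   about four activities).
#' @param pulse_ms Pulse duration, ms.
#' @param amplitude Stimulus amplitude (1/ms) or `NULL` for 2x threshold.
#' @param strip_mm Width of the stimulated strip, mm.
#' @param t0 Onset of the first pulse, ms.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(site = c("left-edge", "bottom-edge",
                                       "top-right-corner"),
                              bcl = 600, n_beats = 4, pulse_ms = 2,
                              amplitude = NULL, strip_mm = 1, t0 = 5) {
  site <- match.arg(site)
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (pulse_ms >= bcl) stop("pulse duration must be shorter than the BCL")
  structure(list(site = site, bcl = bcl, n_beats = as.integer(n_beats),
                 pulse_ms = pulse_ms, amplitude = amplitude,
                 strip_mm = strip_mm, t0 = t0),
            class = "stimulus_protocol")
}

#' Simulation configuration
#'
#' Numerical and biophysical constants for tissue simulations and the
#' electrogram forward model. `scale` is the dimensionless monodomain
#' conductivity multiplier returned by [calibrate_conductivity()]; `k_amp`
#' is the electrogram amplitude calibration constant (see
#' [calibrate_amplitude()]).
#'
#' @param dt Time step, ms.
#' @param output_rate Output sampling rate, Hz (fixed study value 2000).
#' @param trace_length Electrogram length, s.
#' @param sigma_b Bath (blood) conductivity, S/m.
#' @param beta Surface-to-volume ratio, 1/cm.
#' @param c_m Membrane capacitance, uF/cm^2.
#' @param scale Monodomain conductivity scale (from CV calibration).
#' @param k_amp Electrogram amplitude calibration constant.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, output_rate = 2000, trace_length = 2.5,
                       sigma_b = 0.7, beta = 1400, c_m = 1, scale = 1,
                       k_amp = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (output_rate != 2000)
    stop("output_rate is fixed at 2000 Hz for this study")
  structure(list(dt = dt, output_rate = output_rate,
                 trace_length = trace_length, sigma_b = sigma_b, beta = beta,
                 c_m = c_m, scale = scale, k_amp = k_amp),
            class = "sim_config")
}

# Conversion sigma [S/m] -> diffusivity [mm^2/ms] given beta [1/cm], Cm
# [uF/cm^2]: D = sigma / (beta * Cm) with unit bookkeeping.
sigma_to_diff <- function(sigma_s_m, config) {
  (0.01 * sigma_s_m) / (config$beta * config$c_m * 1e-6) / 1000 * 100
}

harm <- function(a, b) {
  s <- a + b
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- (a * b)[pos] * 2 / s[pos]
  out
}

# Monodomain diffusivity per element and axis (mm^2/ms): equal-anisotropy
# harmonic mean of intra- and extracellular conductivity, times the
# calibration scale. x is longitudinal (fibres along +x), y/z transverse.
diffusivity_arrays <- function(grid, config) {
  dl <- sigma_to_diff(harm(grid$sigma_i_long, grid$sigma_e_long), config)
  dtv <- sigma_to_diff(harm(grid$sigma_i_trans, grid$sigma_e_trans), config)
  list(dx = config$scale * dl, dy = config$scale * dtv,
       dz = config$scale * dtv)
}

# Face conductances to the + neighbour (divided by h^2; entries on the last
# slab are zero so no-flux boundaries come for free).
face_conductances <- function(dx, dy, dz, dims, h) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  gx <- numeric(n); gy <- numeric(n); gz <- numeric(n)
  a <- array(seq_len(n), dim = dims)
  if (nx > 1) {
    i <- as.vector(a[-nx, , , drop = FALSE]); j <- i + 1L
    gx[i] <- harm(dx[i], dx[j]) / h^2
  }
  if (ny > 1) {
    i <- as.vector(a[, -ny, , drop = FALSE]); j <- i + nx
    gy[i] <- harm(dy[i], dy[j]) / h^2
  }
  if (nz > 1) {
    i <- as.vector(a[, , -nz, drop = FALSE]); j <- i + nx * ny
    gz[i] <- harm(dz[i], dz[j]) / h^2
  }
  list(gx = gx, gy = gy, gz = gz)
}

# Intracellular source-term face conductances (sigma_i, unscaled), used for
# the Green's-function source div(sigma_i grad Vm).
source_conductances <- function(grid) {
  dims <- dim(grid$label)
  face_conductances(grid$sigma_i_long, grid$sigma_i_trans,
                    grid$sigma_i_trans, dims, grid$spacing)
}

stimulus_mask <- function(grid, protocol) {
  pos <- element_centers(grid)
  lx <- grid$dims_mm[1]; ly <- grid$dims_mm[2]
  sel <- switch(protocol$site,
    "left-edge" = pos[, 1] <= protocol$strip_mm,
    "bottom-edge" = pos[, 2] <= protocol$strip_mm,
    "top-right-corner" = pos[, 1] >= lx - 3 & pos[, 2] >= ly - 3)
  as.numeric(sel)
}

position_to_index <- function(grid, pos) {
  pos <- matrix(pos, ncol = 3)
  h <- grid$spacing
  ii <- pmin(pmax(ceiling(pos[, 1] / h), 1L), grid$nx)
  jj <- pmin(pmax(ceiling(pos[, 2] / h), 1L), grid$ny)
  kk <- pmin(pmax(ceiling(pos[, 3] / h), 1L), grid$nz)
  as.integer(ii + grid$nx * ((jj - 1) + grid$ny * (kk - 1)))
}

#' Run a monodomain tissue simulation
#'
#' Operator-split explicit reaction-diffusion propagation of the reduced
#' ionic model on the voxel grid, with no-flux boundaries; collagen elements
#' act as diffusion barriers through their near-zero conductivity. The cell
#' model is pre-paced to its limit cycle before the tissue run. If a catheter
#' `layout` is supplied, unipolar electrograms are accumulated on the fly at
#' the output rate through the Green's-function weights.
#'
#' @param grid A `tissue_grid`.
#' @param ionic An [ionic_model()].
#' @param protocol A [stimulus_protocol()].
#' @param config A [sim_config()] (with a calibrated `scale`).
#' @param layout Optional [catheter_layout()]; may carry several heights via
#'   [egm_weights()] passed as `weights`.
#' @param weights Optional precomputed weight matrix (n_elements x
#'   n_electrodes); computed from `layout` when missing.
#' @param probes Optional n x 3 matrix of probe positions (mm) at which the
#'   transmembrane voltage is recorded at the output rate.
#' @param record_field If `TRUE`, store the full normalized Vm field every
#'   `field_every_ms` (small grids only).
#' @param field_every_ms Field snapshot interval, ms.
#' @return An object of class `egm_sim` with elements `egm` (samples x
#'   electrodes, mV), `probe_vm` (mV), `fs`, `times_ms`, and the inputs.
#' @export
run_propagation <- function(grid, ionic, protocol, config,
                            layout = NULL, weights = NULL, probes = NULL,
                            record_field = FALSE, field_every_ms = 5) {
  dims <- dim(grid$label)
  dd <- diffusivity_arrays(grid, config)
  fc <- face_conductances(dd$dx, dd$dy, dd$dz, dims, grid$spacing)
  sc <- source_conductances(grid)

  # explicit-stability guard
  dmax <- max(fc$gx + fc$gy + fc$gz)
  if (config$dt > 0.95 / (2 * dmax + 1e-12))
    stop(sprintf("dt = %g ms violates the explicit stability bound (%.4g ms)",
                 config$dt, 0.95 / (2 * dmax)))

  if (is.null(weights)) {
    if (!is.null(layout)) weights <- egm_weights(grid, layout, config)
    else weights <- matrix(0, prod(dims), 0)
  }
  probe_idx <- if (is.null(probes)) integer(0)
               else position_to_index(grid, probes)

  amp <- protocol$amplitude
  if (is.null(amp))
    amp <- 2 * tissue_threshold(ionic, grid$spacing, config$scale,
                                dt = config$dt)
  state <- prepace_cell(ionic, protocol$bcl)
  n <- prod(dims)
  pulses <- protocol$t0 + (seq_len(protocol$n_beats) - 1) * protocol$bcl

  total_ms <- config$trace_length * 1000
  n_steps <- as.integer(round(total_ms / config$dt))
  out_every <- as.integer(round(1000 / config$output_rate / config$dt))
  if (abs(out_every * config$dt - 1000 / config$output_rate) > 1e-9)
    stop("dt must divide the output sampling interval")

  res <- .md_run(dims[1], dims[2], dims[3],
                 fc$gx, fc$gy, fc$gz, sc$gx, sc$gy, sc$gz,
                 stim_mask = stimulus_mask(grid, protocol),
                 pulse_starts = pulses, pulse_dur = protocol$pulse_ms,
                 stim_amp = amp, dt = config$dt, n_steps = n_steps,
                 out_every = out_every,
                 tau_in = ionic$tau_in, tau_out = ionic$tau_out,
                 tau_open = ionic$tau_open, tau_close = ionic$tau_close,
                 u_gate = ionic$u_gate, v_amp = ionic$v_amp,
                 u0 = rep(state$u, n), h0 = rep(state$h, n),
                 W = weights, probes = probe_idx - 1L,
                 record_field = record_field,
                 field_every = as.integer(round(field_every_ms / config$dt)))
  if (res$blowup)
    stop(sprintf("numerical blow-up: reduce dt (currently %g ms)", config$dt))

  n_out <- nrow(res$egm)
  out <- list(egm = res$egm,
              probe_vm = ionic$v_rest + ionic$v_amp * res$probe_vm,
              field = if (record_field) res$field else NULL,
              field_every_ms = if (record_field) field_every_ms else NULL,
              times_ms = seq_len(n_out) * 1000 / config$output_rate,
              fs = config$output_rate, layout = layout,
              protocol = protocol, config = config, ionic = ionic$variant,
              grid_dims = dims, spacing = grid$spacing)
  class(out) <- "egm_sim"
  out
}

#' @export
print.egm_sim <- function(x, ...) {
  cat(sprintf("egm_sim: %d samples @ %g Hz, %d electrodes, %s pacing (%s)\n",
              length(x$times_ms), x$fs, ncol(x$egm), x$protocol$site,
              x$ionic))
  invisible(x)
}

activation_time <- function(vm, times_ms) {
  dv <- diff(vm)
  rng <- diff(range(vm))
  if (rng < 10)  # mV; never depolarized
    return(NA_real_)
  k <- which.max(dv)
  # parabolic refinement of the derivative peak for sub-sample accuracy
  if (k > 1 && k < length(dv)) {
    y0 <- dv[k - 1]; y1 <- dv[k]; y2 <- dv[k + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
  } else off <- 0
  dt <- times_ms[2] - times_ms[1]
  times_ms[k] + (off + 0.5) * dt
}

count_upstrokes <- function(vm, level = -30) {
  above <- vm > level
  sum(diff(above) == 1) + as.integer(above[1])
}

#' Conduction velocity between two probes
#'
#' Activation time at each probe is the instant of maximal dVm/dt during the
#' upstroke (parabolically refined); CV is the probe distance divided by the
#' activation-time difference. Both probes must be activated exactly once in
#' the analysis window.
#'
#' @param sim An `egm_sim` run with at least two probes.
#' @param probe_positions The probe positions (mm) used in the run (n x 3).
#' @param pair Indices of the two probes to use (default first and last).
#' @return Conduction velocity in cm/s.
#' @export
measure_cv <- function(sim, probe_positions, pair = c(1, ncol(sim$probe_vm))) {
  vm1 <- sim$probe_vm[, pair[1]]; vm2 <- sim$probe_vm[, pair[2]]
  for (v in list(vm1, vm2)) {
    nups <- count_upstrokes(v)
    if (nups == 0) stop("probe not activated in the analysis window")
    if (nups > 1) stop("probe activated more than once in the analysis window")
  }
  t1 <- activation_time(vm1, sim$times_ms)
  t2 <- activation_time(vm2, sim$times_ms)
  if (is.na(t1) || is.na(t2)) stop("probe not activated")
  dt_ms <- t2 - t1
  if (abs(dt_ms) < 1e-9) stop("zero activation delay between probes")
  d_mm <- sqrt(sum((probe_positions[pair[2], ] - probe_positions[pair[1], ])^2))
  (d_mm / dt_ms) * 100  # mm/ms -> cm/s
}

strand_cv <- function(scale, ionic, spacing, dt = 0.05, length_mm = 30) {
  nx <- as.integer(round(length_mm / spacing))
  grid <- build_tissue(c(length_mm, spacing, spacing), spacing)
  cfg <- sim_config(dt = dt, trace_length = 0.25, scale = scale)
  prot <- stimulus_protocol("left-edge", n_beats = 1, t0 = 2)
  probes <- rbind(c(length_mm * 0.25, spacing / 2, spacing / 2),
                  c(length_mm * 0.75, spacing / 2, spacing / 2))
  sim <- run_propagation(grid, ionic, prot, cfg, probes = probes)
  measure_cv(sim, probes, pair = c(1, 2))
}

#' Calibrate the monodomain conductivity scale to a target conduction velocity
#'
#' Runs plane-wave simulations in a thin 1-D strand at the given element
#' spacing and iterates on the conductivity scale (using the square-root
#' CV-diffusivity law as the update, with bisection fallback) until the
#' measured CV is within 1% of the target. Results are cached per target,
#' ionic variant and spacing.
#'
#' @param target_cv_cm_s Target plane-wave conduction velocity, cm/s.
#' @param ionic An [ionic_model()].
#' @param spacing_mm Element spacing of the simulations the scale will be
#'   used for (the discretization error is absorbed into the scale).
#' @param dt Strand time step, ms.
#' @return The calibrated dimensionless scale.
#' @export
calibrate_conductivity <- function(target_cv_cm_s, ionic, spacing_mm,
                                   dt = 0.05) {
  if (!is.finite(target_cv_cm_s) || target_cv_cm_s <= 0)
    stop("target CV must be positive")
  key <- sprintf("cvscale_%s_%g_%g_%g", ionic$variant, target_cv_cm_s,
                 spacing_mm, dt)
  cached <- get0(key, envir = .fibroegm_cache)
  if (!is.null(cached)) return(cached)
  scale <- 1
  for (i in 1:20) {
    cv <- tryCatch(strand_cv(scale, ionic, spacing_mm, dt),
                   error = function(e) NA_real_)
    if (is.na(cv) || cv <= 0) {
      scale <- scale * 4
      if (scale > 1e4) stop("CV calibration failed: target unreachable")
      next
    }
    if (abs(cv - target_cv_cm_s) / target_cv_cm_s < 0.01) {
      assign(key, scale, envir = .fibroegm_cache)
      return(scale)
    }
    scale <- scale * (target_cv_cm_s / cv)^2
    if (scale > 1e4 || scale < 1e-6)
      stop("CV calibration failed: scale out of bounds")
  }
  stop("CV calibration did not converge within 5% of the target")
}
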
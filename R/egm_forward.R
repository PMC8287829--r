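#' Catheter electrode layout
#'
#' Electrode positions and bipole pairings for two mapping catheters:
#' * `hd-grid`: 4 x 4 electrodes on four splines with equidistant spacing
#'   (default 3 mm) and 12 bipoles along the splines (adjacent pairs).
#' * `lasso`: 20 electrodes on a circle of radius 80 / (2 pi) mm so the arc
#'   spacing alternates 2 mm within a pair and 6 mm between pairs; 10
#'   intra-pair bipoles.
#'
#' Electrodes sit at `z = -height` (the endocardial surface is z = 0 and the
#' tissue occupies z > 0), so height 0 is contact.
#'
#' @param name `"hd-grid"` or `"lasso"`.
#' @param center `c(x, y)` catheter centre (mm); set when attaching to a grid.
#' @param height Electrode height above the endocardium, mm (>= 0).
#' @param spacing HD-grid inter-electrode spacing, mm.
#' @param footprint_radius Electrode footprint radius, mm.
#' @param rotation_deg In-plane rotation of the catheter about its centre.
#'   An HD grid aligned exactly with a plane wavefront cancels it perfectly
#'   in every along-spline bipole; a non-zero rotation emulates the
#'   arbitrary orientation a catheter has in practice.
#' @return An object of class `catheter_layout` with `electrodes`
#'   (data.frame id, x, y, z) and `bipoles` (data.frame anode, cathode).
#' @export
catheter_layout <- function(name = c("hd-grid", "lasso"), center = c(0, 0),
                            height = 0, spacing = 3, footprint_radius = 0.5,
                            rotation_deg = 0) {
  name <- match.arg(name)
  if (height < 0) stop("electrode height must be non-negative")
  th <- rotation_deg * pi / 180
  if (name == "hd-grid") {
    g <- expand.grid(col = 1:4, row = 1:4)
    off <- (g$col - 2.5) * spacing
    offy <- (g$row - 2.5) * spacing
    ids <- paste0(LETTERS[g$row], g$col)
    el <- data.frame(id = ids,
                     x = center[1] + off * cos(th) - offy * sin(th),
                     y = center[2] + off * sin(th) + offy * cos(th),
                     z = -height, stringsAsFactors = FALSE)
    bp <- do.call(rbind, lapply(1:4, function(r)
      data.frame(anode = paste0(LETTERS[r], 1:3),
                 cathode = paste0(LETTERS[r], 2:4))))
  } else {
    radius <- 80 / (2 * pi)
    arcs <- rep(c(2, 6), 10)[1:20]
    theta <- cumsum(c(0, arcs[-20])) / radius
    ids <- sprintf("L%02d", 1:20)
    el <- data.frame(id = ids,
                     x = center[1] + radius * cos(theta),
                     y = center[2] + radius * sin(theta),
                     z = -height, stringsAsFactors = FALSE)
    bp <- data.frame(anode = ids[seq(1, 19, 2)], cathode = ids[seq(2, 20, 2)])
  }
  structure(list(name = name, electrodes = el, bipoles = bp,
                 center = center, height = height, spacing = spacing,
                 footprint_radius = footprint_radius,
                 rotation_deg = rotation_deg),
            class = "catheter_layout")
}

#' @export
print.catheter_layout <- function(x, ...) {
  cat(sprintf("catheter_layout %s: %d electrodes, %d bipoles, height %g mm\n",
              x$name, nrow(x$electrodes), nrow(x$bipoles), x$height))
  invisible(x)
}

footprint_points <- function(x, y, z, radius, n_ring = 6) {
  ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  rbind(c(x, y, z),
        cbind(x + radius * cos(ang), y + radius * sin(ang), z))
}

#' Green's-function electrode weights
#'
#' Geometric weights of the infinite-homogeneous-medium solution of the
#' extracellular potential equation: each element contributes its source
#' density `-div(sigma_i grad Vm)` divided by `4 pi sigma_b r`, with the
#' distance averaged over points sampled on the electrode footprint. The
#' amplitude calibration constant `config$k_amp` is folded in.
#'
#' @param grid A `tissue_grid`.
#' @param layout A [catheter_layout()].
#' @param config A [sim_config()].
#' @param heights Optional vector of heights (mm) overriding the layout's;
#'   the returned matrix then stacks `n_electrodes` columns per height.
#' @return Matrix of weights, n_elements rows and n_electrodes (times
#'   n_heights, stacked) columns.
#' @export
egm_weights <- function(grid, layout, config, heights = NULL) {
  if (is.null(heights)) heights <- layout$height
  if (any(heights < 0)) stop("electrode heights must be non-negative")
  pos <- element_centers(grid)
  vol <- grid$spacing^3
  rmin <- grid$spacing / 2
  el <- layout$electrodes
  cols <- vector("list", length(heights) * nrow(el))
  k <- 0L
  for (hgt in heights) {
    for (e in seq_len(nrow(el))) {
      pts <- footprint_points(el$x[e], el$y[e], -hgt, layout$footprint_radius)
      inv_r <- rowMeans(vapply(seq_len(nrow(pts)), function(p) {
        r <- sqrt((pos[, 1] - pts[p, 1])^2 + (pos[, 2] - pts[p, 2])^2 +
                    (pos[, 3] - pts[p, 3])^2)
        1 / pmax(r, rmin)
      }, numeric(nrow(pos))))
      k <- k + 1L
      cols[[k]] <- config$k_amp * vol * inv_r / (4 * pi * config$sigma_b)
    }
  }
  W <- do.call(cbind, cols)
  colnames(W) <- as.vector(outer(el$id, heights, function(id, h)
    if (length(heights) > 1) paste0(id, "@", h) else id))
  W
}

# Source density div(sigma_i grad Vm) per element for a field snapshot
# (R reference used for tests and standalone forward computation).
source_density <- function(grid, u) {
  dims <- dim(grid$label)
  sc <- source_conductances(grid)
  n <- prod(dims)
  s <- numeric(n)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  a <- array(seq_len(n), dim = dims)
  if (nx > 1) {
    i <- as.vector(a[-nx, , , drop = FALSE]); j <- i + 1L
    f <- sc$gx[i] * (u[j] - u[i]); s[i] <- s[i] + f
    s[j] <- s[j] - f
  }
  if (ny > 1) {
    i <- as.vector(a[, -ny, , drop = FALSE]); j <- i + nx
    f <- sc$gy[i] * (u[j] - u[i])
    s[i] <- s[i] + f; s[j] <- s[j] - f
  }
  if (nz > 1) {
    i <- as.vector(a[, , -nz, drop = FALSE]); j <- i + nx * ny
    f <- sc$gz[i] * (u[j] - u[i])
    s[i] <- s[i] + f; s[j] <- s[j] - f
  }
  s
}

#' Unipolar electrograms from a recorded transmembrane field
#'
#' Standalone evaluation of the Green's-function forward model: for every
#' field snapshot the intracellular source density is computed on the grid
#' and projected onto the electrode weights. Used for small grids and for
#' superposition tests; large runs accumulate the same quantity on the fly
#' inside [run_propagation()].
#'
#' @param field Matrix (n_elements x n_times) of transmembrane voltage in mV
#'   (an affine function of the normalized state; constants drop out of the
#'   source term).
#' @param grid The `tissue_grid` the field lives on.
#' @param layout A [catheter_layout()].
#' @param config A [sim_config()].
#' @return Matrix (n_times x n_electrodes) of unipolar potentials, mV.
#' @export
compute_unipolar_egms <- function(field, grid, layout, config) {
  if (nrow(field) != length(grid$label))
    stop("field does not match the grid")
  W <- egm_weights(grid, layout, config)
  s <- apply(field, 2, function(u) source_density(grid, u))
  t(-crossprod(W, s))
}

#' Calibrate the electrogram amplitude constant
#'
#' Runs one control (non-fibrotic) simulation at contact and fixes `k_amp`
#' so that the mean bipolar peak-to-peak amplitude over the catheter equals
#' the target (default 2.25 mV, the control contact regime). The constant is
#' then frozen across all conditions so relative amplitude effects are
#' preserved.
#'
#' @param grid Control `tissue_grid`.
#' @param ionic An [ionic_model()].
#' @param protocol A [stimulus_protocol()].
#' @param config A [sim_config()] with `k_amp = 1`.
#' @param layout A contact [catheter_layout()].
#' @param target_p2p_mv Target mean bipolar p2p, mV.
#' @return The calibrated `k_amp`.
#' @export
calibrate_amplitude <- function(grid, ionic, protocol, config, layout,
                                target_p2p_mv = 2.25) {
  cfg <- config
  cfg$k_amp <- 1
  sim <- run_propagation(grid, ionic, protocol, cfg, layout = layout)
  bp <- bipolar_matrix(sim$egm, layout, fs = sim$fs)
  p2p <- mean(apply(bp, 2, function(x) diff(range(x))))
  if (p2p <= 0) stop("degenerate control simulation: zero bipolar amplitude")
  target_p2p_mv / p2p
}
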
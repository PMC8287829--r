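test_that("the ionic model rests at a fixed point and fires finite APs", {
  ion <- ionic_model("control")
  r <- ionic_rates(ion, ion$u0, ion$h0)
  expect_equal(r$du, 0)
  expect_equal(r$dh, 0)
  apd <- cell_apd(ion)
  expect_gt(apd, 150)
  expect_lt(apd, 260)
  expect_lt(cell_apd(ionic_model("af")), apd)  # AF remodeling shortens APD
  # subthreshold stimulus does not fire
  expect_equal(cell_apd(ion, amp = 0.25 * diastolic_threshold(ion)), 0)
})

test_that("pre-pacing converges to a diastolic limit cycle", {
  st <- prepace_cell(ionic_model("control"))
  expect_lt(st$u, 0.01)
  expect_gt(st$h, 0.8)
  expect_lte(st$cycles, 100)
})

test_that("conduction velocity follows its definition on synthetic upstrokes", {
  t_ms <- seq(0, 100, by = 0.5)
  upstroke <- function(t0) -80 + 110 / (1 + exp(-(t_ms - t0) * 4))
  sim <- structure(list(probe_vm = cbind(upstroke(20), upstroke(22.5)),
                        times_ms = t_ms), class = "egm_sim")
  probes <- rbind(c(0, 0, 0), c(1, 0, 0))  # 1 mm apart, 2.5 ms delay
  expect_equal(measure_cv(sim, probes, pair = c(1, 2)), 40, tolerance = 0.02)
  same <- structure(list(probe_vm = cbind(upstroke(20), upstroke(20)),
                         times_ms = t_ms), class = "egm_sim")
  expect_error(measure_cv(same, probes, pair = c(1, 2)), "zero activation")
  flat <- structure(list(probe_vm = cbind(upstroke(20), rep(-80, length(t_ms))),
                         times_ms = t_ms), class = "egm_sim")
  expect_error(measure_cv(flat, probes, pair = c(1, 2)), "not activated")
})

test_that("calibration reaches the target CV and obeys the square-root law", {
  ion <- ionic_model("control")
  for (target in c(30, 40)) {
    sc <- calibrate_conductivity(target, ion, 0.4)
    cv <- fibroegm:::strand_cv(sc, ion, 0.4)
    expect_lt(abs(cv - target) / target, 0.05)
  }
  sc <- calibrate_conductivity(30, ion, 0.4)
  ratio <- fibroegm:::strand_cv(4 * sc, ion, 0.4) /
    fibroegm:::strand_cv(sc, ion, 0.4)
  expect_equal(ratio, 2, tolerance = 0.1)
  expect_error(calibrate_conductivity(0, ion, 0.4), "positive")
})

test_that("plane waves activate monotonically along the propagation axis", {
  tn <- tiny_sim()
  probes <- cbind(seq(1, 7, by = 1), 4, 0.2)
  sim <- run_propagation(tn$grid, tn$ionic, tn$prot, tn$cfg, probes = probes)
  at <- vapply(seq_len(ncol(sim$probe_vm)), function(p)
    fibroegm:::activation_time(sim$probe_vm[, p], sim$times_ms), numeric(1))
  expect_true(all(diff(at) > 0))
})

test_that("unstimulated tissue stays at rest", {
  tn <- tiny_sim()
  prot <- stimulus_protocol("left-edge", n_beats = 1, amplitude = 0)
  sim <- run_propagation(tn$grid, tn$ionic, prot, tn$cfg,
                         probes = cbind(4, 4, 0.2))
  expect_lt(max(abs(sim$probe_vm + 80)), 0.5)
})

test_that("too-large time steps are rejected by the stability guard", {
  tn <- tiny_sim()
  cfg <- tn$cfg
  cfg$dt <- 0.5
  expect_error(run_propagation(tn$grid, tn$ionic, tn$prot, cfg),
               "stability")
})

test_that("the Green's-function forward model is linear with zero response to uniform fields", {
  tn <- tiny_sim()
  n <- length(tn$grid$label)
  # uniform field -> zero potential at every electrode and time
  uni <- matrix(-80, n, 3)
  phi <- compute_unipolar_egms(uni, tn$grid, tn$layout, tn$cfg)
  expect_equal(max(abs(phi)), 0)
  set.seed(4)
  f1 <- matrix(stats::rnorm(n * 2), n)
  f2 <- matrix(stats::rnorm(n * 2), n)
  p1 <- compute_unipolar_egms(f1, tn$grid, tn$layout, tn$cfg)
  p2 <- compute_unipolar_egms(f2, tn$grid, tn$layout, tn$cfg)
  p12 <- compute_unipolar_egms(f1 + f2, tn$grid, tn$layout, tn$cfg)
  expect_equal(p12, p1 + p2, tolerance = 1e-10)
})

test_that("the in-kernel electrogram equals the standalone forward model", {
  tn <- tiny_sim()
  sim <- tn$sim
  # reconstruct EGMs from recorded field snapshots (every 10 ms)
  field_mv <- -80 + 110 * sim$field
  phi <- compute_unipolar_egms(field_mv, tn$grid, tn$layout, tn$cfg)
  stride <- 10 / (1000 / sim$fs)  # field snapshots vs 2 kHz EGM samples
  egm_sub <- sim$egm[seq_len(nrow(phi)) * stride, ]
  expect_equal(unname(egm_sub), unname(phi), tolerance = 1e-8)
})

test_that("electrode amplitude decays monotonically with height", {
  tn <- tiny_sim()
  heights <- c(0, 1, 2, 3, 5)
  W <- egm_weights(tn$grid, tn$layout, tn$cfg, heights = heights)
  field_mv <- -80 + 110 * tn$sim$field
  n_el <- nrow(tn$layout$electrodes)
  s <- apply(field_mv, 2, function(u) fibroegm:::source_density(tn$grid, u))
  p2p <- vapply(seq_along(heights), function(hix) {
    cols <- (hix - 1) * n_el + seq_len(n_el)
    phi <- t(-crossprod(W[, cols], s))
    mean(apply(phi, 2, function(x) diff(range(x))))
  }, numeric(1))
  expect_true(all(diff(p2p) < 0))
  expect_error(egm_weights(tn$grid, tn$layout, tn$cfg, heights = -1),
               "non-negative")
})

test_that("catheter geometries satisfy their printed spacings", {
  hd <- catheter_layout("hd-grid", spacing = 3)
  expect_equal(nrow(hd$electrodes), 16)
  expect_equal(nrow(hd$bipoles), 12)
  d <- as.matrix(dist(hd$electrodes[, c("x", "y")]))
  expect_equal(min(d[d > 0]), 3)
  la <- catheter_layout("lasso")
  expect_equal(nrow(la$electrodes), 20)
  expect_equal(nrow(la$bipoles), 10)
  r <- sqrt(la$electrodes$x^2 + la$electrodes$y^2)
  expect_equal(r, rep(80 / (2 * pi), 20), tolerance = 1e-9)
  # chord distances consistent with 2 mm / 6 mm arcs
  chord <- function(arc) 2 * (80 / (2 * pi)) * sin(arc / (2 * 80 / (2 * pi)))
  d12 <- sqrt(sum((la$electrodes[1, c("x", "y")] -
                     la$electrodes[2, c("x", "y")])^2))
  d23 <- sqrt(sum((la$electrodes[2, c("x", "y")] -
                     la$electrodes[3, c("x", "y")])^2))
  expect_equal(d12, chord(2), tolerance = 1e-9)
  expect_equal(d23, chord(6), tolerance = 1e-9)
  expect_error(catheter_layout("hd-grid", height = -0.5), "non-negative")
})
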
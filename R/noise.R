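#' Blank activity from a trace and collect noise segments
#'
#' Returns the maximal contiguous runs of the trace lying outside all
#' activity windows, each window padded by a guard on both sides; runs
#' shorter than `min_len` samples are discarded.
#'
#' @param x Trace, mV.
#' @param segments Activity segments ([detect_activity()] output; 0-based
#'   half-open sample indices).
#' @param fs Sampling rate, Hz.
#' @param guard_ms Guard band around each activity window, ms.
#' @param min_len Minimum run length in samples (>= 10 x the largest AR
#'   order that will be fitted).
#' @return List of numeric vectors (possibly empty).
#' @export
blank_activity <- function(x, segments, fs = 2000, guard_ms = 10,
                           min_len = 200) {
  n <- length(x)
  if (nrow(segments) > 0 &&
      (min(segments$start) < 0 || max(segments$end) > n))
    stop("activity segments out of trace bounds")
  blocked <- rep(FALSE, n)
  g <- round(guard_ms / 1000 * fs)
  for (i in seq_len(nrow(segments))) {
    s <- max(0, segments$start[i] - g)
    e <- min(n, segments$end[i] + g)
    if (e > s) blocked[(s + 1):e] <- TRUE
  }
  runs <- rle(!blocked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_len
  lapply(which(keep), function(i) x[starts[i]:ends[i]])
}

ar_fit_order <- function(x, p) {
  fit <- stats::ar.ols(x, aic = FALSE, order.max = p, demean = TRUE,
                       intercept = FALSE)
  phi <- as.numeric(fit$ar)
  res <- fit$resid[!is.na(fit$resid)]
  sigma2 <- mean(res^2)
  list(phi = phi, sigma2 = sigma2, n = length(res))
}

#' Fit an autoregressive model to one noise segment
#'
#' Least-squares AR fits at every candidate order `1..max_order`; the
#' per-segment order is the Bayesian information criterion minimizer.
#'
#' @param x Noise segment (mV).
#' @param max_order Largest candidate order.
#' @return List with `order`, `phi`, `sigma2`, and the per-order `bic` and
#'   `aic` vectors.
#' @export
fit_ar_segment <- function(x, max_order = 20) {
  n <- length(x)
  if (n < 10 * max_order) stop("segment too short for the candidate orders")
  if (stats::sd(x) < 1e-14) stop("degenerate (constant) segment")
  fits <- lapply(seq_len(max_order), function(p) ar_fit_order(x, p))
  sig <- vapply(fits, `[[`, numeric(1), "sigma2")
  bic <- n * log(sig) + seq_len(max_order) * log(n)
  aic <- n * log(sig) + 2 * seq_len(max_order)
  p_hat <- which.min(bic)
  list(order = p_hat, phi = fits[[p_hat]]$phi,
       sigma2 = fits[[p_hat]]$sigma2, bic = bic, aic = aic)
}

ar_roots <- function(phi) {
  # roots of z^p - phi_1 z^(p-1) - ... - phi_p (companion eigenvalues);
  # stationarity requires all |roots| < 1
  polyroot(c(-rev(phi), 1))
}

poly_from_roots <- function(roots) {
  coefs <- 1
  for (r in roots) coefs <- c(0, coefs) - c(r * coefs, 0)
  coefs  # ascending powers, monic
}

stabilize_ar <- function(phi, radius = 0.99) {
  rts <- ar_roots(phi)
  if (all(Mod(rts) < 1)) return(list(phi = phi, stabilized = FALSE))
  mods <- Mod(rts)
  rts[mods > radius] <- rts[mods > radius] * (radius / mods[mods > radius])
  coefs <- poly_from_roots(rts)  # z^p + a_{p-1} z^{p-1} + ... + a_0
  p <- length(phi)
  phi_new <- -Re(rev(coefs[seq_len(p)]))
  list(phi = phi_new, stabilized = TRUE)
}

#' Build the global autoregressive noise model
#'
#' Every segment is scored at each candidate order; the global order is the
#' one minimizing the Akaike information criterion summed across segments.
#' All segments are then re-fitted at the global order and the coefficients
#' and innovation variances averaged element-wise. If the averaged
#' polynomial is non-stationary its roots are radially shrunk to 0.99 and
#' the model flagged as stabilized.
#'
#' @param segments List of noise segments (>= 2).
#' @param max_order Largest candidate order.
#' @return An object of class `ar_model` with `order`, `phi`, `sigma2`,
#'   `stabilized`, `n_segments`.
#' @export
build_global_model <- function(segments, max_order = 20) {
  segments <- Filter(function(s) length(s) >= 10 * max_order &&
                       stats::sd(s) > 1e-14, segments)
  if (length(segments) < 2) stop("need at least 2 usable noise segments")
  aics <- vapply(segments, function(s) fit_ar_segment(s, max_order)$aic,
                 numeric(max_order))
  p_star <- which.min(rowSums(aics))
  refits <- lapply(segments, function(s) ar_fit_order(s, p_star))
  phi <- rowMeans(vapply(refits, `[[`, numeric(p_star), "phi"))
  sigma2 <- mean(vapply(refits, `[[`, numeric(1), "sigma2"))
  st <- stabilize_ar(phi)
  structure(list(order = p_star, phi = st$phi, sigma2 = sigma2,
                 stabilized = st$stabilized,
                 n_segments = length(segments)),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("ar_model: order %d, sigma2 = %.4g mV^2, %d segments%s\n",
              x$order, x$sigma2, x$n_segments,
              if (isTRUE(x$stabilized)) " (stabilized)" else ""))
  cat("  phi:", paste(sprintf("%.4f", x$phi), collapse = " "), "\n")
  invisible(x)
}

#' Construct an AR model directly from coefficients
#'
#' @param phi Coefficient vector.
#' @param sigma2 Innovation variance (mV^2).
#' @return An `ar_model`.
#' @export
ar_model <- function(phi, sigma2) {
  structure(list(order = length(phi), phi = phi, sigma2 = sigma2,
                 stabilized = FALSE, n_segments = 0L), class = "ar_model")
}

ar_is_stable <- function(model) all(Mod(ar_roots(model$phi)) < 1)

#' Generate noise from an AR model
#'
#' Forward recursion with Gaussian white innovations and a burn-in of
#' 10 x order samples.
#'
#' @param model An `ar_model` (must be stationary).
#' @param n Number of output samples.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_noise <- function(model, n, seed = NULL) {
  if (!ar_is_stable(model)) stop("AR model is not stationary")
  if (model$sigma2 == 0) return(numeric(n))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  burn <- 10 * model$order
  eps <- stats::rnorm(n + burn, sd = sqrt(model$sigma2))
  x <- stats::filter(eps, model$phi, method = "recursive")
  as.numeric(x)[(burn + 1):(burn + n)]
}

#' AR model transfer-function spectrum
#'
#' Theoretical power spectral density `sigma2 / |1 - sum phi_i e^(-i w k)|^2`
#' (two-sided, unit sampling).
#'
#' @param model An `ar_model`.
#' @param freq Normalized frequencies in cycles/sample.
#' @return PSD values.
#' @export
ar_spectrum <- function(model, freq) {
  H <- vapply(freq, function(f) {
    denom <- 1 - sum(model$phi * exp(-2i * pi * f * seq_along(model$phi)))
    1 / Mod(denom)^2
  }, numeric(1))
  model$sigma2 * H
}

#' Add AR model noise to a trace at a prescribed SNR
#'
#' Noise is generated from the model and rescaled so that the ratio of the
#' signal power inside the active windows to the noise power equals
#' `snr_db`, then added sample-wise. `snr_db = Inf` returns the trace
#' unchanged.
#'
#' @param x Clean trace, mV.
#' @param model An `ar_model`.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Optional integer seed.
#' @param segments Optional activity segments over which signal power is
#'   measured; whole-trace power when `NULL`.
#' @return Noisy trace.
#' @export
add_noise <- function(x, model, snr_db, seed = NULL, segments = NULL) {
  if (length(x) == 0) stop("empty trace")
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  if (is.null(segments) || nrow(segments) == 0) {
    p_sig <- mean(x^2)
  } else {
    active <- unlist(lapply(seq_len(nrow(segments)), function(i)
      (segments$start[i] + 1):segments$end[i]))
    p_sig <- mean(x[active]^2)
  }
  if (p_sig <= 0) stop("trace has zero power in the reference windows")
  w <- generate_noise(model, length(x), seed = seed)
  p_target <- p_sig / 10^(snr_db / 10)
  x + w * sqrt(p_target / mean(w^2))
}

#' Measured SNR between a clean and a noisy trace
#'
#' @param clean,noisy Traces of equal length.
#' @param segments Optional activity segments for the signal-power window.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy, segments = NULL) {
  w <- noisy - clean
  if (is.null(segments) || nrow(segments) == 0) {
    p_sig <- mean(clean^2)
  } else {
    active <- unlist(lapply(seq_len(nrow(segments)), function(i)
      (segments$start[i] + 1):segments$end[i]))
    p_sig <- mean(clean[active]^2)
  }
  10 * log10(p_sig / mean(w^2))
}

#' Serialize an AR model to JSON
#' @param model An `ar_model`.
#' @param path Output file.
#' @export
write_ar_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
}

#' Read an AR model from JSON
#' @param path Input file written by [write_ar_model()].
#' @return An `ar_model`.
#' @export
read_ar_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m[c("order", "phi", "sigma2", "stabilized", "n_segments")],
            class = "ar_model")
}
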
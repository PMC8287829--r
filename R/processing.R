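#' Band-pass filter specification
#'
#' Second-order Butterworth band-pass, applied zero-phase (forward-backward)
#' so activity-segment timing stays unbiased; the effective order doubles.
#' Designed in second-order-sections-free `signal::butter` form; the upper
#' unipolar edge of 900 Hz at fs = 2 kHz is 0.9 x Nyquist and is kept as the
#' study passband.
#'
#' @param low,high Band edges, Hz.
#' @param fs Sampling rate, Hz.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low, high, fs = 2000) {
  ny <- fs / 2
  if (!(low > 0 && high > low && high < ny))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  structure(list(low = low, high = high, fs = fs, order = 2),
            class = "filter_spec")
}

apply_bandpass <- function(x, spec) {
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (spec$fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Filter a unipolar electrogram
#'
#' Zero-phase second-order Butterworth band-pass between 0.05 and 900 Hz at
#' 2 kHz; removes the DC component.
#'
#' @param x Unipolar trace, mV at `fs` Hz.
#' @param fs Sampling rate, Hz (2000).
#' @return Filtered trace.
#' @export
filter_unipolar <- function(x, fs = 2000) {
  # the 0.05 Hz edge cannot drain a DC step within a short trace, so the
  # mean is removed explicitly before filtering
  apply_bandpass(x - mean(x), filter_spec(0.05, 900, fs))
}

#' Derive a bipolar electrogram
#'
#' Difference of two unipolar traces followed by the clinical 30-300 Hz
#' second-order zero-phase Butterworth band-pass.
#'
#' @param u_a,u_b Unipolar traces of equal length (mV).
#' @param fs Sampling rate, Hz.
#' @return Bipolar trace, mV.
#' @export
make_bipolar <- function(u_a, u_b, fs = 2000) {
  if (length(u_a) != length(u_b)) stop("unipolar traces differ in length")
  apply_bandpass(u_a - u_b, filter_spec(30, 300, fs))
}

#' All bipolar traces of a catheter
#'
#' @param unipolar Matrix (samples x electrodes) with electrode ids as column
#'   names (or in layout order).
#' @param layout A [catheter_layout()].
#' @param fs Sampling rate, Hz.
#' @param prefilter If `TRUE`, apply [filter_unipolar()] to each column first.
#' @return Matrix (samples x bipoles), columns named `anode-cathode`.
#' @export
bipolar_matrix <- function(unipolar, layout, fs = 2000, prefilter = FALSE) {
  ids <- colnames(unipolar)
  if (is.null(ids)) ids <- layout$electrodes$id
  if (prefilter) unipolar <- apply(unipolar, 2, filter_unipolar, fs = fs)
  bp <- layout$bipoles
  out <- vapply(seq_len(nrow(bp)), function(b) {
    make_bipolar(unipolar[, match(bp$anode[b], ids)],
                 unipolar[, match(bp$cathode[b], ids)], fs = fs)
  }, numeric(nrow(unipolar)))
  colnames(out) <- paste0(bp$anode, "-", bp$cathode)
  out
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Real-valued trace.
#' @return Complex vector `x + i H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Detect activity segments in Hilbert space
#'
#' Embeds the bipolar trace as its analytic signal, measures the distance of
#' every sample from the trace centroid (the time-mean of the analytic
#' signal), and marks samples whose radius exceeds the mean plus one standard
#' deviation of the radius distribution as active. Gaps shorter than
#' `merge_gap_ms` are merged and segments shorter than `min_dur_ms`
#' discarded. The first and last 50 ms are excluded from threshold
#' estimation (edge transients).
#'
#' @param x Bipolar trace, mV.
#' @param fs Sampling rate, Hz.
#' @param merge_gap_ms Merge gaps shorter than this, ms.
#' @param min_dur_ms Discard segments shorter than this, ms.
#' @return A data.frame of class `activity_segments` with 0-based half-open
#'   `start`/`end` sample indices, `duration_ms`, and the threshold used;
#'   empty for degenerate (constant) traces.
#' @export
detect_activity <- function(x, fs = 2000, merge_gap_ms = 10, min_dur_ms = 5) {
  n <- length(x)
  if (n < 0.25 * fs) stop("trace shorter than 250 ms")
  empty <- data.frame(start = integer(0), end = integer(0),
                      duration_ms = numeric(0), threshold = numeric(0))
  class(empty) <- c("activity_segments", "data.frame")
  if (stats::sd(x) < 1e-12) return(empty)
  z <- analytic_signal(x)
  r <- Mod(z - mean(z))
  guard <- round(0.05 * fs)
  interior <- r[(guard + 1):(n - guard)]
  theta <- mean(interior) + stats::sd(interior)
  if (!is.finite(theta) || stats::sd(interior) < 1e-12) return(empty)
  mask <- r > theta

  runs <- rle(mask)
  # merge short inactive gaps between active runs
  gap <- round(merge_gap_ms / 1000 * fs)
  if (length(runs$values) > 2) {
    for (i in seq_along(runs$values)) {
      if (!runs$values[i] && i > 1 && i < length(runs$values) &&
          runs$lengths[i] < gap)
        runs$values[i] <- TRUE
    }
    mask <- inverse.rle(runs)
    runs <- rle(mask)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths  # 0-based
  keep <- runs$values & runs$lengths >= round(min_dur_ms / 1000 * fs)
  seg <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(seg)) {
    seg$duration_ms <- (seg$end - seg$start) / fs * 1000
    seg$threshold <- theta
  } else seg <- empty
  class(seg) <- c("activity_segments", "data.frame")
  seg
}

#' Peak-to-peak amplitude within a segment
#'
#' @param x Bipolar trace, mV.
#' @param segment One row of [detect_activity()] output (0-based half-open).
#' @return max - min over the segment, mV.
#' @export
peak_to_peak <- function(x, segment) {
  s <- segment$start[1]; e <- segment$end[1]
  if (is.na(s) || is.na(e) || e <= s) stop("empty segment")
  if (s < 0 || e > length(x)) stop("segment out of trace bounds")
  diff(range(x[(s + 1):e]))
}

segment_samples <- function(x, start, end) x[(start + 1):end]

# Window of at least min_len samples centred on the segment, clipped to the
# trace; stabilizes complexity estimates on short activity segments.
segment_window <- function(x, start, end, min_len) {
  len <- end - start
  if (len >= min_len) return(segment_samples(x, start, end))
  pad <- ceiling((min_len - len) / 2)
  s <- max(0, start - pad)
  e <- min(length(x), end + pad)
  if (e - s < min_len) {
    if (s == 0) e <- min(length(x), min_len)
    else s <- max(0, e - min_len)
  }
  segment_samples(x, s, e)
}
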
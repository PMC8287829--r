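#' Sample entropy
#'
#' Negative natural log of the conditional probability that two sequences
#' similar for m points remain similar at m + 1, under the Chebyshev metric
#' with tolerance `r_factor` times the signal standard deviation; self-matches
#' excluded (Richman-Moorman convention, m = 2, r = 0.2 SD by default).
#'
#' @param x Numeric trace.
#' @param m Template length.
#' @param r_factor Tolerance as a fraction of `sd(x)`; alternatively pass an
#'   absolute tolerance via `r`.
#' @param r Absolute tolerance (overrides `r_factor`).
#' @return Sample entropy (0 for a constant sequence; `NA` if no template
#'   matches exist at either length).
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  n <- length(x)
  if (n <= m + 1) stop("trace too short for sample entropy")
  if (is.null(r)) r <- r_factor * stats::sd(x)
  if (r == 0) return(0)  # constant sequence: all templates match
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), r)
  B <- cnt[1]; A <- cnt[2]
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Shannon entropy of the amplitude distribution
#'
#' Histogram entropy over `n_bins` equal-width bins spanning the trace's own
#' range; empty bins contribute zero.
#'
#' @param x Numeric trace.
#' @param n_bins Number of amplitude bins (default 64).
#' @return Entropy in bits (0 for a constant trace).
#' @export
shannon_entropy <- function(x, n_bins = 64) {
  if (length(x) < n_bins) stop("trace shorter than the number of bins")
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  cuts <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Welch power spectral density
#'
#' Hann-windowed segment-averaged periodogram (one-sided).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate, Hz.
#' @param nseg Segment length in samples (default 256).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs = 2000, nseg = 256, overlap = 0.5) {
  n <- length(x)
  if (n < nseg) stop("trace shorter than one Welch segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nseg %/% 2 + 1)]
  }
  psd <- acc / (length(starts) * sum(w^2) * fs)
  psd[2:(nseg %/% 2)] <- 2 * psd[2:(nseg %/% 2)]
  list(freq = (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg, psd = psd)
}

#' Spectral entropy
#'
#' Normalized entropy of the Welch power spectral density treated as a
#' probability mass over frequency bins: `-sum(p log p) / log K`, in \[0, 1\].
#'
#' @param x Numeric trace (length >= 256).
#' @param fs Sampling rate, Hz.
#' @return Spectral entropy in \[0, 1\]; `NA` for a zero-power trace.
#' @export
spectral_entropy <- function(x, fs = 2000) {
  if (length(x) < 256) stop("trace shorter than 256 samples")
  ps <- welch_psd(x, fs)$psd
  tot <- sum(ps)
  if (tot <= 0 || !is.finite(tot)) return(NA_real_)
  p <- ps / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(ps))
}

#' Lempel-Ziv (LZ76) phrase count
#'
#' Exhaustive-history parsing of a binary sequence (Lempel-Ziv production
#' complexity): the number of phrases in the canonical left-to-right parsing
#' where each new phrase is the shortest substring not reproducible from the
#' extended history. A constant sequence parses into two phrases (the first
#' symbol plus one reproducible run).
#'
#' @param b Logical or 0/1 vector.
#' @return Integer phrase count.
#' @export
lz76_phrases <- function(b) {
  b <- as.integer(as.logical(b))
  n <- length(b)
  if (n == 0) return(0L)
  c_n <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  repeat {
    if (b[i + k] == b[l + k]) {
      k <- k + 1L
      if (l + k > n) {
        c_n <- c_n + 1L
        break
      }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_n <- c_n + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  c_n
}

#' Normalized Lempel-Ziv complexity of a signal
#'
#' Binarizes the signal around its median and returns the LZ76 phrase count
#' normalized by the asymptotic phrase rate of a random sequence,
#' `c * log2(n) / n` (a computable surrogate for Kolmogorov complexity).
#'
#' @param x Numeric trace (length >= 16).
#' @return Normalized complexity (near 1 for random sequences).
#' @export
lz_complexity <- function(x) {
  n <- length(x)
  if (n < 16) stop("trace shorter than 16 samples")
  med <- stats::median(x)
  b <- x > med
  # discrete-valued signals can put the median on the upper level; fall back
  # to >= so the binarization still splits the sequence
  if (!any(b)) b <- x >= med
  lz76_phrases(b) * log2(n) / n
}

#' Higuchi fractal dimension
#'
#' Slope of log mean curve length against log(1/k) over lag scales
#' `k = 1..k_max` (Higuchi's method); near 1 for smooth curves and near 2
#' for white noise.
#'
#' @param x Numeric trace (length >= 100).
#' @param k_max Maximum lag (default 16).
#' @return Fractal dimension; `NA` for a constant trace.
#' @export
fractal_dimension <- function(x, k_max = 16) {
  n <- length(x)
  if (n < 100) stop("trace shorter than 100 samples")
  if (stats::sd(x) == 0) return(NA_real_)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm_sum <- 0
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) next
      norm <- (n - 1) / (ni * k)
      lm_sum <- lm_sum + sum(abs(diff(x[idx]))) * norm / k
    }
    lk[k] <- lm_sum / k
  }
  ok <- lk > 0
  if (sum(ok) < 2) return(NA_real_)
  stats::coef(stats::lm(log(lk[ok]) ~ log(1 / seq_len(k_max)[ok])))[[2]]
}

#' Names of the seven study features
#' @return Character vector in the canonical order used for tie-breaking.
#' @export
feature_names <- function() {
  c("duration", "p2p", "samp_en", "sh_en", "sp_en", "lz", "fd")
}

#' Extract the seven features from a bipolar trace
#'
#' Per-segment features (peak-to-peak amplitude, sample entropy, Shannon
#' entropy, spectral entropy, Lempel-Ziv complexity) are averaged across the
#' detected activity segments; the fractal dimension is computed on the
#' whole trace. The duration feature is the mean span of each beat's
#' activity cluster (segments closer than `cluster_gap_ms` belong to one
#' beat): in fibrotic substrate a single activation can fragment into
#' several bursts, and the clinically meaningful duration is the total
#' activation time of the tissue underneath the electrode, i.e. the
#' first-to-last extent of the beat's activity. Complexity estimators on
#' short segments use a window of at least 100 ms (128 ms for spectral
#' entropy, whose Welch estimator needs 256 samples) centred on the segment.
#'
#' @param x Bipolar trace, mV.
#' @param segments [detect_activity()] output for `x`.
#' @param fs Sampling rate, Hz.
#' @param cluster_gap_ms Segments separated by less than this belong to the
#'   same beat (default 250 ms, well below any pacing interval and above
#'   intra-beat fractionation gaps).
#' @return One-row data.frame with columns [feature_names()], or `NULL` when
#'   no activity segment exists (the trace is unusable for classification).
#' @export
extract_features <- function(x, segments, fs = 2000, cluster_gap_ms = 250) {
  if (is.null(segments) || nrow(segments) == 0) return(NULL)
  win100 <- round(0.1 * fs)
  cl <- cumsum(c(1, diff(segments$start) > cluster_gap_ms / 1000 * fs))
  cluster_dur <- mean(vapply(split(segments, cl), function(s)
    (max(s$end) - min(s$start)) / fs * 1000, numeric(1)))
  per <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]; e <- segments$end[i]
    seg <- segment_window(x, s, e, win100)
    seg256 <- segment_window(x, s, e, 256)
    data.frame(p2p = peak_to_peak(x, segments[i, , drop = FALSE]),
               samp_en = sample_entropy(seg),
               sh_en = shannon_entropy(seg, n_bins = min(64, length(seg))),
               sp_en = spectral_entropy(seg256, fs),
               lz = lz_complexity(seg))
  })
  per <- do.call(rbind, per)
  out <- cbind(data.frame(duration = cluster_dur),
               as.data.frame(as.list(colMeans(per))))
  out$fd <- fractal_dimension(x)
  out
}
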
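#' Write electrogram traces to delimited text
#'
#' Tab-separated, one column per electrode, with a comment header carrying
#' the sampling rate and units (mV).
#'
#' @param traces Matrix (samples x electrodes), mV.
#' @param path Output file.
#' @param fs Sampling rate, Hz.
#' @export
write_traces <- function(traces, path, fs = 2000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fibroegm traces v1 fs_hz=%g units=mV", fs), con)
  utils::write.table(as.data.frame(traces), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Read electrogram traces written by [write_traces()]
#'
#' @param path Input file.
#' @return Matrix (samples x electrodes) with `fs` attribute.
#' @export
read_traces <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs_hz=([0-9.]+).*", "\\1", hdr))
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         check.names = FALSE)
  m <- as.matrix(d)
  attr(m, "fs") <- fs
  m
}

#' Write a segments table
#'
#' One row per detected activity segment: trace id, start/end (ms),
#' duration (ms) and segment peak-to-peak amplitude (mV).
#'
#' @param seg_table data.frame as produced by [segments_table()].
#' @param path Output CSV file.
#' @export
write_segments <- function(seg_table, path) {
  utils::write.csv(seg_table, path, row.names = FALSE, quote = FALSE)
}

#' Tabulate detected segments across bipoles
#'
#' @param bipolar Matrix (samples x bipoles).
#' @param segments List of [detect_activity()] outputs per bipole.
#' @param fs Sampling rate, Hz.
#' @return data.frame: trace, start_ms, end_ms, duration_ms, p2p_mv.
#' @export
segments_table <- function(bipolar, segments, fs = 2000) {
  out <- lapply(seq_along(segments), function(b) {
    s <- segments[[b]]
    if (nrow(s) == 0) return(NULL)
    data.frame(trace = colnames(bipolar)[b] %||% as.character(b),
               start_ms = s$start / fs * 1000, end_ms = s$end / fs * 1000,
               duration_ms = s$duration_ms,
               p2p_mv = vapply(seq_len(nrow(s)), function(i)
                 peak_to_peak(bipolar[, b], s[i, , drop = FALSE]),
                 numeric(1)))
  })
  do.call(rbind, out) %||%
    data.frame(trace = character(0), start_ms = numeric(0),
               end_ms = numeric(0), duration_ms = numeric(0),
               p2p_mv = numeric(0))
}

#' Write / read a labeled feature table
#'
#' @param features Labeled feature table.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = TRUE)
}

#' @rdname write_features
#' @return `read_features`: the labeled table with label factors restored.
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("label_binary" %in% names(d)) {
    d$label_binary <- factor(d$label_binary, levels = BINARY_LEVELS)
    d$label_density <- factor(as.character(d$label_density),
                              levels = DENSITY_LEVELS)
    d$label_transmurality <- factor(as.character(d$label_transmurality),
                                    levels = TRANSMURALITY_LEVELS)
  }
  d
}

#' Write / read a substrate map as delimited text
#'
#' @param map A `substrate_map`.
#' @param path TSV path.
#' @export
write_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fibroegm map v1 seed=%d", map$seed), con)
  utils::write.table(map$points, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_map
#' @return `read_map`: a `substrate_map` (without the generating spec).
#' @export
read_map <- function(path) {
  hdr <- readLines(path, n = 1)
  seed <- as.integer(sub(".*seed=(-?[0-9]+).*", "\\1", hdr))
  pts <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  pts$label_binary <- factor(pts$label_binary, levels = BINARY_LEVELS)
  pts$label_density <- factor(as.character(pts$label_density),
                              levels = DENSITY_LEVELS)
  pts$label_transmurality <- factor(as.character(pts$label_transmurality),
                                    levels = TRANSMURALITY_LEVELS)
  if ("voltage" %in% names(pts))
    pts$voltage <- factor(pts$voltage, levels = c("low", "high"))
  structure(list(points = pts, spec = NULL, seed = seed),
            class = "substrate_map")
}
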
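#' Electropherogram forward model
#'
#' Synthesizes a two-channel fluorescence trace for one isolate record: the
#' sample channel carries one Gaussian peak per true amplicon size and the
#' ladder channel one peak per internal-standard fragment. Fragment size is
#' mapped to migration position (scan index) through a strictly monotone,
#' mildly nonlinear mobility curve `scan = a + b * size^p`, so that naive
#' linear sizing is detectably wrong and calibration by interpolation is
#' genuinely exercised.
#'
#' @param record one row of an isolate records data.frame (not trace_failed).
#' @param ladder integer fragment sizes, default [default_ladder()].
#' @param noise_sd additive Gaussian noise s.d. (a.u.), default 25.
#' @param height_major apex height of the major peak (a.u.), default 10000.
#' @param minor_ratio minor-peak apex height as a fraction of the major.
#' @param seed integer seed for the noise.
#' @return an object of class `isr_trace`: list with `scan` (integer axis),
#'   `sample`, `ladder_signal` (non-negative numeric channels) and `ladder`
#'   (the fragment sizes).
#' @export
synth_trace <- function(record, ladder = default_ladder(), noise_sd = 25,
                        height_major = 10000, minor_ratio = 0.35, seed = 1) {
  if (isTRUE(record$trace_failed)) {
    stopf("record '%s' is flagged trace_failed; no trace to synthesize",
          record$isolate_id)
  }
  sizes <- c(record$major_bp, split_sizes(record$minors_bp)[[1]])
  heights <- c(height_major, rep(minor_ratio * height_major,
                                 length(sizes) - 1L))
  if (any(sizes < min(ladder) | sizes > max(ladder))) {
    stopf("record '%s' has peak sizes outside the ladder range %d-%d bp; unsizable",
          record$isolate_id, min(ladder), max(ladder))
  }
  n_scan <- trace_length()
  set.seed(derive_seed(seed, 51L))
  smp <- peak_signal(n_scan, size_to_scan(sizes), heights)
  lad <- peak_signal(n_scan, size_to_scan(ladder),
                     rep(6000, length(ladder)))
  if (noise_sd > 0) {
    smp <- smp + stats::rnorm(n_scan, 0, noise_sd)
    lad <- lad + stats::rnorm(n_scan, 0, noise_sd)
  }
  structure(list(scan = seq_len(n_scan),
                 sample = pmax(smp, 0),
                 ladder_signal = pmax(lad, 0),
                 ladder = ladder),
            class = "isr_trace")
}

# mobility curve: strictly monotone in size; defaults chosen so the full
# 50-1000 bp window maps to ~1.8k-20.6k scans (a 1.5 h capillary run)
size_to_scan <- function(size, a = 500, b = 40, p = 0.9) {
  a + b * size^p
}

trace_length <- function() {
  as.integer(ceiling(size_to_scan(1000)) + 300L)
}

# sum of Gaussian apexes (sigma in scans) evaluated on the integer axis
peak_signal <- function(n_scan, apex, height, sigma = 6) {
  y <- numeric(n_scan)
  for (k in seq_along(apex)) {
    lo <- max(1L, floor(apex[k] - 8 * sigma))
    hi <- min(n_scan, ceiling(apex[k] + 8 * sigma))
    idx <- lo:hi
    y[idx] <- y[idx] + height[k] * exp(-((idx - apex[k])^2) / (2 * sigma^2))
  }
  y
}

#' @export
print.isr_trace <- function(x, ...) {
  cat(sprintf("ISR trace: %d scans, %d ladder fragments (%d-%d bp)\n",
              length(x$scan), length(x$ladder), min(x$ladder),
              max(x$ladder)))
  invisible(x)
}

#' Write a trace as a plain-text TSV (scan, sample, ladder channels)
#' @param trace an `isr_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(
    data.frame(scan = trace$scan, sample = signif(trace$sample, 7),
               ladder = signif(trace$ladder_signal, 7)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
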
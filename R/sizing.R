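#' Detect peaks in one fluorescence channel
#'
#' Returns apexes of local maxima above `min_height`, thinned so that no two
#' reported peaks are closer than `min_separation` scans (taller peaks win;
#' ties broken toward the earlier scan). A plateau of equal values counts as
#' one peak at its left edge.
#'
#' @param channel numeric signal over the scan axis.
#' @param min_height minimum apex height (a.u.), must be > 0.
#' @param min_separation minimum apex spacing in scans.
#' @return data.frame `scan`, `height`, sorted by scan.
#' @export
detect_peaks <- function(channel, min_height = 500, min_separation = 12) {
  if (length(channel) == 0L) stopf("empty signal")
  if (!all(is.finite(channel))) stopf("signal contains non-finite values")
  if (min_height <= 0) stopf("min_height must be positive")
  n <- length(channel)
  prev <- c(-Inf, channel[-n])
  nxt <- c(channel[-1L], -Inf)
  cand <- which(channel >= min_height & channel >= prev & channel > nxt)
  if (length(cand) == 0L) {
    return(data.frame(scan = integer(0), height = numeric(0)))
  }
  h <- channel[cand]
  ord <- order(-h, cand)
  keep <- logical(length(cand))
  kept_scans <- integer(0)
  for (i in ord) {
    if (length(kept_scans) == 0L ||
        all(abs(kept_scans - cand[i]) >= min_separation)) {
      keep[i] <- TRUE
      kept_scans <- c(kept_scans, cand[i])
    }
  }
  out <- data.frame(scan = cand[keep], height = h[keep])
  out[order(out$scan), , drop = FALSE]
}

#' Calibrate scan position against the internal size standard
#'
#' Matches detected ladder-channel peaks to the known fragment sizes by rank
#' order and fits a strictly monotone piecewise-cubic interpolant
#' (Hyman-filtered spline, local-Southern-like behaviour) through the
#' (scan, size) knots. All fragments must be accounted for: if fewer peaks
#' than fragments were detected the trace fails calibration, mirroring
#' failed electropherograms; extra noise peaks are discarded by keeping the
#' tallest `length(ladder)` before matching.
#'
#' @param ladder_peaks data.frame from [detect_peaks()] on the ladder
#'   channel, sorted by scan.
#' @param ladder known fragment sizes (bp), default [default_ladder()].
#' @return an `isr_calibration`: list with `knots` (scan, size_bp) and the
#'   interpolating function; exact at every knot.
#' @export
calibrate <- function(ladder_peaks, ladder = default_ladder()) {
  n_frag <- length(ladder)
  if (nrow(ladder_peaks) < n_frag) {
    stop(structure(
      class = c("isr_calibration_error", "error", "condition"),
      list(message = sprintf(
        "calibration failure: %d ladder peaks detected, %d fragments required",
        nrow(ladder_peaks), n_frag), call = NULL)))
  }
  if (nrow(ladder_peaks) > n_frag) {
    ord <- order(-ladder_peaks$height, ladder_peaks$scan)
    ladder_peaks <- ladder_peaks[sort(ord[seq_len(n_frag)]), , drop = FALSE]
  }
  ladder_peaks <- ladder_peaks[order(ladder_peaks$scan), , drop = FALSE]
  knots <- data.frame(scan = ladder_peaks$scan, size_bp = sort(ladder))
  if (is.unsorted(knots$scan, strictly = TRUE)) {
    stopf("ladder peak scans are not strictly increasing")
  }
  fun <- stats::splinefun(knots$scan, knots$size_bp, method = "hyman")
  structure(list(knots = knots, fun = fun), class = "isr_calibration")
}

#' Convert scan positions to fragment sizes
#'
#' Positions outside the calibrated knot range are not extrapolated and
#' return NA.
#'
#' @param calibration an `isr_calibration`.
#' @param scan numeric scan positions.
#' @return numeric sizes in bp (NA outside the calibrated range).
#' @export
predict_size <- function(calibration, scan) {
  out <- calibration$fun(scan)
  rng <- range(calibration$knots$scan)
  out[scan < rng[1] | scan > rng[2]] <- NA_real_
  out
}

#' @export
print.isr_calibration <- function(x, ...) {
  cat(sprintf("ISR calibration: %d knots, %d-%d bp over scans %d-%d\n",
              nrow(x$knots), min(x$knots$size_bp), max(x$knots$size_bp),
              min(x$knots$scan), max(x$knots$scan)))
  invisible(x)
}

#' Size sample peaks and classify them into a major/minor fingerprint
#'
#' Each detected sample peak is sized through the calibration and rounded
#' half away from zero to integer bp. The tallest peak is the isolate's
#' major amplicon (exact height ties go to the smaller size); remaining
#' peaks at least `minor_height_frac` of the major's height become minors,
#' anything smaller is treated as noise. Peaks outside the calibrated range
#' are dropped with a warning.
#'
#' @param sample_peaks data.frame from [detect_peaks()] on the sample
#'   channel.
#' @param calibration an `isr_calibration`.
#' @param minor_height_frac minimum minor/major height ratio, in (0, 1).
#' @param isolate_id label carried into the profile.
#' @return one-row profile data.frame: `isolate_id`, `quality` (ok/failed),
#'   `major_bp`, `minors_bp` (semicolon-joined ascending).
#' @export
size_and_classify <- function(sample_peaks, calibration,
                              minor_height_frac = 0.10,
                              isolate_id = "isolate") {
  if (minor_height_frac <= 0 || minor_height_frac >= 1) {
    stopf("minor_height_frac must lie in (0, 1)")
  }
  if (nrow(sample_peaks) == 0L) return(failed_profile(isolate_id))
  size <- predict_size(calibration, sample_peaks$scan)
  if (anyNA(size)) {
    warning(sprintf("isolate '%s': %d peak(s) outside the calibrated range dropped",
                    isolate_id, sum(is.na(size))), call. = FALSE)
  }
  ok <- !is.na(size)
  if (!any(ok)) return(failed_profile(isolate_id))
  size <- as.integer(round_half_away(size[ok]))
  height <- sample_peaks$height[ok]
  ord <- order(-height, size)
  major_size <- size[ord[1L]]
  major_h <- height[ord[1L]]
  rest <- ord[-1L]
  minors <- size[rest][height[rest] >= minor_height_frac * major_h]
  minors <- sort(unique(setdiff(minors, major_size)))
  data.frame(isolate_id = isolate_id, quality = "ok",
             major_bp = major_size, minors_bp = join_sizes(list(minors)),
             stringsAsFactors = FALSE)
}

failed_profile <- function(isolate_id) {
  n <- length(isolate_id)
  data.frame(isolate_id = isolate_id, quality = rep("failed", n),
             major_bp = rep(NA_integer_, n), minors_bp = rep("", n),
             stringsAsFactors = FALSE)
}

#' Interspacer length of a sized amplicon
#'
#' The PCR amplicon carries 99 bp of 16S and 22 bp of 23S rDNA flanking the
#' interspacer, so the spacer proper is the sized fragment minus 121 bp.
#'
#' @param size_bp sized amplicon length(s), must exceed 121.
#' @return integer interspacer length(s).
#' @export
#' @examples
#' amplicon_to_isr(289)
amplicon_to_isr <- function(size_bp) {
  if (any(size_bp <= 121)) {
    stopf("amplicon of <= 121 bp cannot contain an interspacer")
  }
  as.integer(size_bp) - 121L
}

#' Full trace-to-fingerprint pipeline for one trace
#'
#' Detects peaks in both channels, calibrates against the ladder, sizes the
#' sample peaks and classifies them. Calibration failure yields a failed
#' profile rather than an error.
#'
#' @param trace an `isr_trace`.
#' @param isolate_id label for the profile.
#' @param min_height,min_separation peak-detection settings (both channels).
#' @param minor_height_frac see [size_and_classify()].
#' @return one-row profile data.frame.
#' @export
profile_trace <- function(trace, isolate_id = "isolate", min_height = 500,
                          min_separation = 12, minor_height_frac = 0.10) {
  lad <- detect_peaks(trace$ladder_signal, min_height, min_separation)
  cal <- tryCatch(calibrate(lad, trace$ladder),
                  isr_calibration_error = function(e) NULL)
  if (is.null(cal)) return(failed_profile(isolate_id))
  smp <- detect_peaks(trace$sample, min_height, min_separation)
  size_and_classify(smp, cal, minor_height_frac, isolate_id)
}

#' Profiles from a pre-sized peak table
#'
#' Alternative entry point bypassing trace synthesis and calibration: a peak
#' table with one row per (isolate, sized peak) is classified directly into
#' major/minor fingerprints with the same height rules as
#' [size_and_classify()].
#'
#' @param peak_table data.frame with columns `isolate_id`, `size_bp`,
#'   `height`.
#' @param minor_height_frac minimum minor/major height ratio.
#' @return profile data.frame, one row per isolate, sorted by isolate_id.
#' @export
classify_peak_table <- function(peak_table, minor_height_frac = 0.10) {
  stopifnot(all(c("isolate_id", "size_bp", "height") %in%
                  names(peak_table)))
  ids <- sort(unique(peak_table$isolate_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    pt <- peak_table[peak_table$isolate_id == id, , drop = FALSE]
    ord <- order(-pt$height, pt$size_bp)
    major <- as.integer(pt$size_bp[ord[1L]])
    major_h <- pt$height[ord[1L]]
    rest <- ord[-1L]
    minors <- as.integer(pt$size_bp[rest][pt$height[rest] >=
                                            minor_height_frac * major_h])
    minors <- sort(unique(setdiff(minors, major)))
    data.frame(isolate_id = id, quality = "ok", major_bp = major,
               minors_bp = join_sizes(list(minors)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fingerprints straight from generator truth
#'
#' Bypasses the trace layer entirely: each intact record's true peak sizes
#' become its profile (majors keep unit height ratio to minors of 0.35, so
#' the minor threshold behaves as in the trace path); records flagged
#' trace_failed yield failed profiles.
#'
#' @param records isolate records data.frame.
#' @param minor_height_frac minimum minor/major height ratio.
#' @return profile data.frame, one row per record.
#' @export
profiles_from_records <- function(records, minor_height_frac = 0.10) {
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    if (records$trace_failed[i]) {
      return(failed_profile(records$isolate_id[i]))
    }
    minors <- split_sizes(records$minors_bp[i])[[1]]
    keep <- if (0.35 >= minor_height_frac) minors else integer(0)
    data.frame(isolate_id = records$isolate_id[i], quality = "ok",
               major_bp = records$major_bp[i],
               minors_bp = join_sizes(list(sort(unique(keep)))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read fingerprint profiles as TSV
#' @param profiles profile data.frame.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  pr <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  pr$major_bp <- suppressWarnings(as.integer(pr$major_bp))
  pr$minors_bp[is.na(pr$minors_bp)] <- ""
  pr
}
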
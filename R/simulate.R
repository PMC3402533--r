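#' Simulate an isolate collection from the phylotype panel
#'
#' Draws isolate records whose true ISR peak sizes, phenotype scores and
#' study-arm membership follow the panel's per-phylotype parameters.
#'
#' Peak-size wobble: each size is the phylotype's modal value with
#' probability `1 - 0.3 * wobble_scale`, otherwise uniform over the rest of
#' the stated integer range, so the printed mode remains the most likely
#' value while the full observed range is exercised. `wobble_scale = 0`
#' collapses every size to its mode. Linked-wobble phylotypes draw a single
#' major and place each minor at the fixed interval from it, so all peaks of
#' an isolate shift together.
#'
#' Phenotype scores: the phylotype's modal score with probability 0.7, else
#' one adjacent score (equal split, clipped to 0-3). Adjacent tie-set modes
#' ("a-b") first pick one of the two uniformly.
#'
#' @param panel data.frame from [load_phylotype_panel()].
#' @param mode `"census"` emits exactly the per-phylotype pilot/main counts;
#'   `"resample"` draws `n` isolates with probability proportional to
#'   counts.
#' @param n number of isolates for `mode = "resample"`; ignored for census.
#' @param wobble_scale non-negative scalar scaling the non-modal size mass.
#' @param seed integer seed; the draw is fully reproducible.
#' @return data.frame of isolate records: `isolate_id`, `study`
#'   (pilot/main), `phylotype`, `major_bp`, `minors_bp` (semicolon-joined),
#'   `acid`, `h2o2`, `gram`, `is_mixture`, `trace_failed`,
#'   `sequencing_excluded`.
#' @export
#' @examples
#' panel <- load_phylotype_panel()
#' rec <- sample_isolates(panel, "census", wobble_scale = 0, seed = 1)
#' nrow(rec)
sample_isolates <- function(panel, mode = c("census", "resample"), n = NULL,
                            wobble_scale = 1, seed = 1) {
  mode <- match.arg(mode)
  if (nrow(panel) == 0L) stopf("empty phylotype panel")
  if (wobble_scale < 0) stopf("wobble_scale must be non-negative")
  set.seed(derive_seed(seed, 11L))

  counts <- panel$n_pilot + panel$n_main
  if (mode == "census") {
    idx <- rep(seq_len(nrow(panel)), counts)
    study <- unlist(lapply(seq_len(nrow(panel)), function(i) {
      c(rep("pilot", panel$n_pilot[i]), rep("main", panel$n_main[i]))
    }))
  } else {
    if (is.null(n) || is.na(n) || n < 0) {
      stopf("resample mode needs a non-negative n")
    }
    n <- as.integer(n)
    if (n == 0L) return(empty_records())
    idx <- sample(seq_len(nrow(panel)), n, replace = TRUE,
                  prob = counts / sum(counts))
    study <- vapply(idx, function(i) {
      sample(c("pilot", "main"), 1L,
             prob = c(panel$n_pilot[i], panel$n_main[i]) + 1e-9)
    }, character(1))
  }

  n_rec <- length(idx)
  major <- integer(n_rec)
  minors <- character(n_rec)
  acid <- integer(n_rec)
  h2o2 <- integer(n_rec)
  failed <- logical(n_rec)
  for (k in seq_len(n_rec)) {
    p <- panel[idx[k], ]
    if (is.na(p$major_mode)) {
      # phylotype with no stated ISR sizes: its traces cannot be generated
      major[k] <- NA_integer_
      minors[k] <- ""
      failed[k] <- TRUE
    } else {
      pk <- draw_peaks(p, wobble_scale)
      major[k] <- pk$major
      minors[k] <- join_sizes(list(pk$minors))
    }
    acid[k] <- draw_score(p$acid_mode)
    h2o2[k] <- draw_score(p$h2o2_mode)
  }

  data.frame(
    isolate_id = sprintf("iso%04d", seq_len(n_rec)),
    study = study,
    phylotype = panel$name[idx],
    major_bp = major,
    minors_bp = minors,
    acid = acid,
    h2o2 = h2o2,
    gram = panel$gram[idx],
    is_mixture = FALSE,
    trace_failed = failed,
    sequencing_excluded = FALSE,
    stringsAsFactors = FALSE
  )
}

empty_records <- function() {
  data.frame(isolate_id = character(0), study = character(0),
             phylotype = character(0), major_bp = integer(0),
             minors_bp = character(0), acid = integer(0), h2o2 = integer(0),
             gram = character(0), is_mixture = logical(0),
             trace_failed = logical(0), sequencing_excluded = logical(0),
             stringsAsFactors = FALSE)
}

draw_size <- function(mode, lo, hi, wobble_scale) {
  if (wobble_scale <= 0 || lo >= hi) return(mode)
  p_off <- min(1, 0.3 * wobble_scale)
  offs <- setdiff(seq.int(lo, hi), mode)
  if (length(offs) == 0L || stats::runif(1) >= p_off) return(mode)
  offs[sample.int(length(offs), 1L)]
}

draw_peaks <- function(p, wobble_scale) {
  major <- draw_size(p$major_mode, p$major_lo, p$major_hi, wobble_scale)
  mm <- p$minor_modes[[1]]
  if (length(mm) == 0L) return(list(major = major, minors = integer(0)))
  if (isTRUE(p$linked_wobble) && !is.na(p$link_interval_bp)) {
    # all peaks shift together, preserving the stated interval
    minors <- major - p$link_interval_bp
  } else {
    lo <- p$minor_lo[[1]]; hi <- p$minor_hi[[1]]
    minors <- vapply(seq_along(mm), function(j) {
      as.integer(draw_size(mm[j], lo[j], hi[j], wobble_scale))
    }, integer(1))
  }
  list(major = as.integer(major), minors = sort(as.integer(minors)))
}

draw_score <- function(mode_str) {
  m <- parse_score_mode(mode_str)
  centre <- if (length(m) > 1L) m[sample.int(length(m), 1L)] else m
  if (stats::runif(1) < 0.7) return(as.integer(centre))
  step <- if (stats::runif(1) < 0.5) -1L else 1L
  as.integer(min(3L, max(0L, centre + step)))
}

#' Inject trace failures and strain mixtures
#'
#' Marks `n_failures` records as failed electropherograms and turns
#' `n_mixtures` records into "enrichments": the record keeps its own major
#' peak while the full peak set of one other record with a different
#' phylotype is unioned into its minors, mirroring nominally single isolates
#' that actually contain more than one strain.
#'
#' @param records data.frame from [sample_isolates()].
#' @param n_failures,n_mixtures counts of records to alter.
#' @param seed integer seed for the (reproducible) selection.
#' @return the records with `trace_failed` / `is_mixture` set.
#' @export
inject_artifacts <- function(records, n_failures, n_mixtures, seed = 1) {
  if (n_failures == 0L && n_mixtures == 0L) return(records)
  if (n_failures + n_mixtures > nrow(records)) {
    stopf("n_failures + n_mixtures (%d) exceeds the dataset size (%d)",
          n_failures + n_mixtures, nrow(records))
  }
  set.seed(derive_seed(seed, 23L))
  eligible <- which(!records$trace_failed)
  if (length(eligible) < n_failures + n_mixtures) {
    stopf("not enough intact records to alter")
  }
  pick <- sample(eligible, n_failures + n_mixtures)
  fail_idx <- pick[seq_len(n_failures)]
  mix_idx <- pick[n_failures + seq_len(n_mixtures)]
  records$trace_failed[fail_idx] <- TRUE
  for (i in mix_idx) {
    partners <- which(!records$trace_failed &
                        records$phylotype != records$phylotype[i])
    partners <- setdiff(partners, i)
    if (length(partners) == 0L) next
    j <- partners[sample.int(length(partners), 1L)]
    extra <- c(records$major_bp[j], split_sizes(records$minors_bp[j])[[1]])
    minors <- sort(unique(c(split_sizes(records$minors_bp[i])[[1]], extra)))
    minors <- setdiff(minors, records$major_bp[i])
    records$minors_bp[i] <- join_sizes(list(minors))
    records$is_mixture[i] <- TRUE
  }
  records
}

#' Append isolates from fingerprint groups that will never be sequenced
#'
#' Emulates isolates belonging to ISR groups with no sequenced
#' representative: a small set of synthetic fingerprints distinct from every
#' panel signature (majors placed in the 600-720 bp window the panel does
#' not occupy), flagged `sequencing_excluded` so representative selection
#' skips their groups.
#'
#' @param records existing records (ids are extended past them).
#' @param n number of isolates to append.
#' @param seed integer seed.
#' @return records with `n` extra rows.
#' @export
append_unassigned_isolates <- function(records, n = 22, seed = 1) {
  if (n == 0L) return(records)
  set.seed(derive_seed(seed, 37L))
  sig_major <- seq(605L, by = 20L, length.out = 8L)
  sizes <- rep(c(5L, 4L, 3L, 2L, 2L, 2L, 2L, 2L), length.out = 8L)
  take <- integer(0)
  g <- 1L
  while (sum(take) < n) {
    take <- c(take, min(sizes[(g - 1L) %% 8L + 1L], n - sum(take)))
    g <- g + 1L
  }
  rows <- do.call(rbind, lapply(seq_along(take), function(k) {
    data.frame(
      isolate_id = NA_character_, study = "main",
      phylotype = sprintf("unassigned %s", LETTERS[k]),
      major_bp = sig_major[k],
      minors_bp = as.character(sig_major[k] + 110L),
      acid = 1L, h2o2 = 0L, gram = "unknown",
      is_mixture = FALSE, trace_failed = FALSE,
      sequencing_excluded = TRUE, stringsAsFactors = FALSE
    )[rep(1L, take[k]), ]
  }))
  rows$isolate_id <- sprintf("iso%04d", nrow(records) + seq_len(nrow(rows)))
  rownames(rows) <- NULL
  rbind(records, rows)
}

#' Write / read isolate records as TSV
#'
#' @param records isolate records data.frame.
#' @param path file path.
#' @return `read_isolates()` returns the records data.frame.
#' @export
write_isolates <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_isolates
#' @export
read_isolates <- function(path) {
  rec <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  rec$major_bp <- suppressWarnings(as.integer(rec$major_bp))
  rec$acid <- as.integer(rec$acid)
  rec$h2o2 <- as.integer(rec$h2o2)
  rec$is_mixture <- as.logical(rec$is_mixture)
  rec$trace_failed <- as.logical(rec$trace_failed)
  rec$sequencing_excluded <- as.logical(rec$sequencing_excluded)
  rec$minors_bp[is.na(rec$minors_bp)] <- ""
  rec
}
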
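# shared fixtures: profiles are built in code, never stored

make_profile <- function(id, major, minors = integer(0), quality = "ok") {
  data.frame(isolate_id = id, quality = quality,
             major_bp = as.integer(major),
             minors_bp = paste(minors, collapse = ";"),
             stringsAsFactors = FALSE)
}

make_profiles <- function(majors, minors = NULL, ids = NULL) {
  n <- length(majors)
  if (is.null(ids)) ids <- sprintf("iso%04d", seq_len(n))
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_profile(ids[i], majors[i],
                 if (is.null(minors)) integer(0) else minors[[i]])
  }))
}

# independent brute-force peak caller used as the oracle for detect_peaks:
# scans every index for the local-maximum condition, then removes peaks in
# height order when a taller kept peak sits within min_separation
oracle_peaks <- function(y, min_height, min_separation) {
  apex <- integer(0)
  for (i in seq_along(y)) {
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (i == length(y)) -Inf else y[i + 1L]
    if (y[i] >= min_height && y[i] >= left && y[i] > right) {
      apex <- c(apex, i)
    }
  }
  keep <- integer(0)
  for (i in apex[order(-y[apex], apex)]) {
    if (all(abs(keep - i) >= min_separation)) keep <- c(keep, i)
  }
  sort(keep)
}

# records realizing a given set of joint-category counts
records_from_counts <- function(dn, ao, ho, dp, ds, study = "main") {
  stopifnot(ds <= dp)
  pairs <- rbind(
    matrix(rep(c(0L, 0L), dn), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 0L), ao), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 2L), ho), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 1L), dp - ds), ncol = 2, byrow = TRUE),
    matrix(rep(c(3L, 3L), ds), ncol = 2, byrow = TRUE))
  n <- nrow(pairs)
  data.frame(isolate_id = sprintf("iso%04d", seq_len(n)),
             study = rep(study, n), phylotype = rep("x", n),
             major_bp = rep(300L, n), minors_bp = rep("", n),
             acid = pairs[, 1], h2o2 = pairs[, 2], gram = rep("gpr", n),
             is_mixture = rep(FALSE, n), trace_failed = rep(FALSE, n),
             sequencing_excluded = rep(FALSE, n), stringsAsFactors = FALSE)
}

# one synthetic single-fragment record for round-trip checks
fragment_record <- function(size, id = "frag") {
  data.frame(isolate_id = id, study = "main", phylotype = "synthetic",
             major_bp = as.integer(size), minors_bp = "", acid = 1L,
             h2o2 = 1L, gram = "unknown", is_mixture = FALSE,
             trace_failed = FALSE, sequencing_excluded = FALSE,
             stringsAsFactors = FALSE)
}
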
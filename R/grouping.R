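#' Fingerprint matching policy
#'
#' Tolerances for deciding that two isolates share an ISR fingerprint.
#' Observed per-phylotype ranges motivate defaults of +/-1 bp on the major
#' and +/-2 bp on minors. `interval_mode` additionally accepts pairs whose
#' whole peak pattern is superimposed by one common shift of at most
#' `max_shift` bp — the linked dual-peak wobble seen in Gardnerella-like
#' organisms, whose peaks move together while maintaining a fixed interval.
#' `minor_subset` is a lenient mode in which the smaller minor set need only
#' embed in the larger; by default the minor sets must correspond
#' one-to-one.
#'
#' @param tol_major,tol_minor non-negative tolerances in bp.
#' @param interval_mode logical; enable shift-invariant matching.
#' @param max_shift largest common shift considered (bp).
#' @param minor_subset logical; lenient minor matching.
#' @return an `isr_match_policy` list.
#' @export
match_policy <- function(tol_major = 1, tol_minor = 2, interval_mode = TRUE,
                         max_shift = 4, minor_subset = FALSE) {
  if (tol_major < 0 || tol_minor < 0 || max_shift < 0) {
    stopf("tolerances must be non-negative")
  }
  structure(list(tol_major = tol_major, tol_minor = tol_minor,
                 interval_mode = isTRUE(interval_mode),
                 max_shift = max_shift,
                 minor_subset = isTRUE(minor_subset)),
            class = "isr_match_policy")
}

# one-to-one correspondence of two sorted minor sets within tol
minors_align <- function(m1, m2, tol, subset = FALSE) {
  if (subset) {
    if (length(m1) > length(m2)) { tmp <- m1; m1 <- m2; m2 <- tmp }
    j <- 1L
    for (v in m1) {
      while (j <= length(m2) && m2[j] < v - tol) j <- j + 1L
      if (j > length(m2) || abs(m2[j] - v) > tol) return(FALSE)
      j <- j + 1L
    }
    return(TRUE)
  }
  if (length(m1) != length(m2)) return(FALSE)
  if (length(m1) == 0L) return(TRUE)
  all(abs(m1 - m2) <= tol)
}

#' Do two fingerprints match under a policy?
#'
#' @param p,q one-row profile data.frames (or lists with `major_bp`,
#'   `minors_bp`, `quality`). Failed profiles never match.
#' @param policy an [match_policy()].
#' @return logical scalar.
#' @export
match_profiles <- function(p, q, policy = match_policy()) {
  if (!identical(p$quality, "ok") || !identical(q$quality, "ok")) {
    return(FALSE)
  }
  mp <- as.integer(p$major_bp); mq <- as.integer(q$major_bp)
  n1 <- if (is.character(p$minors_bp)) split_sizes(p$minors_bp)[[1]] else
    as.integer(p$minors_bp)
  n2 <- if (is.character(q$minors_bp)) split_sizes(q$minors_bp)[[1]] else
    as.integer(q$minors_bp)
  match_peaks(mp, n1, mq, n2, policy)
}

match_peaks <- function(mp, n1, mq, n2, policy) {
  if (abs(mp - mq) <= policy$tol_major &&
      minors_align(n1, n2, policy$tol_minor, policy$minor_subset)) {
    return(TRUE)
  }
  if (policy$interval_mode) {
    # the one shift that superimposes the majors must also superimpose
    # every minor: peak intervals are preserved under linked wobble
    s <- mq - mp
    if (abs(s) <= policy$max_shift &&
        minors_align(n1 + s, n2, policy$tol_minor, policy$minor_subset)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Partition fingerprints into groups
#'
#' Single-linkage closure of [match_profiles()]: two isolates share a group
#' iff they are connected by a chain of pairwise matches. Profiles are
#' processed in ascending isolate_id order, so the partition and the group
#' labels are invariant to input permutation. Failed profiles are excluded
#' and reported separately; singletons are flagged unique.
#'
#' @param profiles profile data.frame (one row per isolate, deduplicated).
#' @param policy an [match_policy()].
#' @return an `isr_grouping`: list with `groups` (group_id, n, is_unique,
#'   consensus and observed ranges), `membership` (isolate_id, group_id)
#'   and `failed_ids`.
#' @export
group_profiles <- function(profiles, policy = match_policy()) {
  if (anyDuplicated(profiles$isolate_id)) {
    stopf("profiles must be deduplicated by isolate_id")
  }
  profiles <- profiles[order(profiles$isolate_id), , drop = FALSE]
  failed_ids <- profiles$isolate_id[profiles$quality != "ok"]
  ok <- profiles[profiles$quality == "ok", , drop = FALSE]
  n <- nrow(ok)
  if (n == 0L) {
    return(structure(list(groups = empty_groups(),
                          membership = data.frame(isolate_id = character(0),
                                                  group_id = character(0)),
                          failed_ids = failed_ids),
                     class = "isr_grouping"))
  }
  majors <- as.integer(ok$major_bp)
  minors <- split_sizes(ok$minors_bp)
  window <- policy$tol_major + if (policy$interval_mode) policy$max_shift else 0L

  ord <- order(majors)
  from <- integer(0); to <- integer(0)
  for (a in seq_len(max(0L, n - 1L))) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n && majors[ord[b]] - majors[i] <= window) {
      j <- ord[b]
      if (match_peaks(majors[i], minors[[i]], majors[j], minors[[j]],
                      policy)) {
        from <- c(from, i); to <- c(to, j)
      }
      b <- b + 1L
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from) > 0L) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  # canonical group ids: ordered by first (smallest) member isolate_id
  first_member <- tapply(seq_len(n), comp, min)
  rank <- match(comp, names(sort(first_member)))
  gid <- sprintf("G%03d", rank)

  membership <- data.frame(isolate_id = ok$isolate_id, group_id = gid,
                           stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(sort(unique(gid)), function(id) {
    members <- which(gid == id)
    cons <- consensus_profile(ok[members, , drop = FALSE])
    data.frame(group_id = id, n = length(members),
               is_unique = length(members) == 1L,
               consensus_major = cons$major,
               major_lo = cons$major_range[1], major_hi = cons$major_range[2],
               consensus_minors = join_sizes(list(cons$minors)),
               minors_lo = join_sizes(list(cons$minors_range$lo)),
               minors_hi = join_sizes(list(cons$minors_range$hi)),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(groups = groups, membership = membership,
                 failed_ids = failed_ids),
            class = "isr_grouping")
}

empty_groups <- function() {
  data.frame(group_id = character(0), n = integer(0), is_unique = logical(0),
              consensus_major = integer(0), major_lo = integer(0),
              major_hi = integer(0), consensus_minors = character(0),
              minors_lo = character(0), minors_hi = character(0),
              stringsAsFactors = FALSE)
}

#' Consensus fingerprint of a set of profiles
#'
#' Per-position modal sizes (ties toward the smaller size) plus observed
#' ranges. Minor positions are taken over the members carrying the modal
#' minor cardinality.
#'
#' @param profiles profile data.frame of the group members (quality ok).
#' @return list with `major`, `major_range`, `minors`, `minors_range`.
#' @export
consensus_profile <- function(profiles) {
  stopifnot(nrow(profiles) >= 1L)
  majors <- as.integer(profiles$major_bp)
  minors <- split_sizes(profiles$minors_bp)
  card <- vapply(minors, length, integer(1))
  modal_card <- as.integer(mode_min(card))
  use <- minors[card == modal_card]
  cons_minors <- integer(0); lo <- integer(0); hi <- integer(0)
  if (modal_card > 0L) {
    for (pos in seq_len(modal_card)) {
      v <- vapply(use, `[`, integer(1), pos)
      cons_minors <- c(cons_minors, as.integer(mode_min(v)))
      lo <- c(lo, min(v)); hi <- c(hi, max(v))
    }
  }
  list(major = as.integer(mode_min(majors)),
       major_range = c(min(majors), max(majors)),
       minors = cons_minors,
       minors_range = list(lo = lo, hi = hi))
}

#' @export
print.isr_grouping <- function(x, ...) {
  cat(sprintf("ISR grouping: %d groups over %d isolates (%d unique profiles, %d failed)\n",
              nrow(x$groups), nrow(x$membership),
              sum(x$groups$is_unique), length(x$failed_ids)))
  invisible(x)
}

#' Write grouping results as TSVs
#' @param grouping an `isr_grouping`.
#' @param groups_path,membership_path output files.
#' @export
write_grouping <- function(grouping, groups_path, membership_path) {
  utils::write.table(grouping$groups, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(grouping$membership, membership_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(grouping)
}
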
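#' Categorize acid / H2O2 phenotype scores
#'
#' Both chromogenic assays are scored 0-3 (no colour to strongest colour).
#' Joint categories: double_negative (0/0), acid_only (a>0, h=0), h2o2_only
#' (a=0, h>0), double_positive (a>0, h>0). An isolate is double-strong —
#' the probiotic-candidate criterion — iff its (acid, h2o2) pair is one of
#' {2/3, 3/2, 3/3}.
#'
#' @param acid,h2o2 integer vectors of scores in 0..3.
#' @return data.frame with `category` (character) and `double_strong`
#'   (logical), one row per input pair.
#' @export
#' @examples
#' categorize_phenotype(c(0, 3, 2), c(0, 3, 2))
categorize_phenotype <- function(acid, h2o2) {
  acid <- as.integer(acid); h2o2 <- as.integer(h2o2)
  if (length(acid) != length(h2o2)) stopf("score vectors differ in length")
  bad <- is.na(acid) | is.na(h2o2) | acid < 0L | acid > 3L |
    h2o2 < 0L | h2o2 > 3L
  if (any(bad)) stopf("phenotype scores must be integers in 0..3")
  category <- ifelse(acid == 0L & h2o2 == 0L, "double_negative",
              ifelse(acid > 0L & h2o2 == 0L, "acid_only",
              ifelse(acid == 0L & h2o2 > 0L, "h2o2_only",
                     "double_positive")))
  double_strong <- (acid == 2L & h2o2 == 3L) | (acid == 3L & h2o2 == 2L) |
    (acid == 3L & h2o2 == 3L)
  data.frame(category = category, double_strong = double_strong,
             stringsAsFactors = FALSE)
}

#' Phenotype summary table
#'
#' Counts and percentages (rounded half away from zero, integer percent)
#' for each acid score, each H2O2 score, the four joint categories, the
#' double-strong subset and each Gram morphotype, in the layout of a study
#' summary table. Category counts within each block sum to the number of
#' records.
#'
#' @param records isolate records with `acid`, `h2o2`, `gram`, `study`.
#' @param study `"all"`, `"pilot"` or `"main"`.
#' @return data.frame with `block`, `level`, `n`, `pct`.
#' @export
tabulate_phenotypes <- function(records, study = c("all", "pilot", "main")) {
  study <- match.arg(study)
  if (study != "all") {
    records <- records[records$study == study, , drop = FALSE]
  }
  n_total <- nrow(records)
  pct <- function(n) {
    if (n_total == 0L) return(rep(0, length(n)))
    round_half_away(100 * n / n_total)
  }
  count_levels <- function(x, levels) {
    vapply(levels, function(l) sum(x == l), integer(1))
  }
  score_levels <- as.character(0:3)
  joint <- if (n_total > 0L) {
    categorize_phenotype(records$acid, records$h2o2)
  } else {
    data.frame(category = character(0), double_strong = logical(0))
  }
  joint_levels <- c("double_negative", "acid_only", "h2o2_only",
                    "double_positive")
  gram_levels <- c("gpr", "gpc", "gvcb", "gnr", "pleiomorphic_mixed",
                   "unknown")
  blocks <- list(
    data.frame(block = "acid", level = score_levels,
               n = count_levels(as.character(records$acid), score_levels)),
    data.frame(block = "h2o2", level = score_levels,
               n = count_levels(as.character(records$h2o2), score_levels)),
    data.frame(block = "joint", level = joint_levels,
               n = count_levels(joint$category, joint_levels)),
    data.frame(block = "joint", level = "double_strong",
               n = sum(joint$double_strong)),
    data.frame(block = "gram", level = gram_levels,
               n = count_levels(records$gram, gram_levels))
  )
  out <- do.call(rbind, blocks)
  out$pct <- pct(out$n)
  rownames(out) <- NULL
  out
}

# modal score rendered as "a" or, for adjacent ties, "a-b"; wider ties as
# the full comma-joined set
score_mode_str <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return("")
  tab <- table(x)
  winners <- sort(as.integer(names(tab)[tab == max(tab)]))
  if (length(winners) == 1L) return(as.character(winners))
  if (length(winners) == 2L && diff(winners) == 1L) {
    return(paste(winners, collapse = "-"))
  }
  paste(winners, collapse = ",")
}

#' Per-phylotype summary of counts, fingerprints and phenotypes
#'
#' One row per assigned label: isolate counts by study arm, modal major and
#' minor amplicon sizes with observed ranges, modal acid and H2O2 scores
#' (adjacent ties rendered "a-b") and the number of double-strong isolates.
#'
#' @param records isolate records.
#' @param identifications per-isolate identifications (labels).
#' @param profiles fingerprint profiles.
#' @return data.frame, one row per label, sorted by label.
#' @export
summarize_by_phylotype <- function(records, identifications, profiles) {
  ids <- identifications[identifications$label != "unidentified", ,
                         drop = FALSE]
  labels <- sort(unique(ids$label))
  out <- lapply(labels, function(lab) {
    members <- ids$isolate_id[ids$label == lab]
    rec <- records[records$isolate_id %in% members, , drop = FALSE]
    pr <- profiles[profiles$isolate_id %in% members &
                     profiles$quality == "ok", , drop = FALSE]
    if (nrow(pr) > 0L) {
      cons <- consensus_profile(pr)
      major <- cons$major
      major_rng <- paste(cons$major_range, collapse = "-")
      if (cons$major_range[1] == cons$major_range[2]) major_rng <- ""
      minors <- join_sizes(list(cons$minors))
      minors_rng <- if (length(cons$minors) > 0L &&
                        any(cons$minors_range$hi > cons$minors_range$lo)) {
        paste(paste(cons$minors_range$lo, cons$minors_range$hi, sep = "-"),
              collapse = ";")
      } else ""
    } else {
      major <- NA_integer_; major_rng <- ""; minors <- ""; minors_rng <- ""
    }
    joint <- categorize_phenotype(rec$acid, rec$h2o2)
    data.frame(label = lab,
               n_isolates = nrow(rec),
               n_pilot = sum(rec$study == "pilot"),
               n_main = sum(rec$study == "main"),
               major_mode = major, major_range = major_rng,
               minor_modes = minors, minor_ranges = minors_rng,
               acid_mode = score_mode_str(rec$acid),
               h2o2_mode = score_mode_str(rec$h2o2),
               double_strong_n = sum(joint$double_strong),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count detected taxa
#'
#' From one entry per distinct label: the number of previously described
#' species (named binomials), the number of distinct genera (excluding
#' "unassigned"), and the number of novel groups — labels whose percent
#' identity to the reference database falls below the 97% novelty
#' threshold.
#'
#' @param labels data.frame with one row per distinct label and columns
#'   `name`, `named_species`, `genus`, `percent_identity` (the phylotype
#'   panel qualifies, via its `percent_identity_mode` column).
#' @return list with `n_named_species`, `n_genera`, `n_novel_groups`.
#' @export
#' @examples
#' count_taxa(load_phylotype_panel())
count_taxa <- function(labels) {
  if (nrow(labels) == 0L) {
    return(list(n_named_species = 0L, n_genera = 0L, n_novel_groups = 0L))
  }
  if (!"percent_identity" %in% names(labels) &&
      "percent_identity_mode" %in% names(labels)) {
    labels$percent_identity <- labels$percent_identity_mode
  }
  if (anyDuplicated(labels$name)) stopf("one entry per distinct label required")
  list(
    n_named_species = length(unique(labels$name[labels$named_species])),
    n_genera = length(unique(labels$genus[labels$genus != "unassigned"])),
    n_novel_groups = length(unique(labels$name[labels$percent_identity < 97]))
  )
}
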
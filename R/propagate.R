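#' Select isolates for sequencing
#'
#' Union of (a) every double-strong isolate (acid/H2O2 scores in
#' {2/3, 3/2, 3/3}) and (b) the first `budget_per_group` members of every
#' fingerprint group — singletons included — in ascending isolate_id order.
#' Groups listed in `exclude_groups`, and groups whose members are all
#' flagged `sequencing_excluded`, contribute no representatives (these model
#' fingerprint groups that were never sequenced); individually flagged
#' records are likewise skipped. The selection is deterministic.
#'
#' @param grouping an `isr_grouping` from [group_profiles()].
#' @param records isolate records (for phenotype scores and flags).
#' @param budget_per_group representatives per group, >= 1.
#' @param exclude_groups optional character vector of group_ids.
#' @return character vector of selected isolate_ids, sorted.
#' @export
select_representatives <- function(grouping, records, budget_per_group = 1,
                                   exclude_groups = NULL) {
  if (budget_per_group < 1) stopf("budget_per_group must be >= 1")
  mem <- grouping$membership
  flagged <- records$isolate_id[records$sequencing_excluded %in% TRUE]
  auto_excluded <- vapply(split(mem$isolate_id, mem$group_id),
                          function(ids) all(ids %in% flagged), logical(1))
  excl <- union(exclude_groups, names(auto_excluded)[auto_excluded])
  reps <- unlist(lapply(split(mem$isolate_id, mem$group_id), function(ids) {
    utils::head(sort(ids), budget_per_group)
  }), use.names = FALSE)
  reps <- setdiff(reps, mem$isolate_id[mem$group_id %in% excl])
  cat_df <- categorize_phenotype(records$acid, records$h2o2)
  ds <- records$isolate_id[cat_df$double_strong]
  sort(setdiff(union(reps, ds), flagged))
}

#' Reveal reference-database identities of sequenced representatives
#'
#' Simulates identification of the sequenced subset against a reference
#' database: each intact representative receives its generator-truth
#' phylotype label and a percent identity drawn from 97-100 for previously
#' described species and 85-96 for novel groups (phylotypes absent from the
#' panel are treated as novel). Representatives with failed traces come
#' back unidentified.
#'
#' @param representatives character vector of isolate_ids.
#' @param records isolate records (generator truth).
#' @param panel phylotype panel (named-species status).
#' @param seed integer seed for the identity draws.
#' @return identifications data.frame: `isolate_id`, `label`, `method`,
#'   `percent_identity`, `discordant`, `reason`.
#' @export
reveal_labels <- function(representatives, records,
                          panel = load_phylotype_panel(), seed = 1) {
  unknown <- setdiff(representatives, records$isolate_id)
  if (length(unknown) > 0L) {
    stopf("unknown representative id(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  }
  set.seed(derive_seed(seed, 67L))
  if (length(representatives) == 0L) {
    return(data.frame(isolate_id = character(0), label = character(0),
                      method = character(0), percent_identity = numeric(0),
                      discordant = logical(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  representatives <- sort(representatives)
  rec <- records[match(representatives, records$isolate_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(rec)), function(i) {
    if (rec$trace_failed[i]) {
      return(data.frame(isolate_id = rec$isolate_id[i],
                        label = "unidentified", method = "unidentified",
                        percent_identity = NA_real_, discordant = FALSE,
                        reason = "failed", stringsAsFactors = FALSE))
    }
    row <- match(rec$phylotype[i], panel$name)
    named <- !is.na(row) && isTRUE(panel$named_species[row])
    pid <- if (named) stats::runif(1, 97, 100) else stats::runif(1, 85, 96)
    data.frame(isolate_id = rec$isolate_id[i], label = rec$phylotype[i],
               method = "sequenced",
               percent_identity = round(pid, 1), discordant = FALSE,
               reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag fingerprint groups with discordant sequenced labels
#'
#' A group whose sequenced members carry two or more distinct labels
#' indicates more than one strain behind one fingerprint (or a chained
#' group). Groups with no sequenced member are not assessable and are not
#' flagged.
#'
#' @param grouping an `isr_grouping`.
#' @param sequenced identifications of the sequenced subset.
#' @return character vector of flagged group_ids.
#' @export
detect_discordance <- function(grouping, sequenced) {
  seqd <- sequenced[sequenced$method == "sequenced", , drop = FALSE]
  mem <- grouping$membership
  lab <- seqd$label[match(mem$isolate_id, seqd$isolate_id)]
  by_group <- split(lab, mem$group_id)
  flagged <- vapply(by_group, function(l) {
    length(unique(l[!is.na(l)])) >= 2L
  }, logical(1))
  names(flagged)[flagged]
}

#' Propagate labels from sequenced representatives to group mates
#'
#' Every unsequenced member of a group containing at least one sequenced
#' member receives the group's majority sequenced label
#' (method = propagated). A label tie is resolved conservatively to
#' unidentified. Members of groups with no sequenced representative, and
#' isolates with failed profiles, are unidentified. All members of
#' discordant groups carry `discordant = TRUE`.
#'
#' @param grouping an `isr_grouping`.
#' @param sequenced identifications from [reveal_labels()].
#' @return identifications data.frame covering every isolate in the
#'   grouping (ok and failed), one row each; `reason` distinguishes
#'   `failed`, `no_rep` and `tie` among the unidentified.
#' @export
propagate_labels <- function(grouping, sequenced) {
  flagged <- detect_discordance(grouping, sequenced)
  seqd <- sequenced[sequenced$method == "sequenced", , drop = FALSE]
  mem <- grouping$membership
  rows <- lapply(seq_len(nrow(mem)), function(i) {
    id <- mem$isolate_id[i]; gid <- mem$group_id[i]
    disc <- gid %in% flagged
    hit <- match(id, seqd$isolate_id)
    if (!is.na(hit)) {
      r <- seqd[hit, , drop = FALSE]
      r$discordant <- disc
      return(r)
    }
    labs <- seqd$label[seqd$isolate_id %in%
                         mem$isolate_id[mem$group_id == gid]]
    if (length(labs) == 0L) {
      return(data.frame(isolate_id = id, label = "unidentified",
                        method = "unidentified",
                        percent_identity = NA_real_, discordant = disc,
                        reason = "no_rep", stringsAsFactors = FALSE))
    }
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) {
      return(data.frame(isolate_id = id, label = "unidentified",
                        method = "unidentified",
                        percent_identity = NA_real_, discordant = TRUE,
                        reason = "tie", stringsAsFactors = FALSE))
    }
    data.frame(isolate_id = id, label = winners, method = "propagated",
               percent_identity = NA_real_, discordant = disc,
               reason = "", stringsAsFactors = FALSE)
  })
  # failed representatives keep their unidentified row; other failed
  # profiles are added here
  failed_extra <- setdiff(grouping$failed_ids, sequenced$isolate_id)
  failed_rows <- sequenced[sequenced$method == "unidentified", , drop = FALSE]
  if (length(failed_extra) > 0L) {
    failed_rows <- rbind(failed_rows, data.frame(
      isolate_id = failed_extra, label = "unidentified",
      method = "unidentified", percent_identity = NA_real_,
      discordant = FALSE, reason = "failed", stringsAsFactors = FALSE))
  }
  out <- rbind(do.call(rbind, rows), failed_rows)
  out <- out[order(out$isolate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identification-coverage statistics
#'
#' Counts isolates by identification method and reports the printed-style
#' percentages: sequenced and identified (sequenced + propagated) as
#' integer percent, isolates in groups without sequenced representatives to
#' one decimal, all rounded half away from zero. Unidentified isolates
#' split into three classes: failed electropherograms, members of groups
#' with no sequenced representative (`n_no_rep`), and members of groups
#' whose sequenced labels tied (`n_tie`); methods plus classes always
#' partition the total.
#'
#' @param identifications data.frame with one row per isolate.
#' @return list with `n_total`, `n_sequenced`, `n_propagated`, `n_failed`,
#'   `n_no_rep`, `n_tie`, `pct_sequenced`, `pct_identified`, `pct_no_rep`.
#' @export
#' @examples
#' ids <- data.frame(
#'   method = rep(c("sequenced", "propagated", "unidentified",
#'                  "unidentified"), c(149, 593, 22, 4)),
#'   reason = rep(c("", "", "no_rep", "failed"), c(149, 593, 22, 4)))
#' coverage_stats(ids)
coverage_stats <- function(identifications) {
  if (nrow(identifications) == 0L) stopf("no identifications supplied")
  n_total <- nrow(identifications)
  n_seq <- sum(identifications$method == "sequenced")
  n_prop <- sum(identifications$method == "propagated")
  unid <- identifications$method == "unidentified"
  n_failed <- sum(unid & identifications$reason == "failed")
  n_tie <- sum(unid & identifications$reason == "tie")
  n_no_rep <- sum(unid & !identifications$reason %in% c("failed", "tie"))
  stopifnot(n_seq + n_prop + n_failed + n_no_rep + n_tie == n_total)
  list(n_total = n_total, n_sequenced = n_seq, n_propagated = n_prop,
       n_failed = n_failed, n_no_rep = n_no_rep, n_tie = n_tie,
       pct_sequenced = round_half_away(100 * n_seq / n_total),
       pct_identified = round_half_away(100 * (n_seq + n_prop) / n_total),
       pct_no_rep = round_half_away(100 * n_no_rep / n_total, 1))
}
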
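# a small hand-built collection: two 3-member groups and one singleton
small_records <- function() {
  data.frame(
    isolate_id = sprintf("iso%04d", 1:7),
    study = "main",
    phylotype = c("L. salivarius", "L. salivarius", "L. salivarius",
                  "S. bovis", "S. bovis", "S. bovis", "Pe. harei"),
    major_bp = c(293L, 293L, 293L, 361L, 361L, 361L, 470L),
    minors_bp = c("509", "509", "509", "", "", "", ""),
    acid = c(3L, 3L, 2L, 2L, 2L, 2L, 1L),
    h2o2 = c(3L, 1L, 1L, 2L, 2L, 2L, 1L),
    gram = "gpc", is_mixture = FALSE, trace_failed = FALSE,
    sequencing_excluded = FALSE, stringsAsFactors = FALSE)
}

test_that("representative selection covers every group and all double-strongs", {
  rec <- small_records()
  g <- group_profiles(profiles_from_records(rec), match_policy())
  reps <- select_representatives(g, rec, budget_per_group = 1)
  # first member of each group by id, plus nothing else double-strong here
  # beyond iso0001 (3/3), which is also the first member of its group
  expect_setequal(reps, c("iso0001", "iso0004", "iso0007"))
  # a double-strong that is not a group's first member is still selected
  rec$acid[3] <- 3L; rec$h2o2[3] <- 2L
  reps2 <- select_representatives(g, rec, 1)
  expect_true("iso0003" %in% reps2)
  # deterministic
  expect_identical(reps2, select_representatives(g, rec, 1))
  expect_error(select_representatives(g, rec, 0), ">= 1")
})

test_that("revealed labels carry truth and class-appropriate percent identity", {
  panel <- load_phylotype_panel()
  rec <- sample_isolates(panel, "census", wobble_scale = 0, seed = 30)
  named_id <- rec$isolate_id[rec$phylotype == "L. crispatus"][1]
  novel_id <- rec$isolate_id[rec$phylotype == "L. sp. N6"][1]
  failed_id <- rec$isolate_id[rec$trace_failed][1]
  ids <- reveal_labels(c(named_id, novel_id, failed_id), rec, panel,
                       seed = 1)
  named <- ids[ids$isolate_id == named_id, ]
  novel <- ids[ids$isolate_id == novel_id, ]
  failed <- ids[ids$isolate_id == failed_id, ]
  expect_equal(named$label, "L. crispatus")
  expect_gte(named$percent_identity, 97)
  expect_lt(novel$percent_identity, 97)
  expect_equal(failed$method, "unidentified")
  expect_equal(failed$reason, "failed")
  expect_error(reveal_labels("nope", rec, panel), "unknown")
})

test_that("labels propagate to unsequenced group mates by majority", {
  rec <- small_records()
  g <- group_profiles(profiles_from_records(rec), match_policy())
  seqd <- reveal_labels(c("iso0001", "iso0004"), rec,
                        load_phylotype_panel(), seed = 2)
  ids <- propagate_labels(g, seqd)
  expect_equal(nrow(ids), 7L)
  expect_equal(ids$label[ids$isolate_id %in% c("iso0002", "iso0003")],
               rep("L. salivarius", 2))
  expect_equal(ids$method[ids$isolate_id == "iso0002"], "propagated")
  # the unsequenced singleton's group has no representative
  pe <- ids[ids$isolate_id == "iso0007", ]
  expect_equal(pe$method, "unidentified")
  expect_equal(pe$reason, "no_rep")
  # methods partition the isolates
  expect_equal(sum(ids$method == "sequenced") +
                 sum(ids$method == "propagated") +
                 sum(ids$method == "unidentified"), 7L)
})

test_that("everyone sequenced means nothing propagated", {
  rec <- small_records()
  g <- group_profiles(profiles_from_records(rec), match_policy())
  seqd <- reveal_labels(rec$isolate_id, rec, load_phylotype_panel(), 3)
  ids <- propagate_labels(g, seqd)
  expect_equal(sum(ids$method == "propagated"), 0L)
})

test_that("discordant groups are flagged and ties fall back to unidentified", {
  rec <- small_records()
  g <- group_profiles(profiles_from_records(rec), match_policy())
  seqd <- reveal_labels(c("iso0001", "iso0002", "iso0004"), rec,
                        load_phylotype_panel(), seed = 4)
  # concordant sequenced pair: nothing flagged
  expect_length(detect_discordance(g, seqd), 0L)
  # force a conflicting label in the salivarius group (a strain mixture)
  seqd$label[seqd$isolate_id == "iso0002"] <- "S. epidermidis"
  flagged <- detect_discordance(g, seqd)
  expect_length(flagged, 1L)
  ids <- propagate_labels(g, seqd)
  sal <- ids[ids$isolate_id %in% sprintf("iso%04d", 1:3), ]
  expect_true(all(sal$discordant))
  # 1-1 label tie: the unsequenced member becomes unidentified
  expect_equal(ids$method[ids$isolate_id == "iso0003"], "unidentified")
  expect_equal(ids$reason[ids$isolate_id == "iso0003"], "tie")
})

test_that("coverage percentages reproduce the printed study arithmetic", {
  ids <- data.frame(
    isolate_id = sprintf("iso%04d", 1:768),
    method = rep(c("sequenced", "propagated", "unidentified",
                   "unidentified"), c(149, 593, 22, 4)),
    reason = rep(c("", "", "no_rep", "failed"), c(149, 593, 22, 4)),
    stringsAsFactors = FALSE)
  cov <- coverage_stats(ids)
  expect_equal(cov$pct_identified, 97)
  expect_equal(cov$pct_sequenced, 19)
  expect_equal(cov$pct_no_rep, 2.9)
  expect_equal(cov$n_sequenced + cov$n_propagated + cov$n_failed +
                 cov$n_no_rep + cov$n_tie, cov$n_total)
  # invariant to relabeling and reordering
  ids2 <- ids[rev(seq_len(nrow(ids))), ]
  ids2$isolate_id <- sprintf("x%04d", seq_len(nrow(ids2)))
  expect_equal(coverage_stats(ids2)[-1], cov[-1])
  # degenerate corners
  all_seq <- data.frame(method = rep("sequenced", 5), reason = "")
  expect_equal(coverage_stats(all_seq)$pct_identified, 100)
  none <- data.frame(method = rep("unidentified", 5), reason = "no_rep")
  expect_equal(coverage_stats(none)$pct_identified, 0)
  expect_error(coverage_stats(all_seq[0, , drop = FALSE]), "no identifications")
})
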
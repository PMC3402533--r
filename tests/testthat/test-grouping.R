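test_that("fingerprint matching follows the tolerance policy", {
  pol <- match_policy(1, 2, interval_mode = FALSE)
  p <- make_profile("a", 293, 546)
  expect_true(match_profiles(p, make_profile("b", 293, 546), pol))
  expect_true(match_profiles(p, make_profile("b", 294, 547), pol))
  # a minor 37 bp away distinguishes otherwise identical majors
  expect_false(match_profiles(p, make_profile("b", 293, 509), pol))
  # differing minor cardinality never matches by default
  expect_false(match_profiles(p, make_profile("b", 293), pol))
  # failed profiles never match
  expect_false(match_profiles(make_profile("a", 293, quality = "failed"),
                              make_profile("b", 293), pol))
})

test_that("interval mode accepts linked dual-peak wobble", {
  pol <- match_policy(1, 2, interval_mode = TRUE, max_shift = 4)
  p <- make_profile("a", 455, 440)
  expect_true(match_profiles(p, make_profile("b", 458, 443), pol))
  expect_false(match_profiles(p, make_profile("b", 465, 450), pol))
  nopol <- match_policy(1, 2, interval_mode = FALSE)
  expect_false(match_profiles(p, make_profile("b", 458, 443), nopol))
})

test_that("matching is symmetric", {
  set.seed(17)
  for (k in 1:30) {
    p <- make_profile("a", sample(280:300, 1),
                      sort(sample(400:500, sample(0:2, 1))))
    q <- make_profile("b", sample(280:300, 1),
                      sort(sample(400:500, sample(0:2, 1))))
    pol <- match_policy(sample(0:2, 1), sample(0:3, 1),
                        interval_mode = sample(c(TRUE, FALSE), 1))
    expect_equal(match_profiles(p, q, pol), match_profiles(q, p, pol))
  }
})

test_that("identical profiles collapse to one group; lone profiles are unique", {
  pr <- make_profiles(rep(293, 5), rep(list(546), 5))
  g <- group_profiles(pr, match_policy())
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$n, 5L)
  expect_false(g$groups$is_unique)
  pr2 <- rbind(pr, make_profile("iso9999", 700))
  g2 <- group_profiles(pr2, match_policy())
  expect_equal(nrow(g2$groups), 2L)
  expect_true(g2$groups$is_unique[g2$groups$consensus_major == 700])
})

test_that("grouping returns a partition of the ok profiles", {
  panel <- load_phylotype_panel()
  rec <- sample_isolates(panel, "census", wobble_scale = 1, seed = 19)
  pr <- profiles_from_records(rec)
  g <- group_profiles(pr, match_policy())
  ok_ids <- pr$isolate_id[pr$quality == "ok"]
  expect_setequal(g$membership$isolate_id, ok_ids)
  expect_false(anyDuplicated(g$membership$isolate_id) > 0L)
  expect_equal(sum(g$groups$n), length(ok_ids))
  expect_setequal(g$failed_ids, pr$isolate_id[pr$quality != "ok"])
})

test_that("zero-wobble, zero-tolerance groups equal the true signature partition", {
  panel <- load_phylotype_panel()
  rec <- sample_isolates(panel, "census", wobble_scale = 0, seed = 20)
  pr <- profiles_from_records(rec)
  g <- group_profiles(pr, match_policy(0, 0, interval_mode = FALSE))
  ok <- !rec$trace_failed
  sig <- paste(rec$major_bp, rec$minors_bp)[ok]
  expect_equal(nrow(g$groups), length(unique(sig)))
  # every group is pure in true phylotype
  truth <- rec$phylotype[match(g$membership$isolate_id, rec$isolate_id)]
  purity <- tapply(truth, g$membership$group_id,
                   function(x) length(unique(x)))
  expect_true(all(purity == 1L))
})

test_that("grouping is invariant to input permutation", {
  set.seed(21)
  pr <- make_profiles(sample(rep(c(290, 293, 360, 455), each = 6)))
  g1 <- group_profiles(pr, match_policy())
  g2 <- group_profiles(pr[sample(nrow(pr)), ], match_policy())
  expect_identical(g1$membership, g2$membership)
  expect_identical(g1$groups, g2$groups)
})

test_that("enlarging tolerances never increases the group count", {
  panel <- load_phylotype_panel()
  rec <- sample_isolates(panel, "census", wobble_scale = 1, seed = 22)
  pr <- profiles_from_records(rec)
  counts <- vapply(0:3, function(tol) {
    nrow(group_profiles(pr, match_policy(tol, tol + 1,
                                         interval_mode = FALSE))$groups)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("consensus takes per-position modes with ties toward smaller sizes", {
  pr <- make_profiles(c(293, 293, 294), list(546, 546, 547))
  cons <- consensus_profile(pr)
  expect_equal(cons$major, 293L)
  expect_equal(cons$major_range, c(293L, 294L))
  expect_equal(cons$minors, 546L)
  expect_equal(cons$minors_range$hi, 547L)
  # singleton: its own profile back
  single <- consensus_profile(make_profile("a", 311, 413))
  expect_equal(single$major, 311L)
  expect_equal(single$minors, 413L)
  # 1-1 tie breaks to the smaller value
  tie <- consensus_profile(make_profiles(c(455, 466)))
  expect_equal(tie$major, 455L)
})
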
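test_that("agreement filtering partitions exactly at every threshold", {
  agr <- c(15L, 14L, 15L, 9L)
  rows <- t(sapply(agr, function(a) c(rep(1L, a), rep(0L, 15 - a))))
  rownames(rows) <- sprintf("t%d", 1:4)
  v <- vote_matrix(rows)
  f15 <- agreement_filter(v, 15)
  expect_equal(nrow(f15$retained), 2)
  f8 <- agreement_filter(v, 8)
  expect_equal(nrow(f8$retained), 4)
  expect_equal(nrow(f8$discarded), 0)
  expect_error(agreement_filter(v, 7), "threshold")
  expect_error(agreement_filter(v, 16), "threshold")

  # exhaustive partition & monotonicity over all vote patterns, n = 7 and 9
  for (n in c(7L, 9L)) {
    pats <- as.matrix(expand.grid(rep(list(0:1), n)))
    rownames(pats) <- sprintf("p%04d", seq_len(nrow(pats)))
    vm <- vote_matrix(pats)
    prev <- Inf
    for (t in ceiling(n / 2):n) {
      f <- agreement_filter(vm, t)
      expect_equal(nrow(f$retained) + nrow(f$discarded), nrow(pats))
      expect_length(intersect(f$retained$tile_id, f$discarded$tile_id), 0)
      expect_lte(nrow(f$retained), prev)
      prev <- nrow(f$retained)
    }
    expect_equal(nrow(agreement_filter(vm, ceiling(n / 2))$retained), nrow(pats))
  }
})

# independent 2x2-table oracle for one threshold
curve_oracle <- function(votes, truth, t) {
  mv <- majority_vote(votes)
  y <- truth[mv$tile_id]
  keep <- mv$agreement >= t
  lab <- mv$ensemble_label
  list(n = sum(keep),
       acc = if (any(keep)) sum(lab[keep] == y[keep]) / sum(keep) else NA_real_,
       fp = sum(keep & lab == 1 & y == 0),
       fn = sum(keep & lab == 0 & y == 1))
}

test_that("accuracy-by-agreement matches a hand 2x2 computation", {
  # hand-built 6-tile vote set, n = 5 members
  rows <- rbind(
    c(1, 1, 1, 1, 1),  # agr 5, label 1
    c(1, 1, 1, 1, 0),  # agr 4, label 1
    c(1, 1, 1, 0, 0),  # agr 3, label 1
    c(0, 0, 0, 1, 1),  # agr 3, label 0
    c(0, 0, 0, 0, 1),  # agr 4, label 0
    c(0, 0, 0, 0, 0))  # agr 5, label 0
  rownames(rows) <- sprintf("t%d", 1:6)
  truth <- setNames(c(1L, 0L, 1L, 1L, 0L, 1L), rownames(rows))
  v <- vote_matrix(rows)
  curve <- accuracy_by_agreement(v, truth)
  expect_equal(curve$threshold, 3:5)
  for (i in seq_len(nrow(curve))) {
    o <- curve_oracle(v, truth, curve$threshold[i])
    expect_equal(curve$n_retained[i], o$n)
    expect_equal(curve$accuracy[i], o$acc)
    expect_equal(curve$false_positives[i], o$fp)
    expect_equal(curve$false_negatives[i], o$fn)
  }
  # spot-check the hand numbers at t = 5: tiles t1 (correct) and t6 (wrong)
  expect_equal(curve$n_retained[curve$threshold == 5], 2)
  expect_equal(curve$accuracy[curve$threshold == 5], 0.5)
  expect_equal(curve$false_negatives[curve$threshold == 5], 1)

  # random matrices against the oracle
  for (s in 1:5) {
    v2 <- random_votes(30, 7, seed = s)
    y2 <- withr::with_seed(100 + s, setNames(rbinom(30, 1, 0.5), rownames(v2)))
    c2 <- accuracy_by_agreement(v2, y2)
    for (i in seq_len(nrow(c2))) {
      o <- curve_oracle(v2, y2, c2$threshold[i])
      expect_equal(c2$accuracy[i], o$acc)
      expect_equal(c2$n_retained[i], o$n)
    }
    expect_true(all(diff(c2$n_retained) <= 0))
  }
})

test_that("unanimously correct votes give a flat perfect curve", {
  truth <- setNames(rep_len(0:1, 10), sprintf("t%d", 1:10))
  rows <- t(sapply(truth, function(y) rep(y, 5)))
  rownames(rows) <- names(truth)
  curve <- accuracy_by_agreement(vote_matrix(rows), truth)
  expect_true(all(curve$accuracy == 1))
  expect_true(all(curve$n_retained == 10))
  expect_false(any(curve$undefined))
})

test_that("zero retained tiles reports undefined accuracy, not zero", {
  rows <- matrix(c(1, 1, 0, 0, 1), 1, 5, dimnames = list("t1", NULL))  # agr 3
  curve <- accuracy_by_agreement(vote_matrix(rows),
                                 setNames(1L, "t1"))
  at5 <- curve[curve$threshold == 5, ]
  expect_equal(at5$n_retained, 0)
  expect_true(is.na(at5$accuracy))
  expect_true(at5$undefined)
})

test_that("stratified performance partitions the evaluated tiles", {
  co <- meta_cohort(c(A = 4L, B = 4L), 4L)
  v <- random_votes(nrow(co), 5, seed = 3)
  rownames(v) <- co$tile_id
  attr(v, "dimnames")[[1]] <- co$tile_id
  rep_site <- stratified_performance(v, co, by = "site")
  expect_setequal(rep_site$group, c("A", "B"))
  expect_equal(sum(rep_site$n_tiles), nrow(co))

  rep_q <- stratified_performance(v, co, by = "quality")
  expect_equal(sum(rep_q$n_tiles), nrow(co))

  rep_p <- stratified_performance(v, co, by = "patient")
  expect_equal(nrow(rep_p), 8)

  # single-group cohort: one entry equal to overall accuracy
  co1 <- meta_cohort(c(A = 4L), 4L)
  v1 <- random_votes(nrow(co1), 5, seed = 4)
  attr(v1, "dimnames")[[1]] <- co1$tile_id
  r1 <- stratified_performance(v1, co1, by = "site")
  mv <- majority_vote(v1)
  expect_equal(r1$accuracy,
               mean(mv$ensemble_label == co1$class_label[match(mv$tile_id, co1$tile_id)]))

  expect_error(stratified_performance(v1, co1, by = "slide"), "arg")
})

test_that("exclusion lists recompute accuracy on the complement", {
  v <- random_votes(50, 7, seed = 9)
  truth <- withr::with_seed(10, setNames(rbinom(50, 1, 0.5), rownames(v)))
  # empty list: identity
  r0 <- apply_exclusion_list(v, truth, character(0))
  expect_equal(r0$delta$delta, 0)
  expect_equal(r0$delta$n_after, 50)

  # excluding exactly the wrong predictions leaves accuracy 1
  mv <- majority_vote(v)
  wrong <- mv$tile_id[mv$ensemble_label != truth[mv$tile_id]]
  r1 <- apply_exclusion_list(v, truth, wrong)
  expect_equal(r1$delta$accuracy_after, 1)

  # random 20%: delta equals brute-force recomputation on the complement
  drop <- withr::with_seed(11, sample(rownames(v), 10))
  r2 <- apply_exclusion_list(v, truth, drop)
  keep <- setdiff(rownames(v), drop)
  brute <- mean(mv$ensemble_label[match(keep, mv$tile_id)] == truth[keep])
  expect_equal(r2$delta$accuracy_after, brute)
  expect_equal(r2$delta$delta, brute - mean(mv$ensemble_label == truth[mv$tile_id]))

  # unknown ids are counted, not fatal; file input works
  f <- tempfile()
  writeLines(c(drop, "not_a_tile"), f)
  r3 <- apply_exclusion_list(v, truth, f)
  expect_equal(r3$n_unknown, 1)
  expect_equal(r3$delta$accuracy_after, brute)
})

test_that("suspect labels are ranked by contradiction confidence", {
  rows <- rbind(
    t1 = rep(1L, 15),                    # truth 0, agr 15 -> first
    t2 = c(rep(1L, 12), rep(0L, 3)),     # truth 0, agr 12
    t3 = c(rep(1L, 9), rep(0L, 6)),      # truth 0, agr 9
    t4 = rep(1L, 15))                    # truth 1, correct
  truth <- setNames(c(0L, 0L, 0L, 1L), rownames(rows))
  v <- vote_matrix(rows)
  flagged <- flag_suspect_labels(v, truth, review_threshold = 8)
  expect_equal(flagged$tile_id, c("t1", "t2", "t3"))
  expect_equal(flagged$agreement, c(15L, 12L, 9L))

  # review threshold excludes weaker contradictions (filter oracle)
  f12 <- flag_suspect_labels(v, truth, review_threshold = 12)
  expect_equal(f12$tile_id, c("t1", "t2"))

  # full agreement with truth -> empty list
  ok <- flag_suspect_labels(v, setNames(c(1L, 1L, 1L, 1L), rownames(rows)),
                            review_threshold = 8)
  expect_equal(nrow(ok), 0)
})
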
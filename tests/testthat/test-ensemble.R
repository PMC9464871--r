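test_that("checkpointing keeps the earliest best validation epoch", {
  sched <- c(0.6, 0.8, 0.75, 0.8, 0.7, 0.6, 0.6, 0.6, 0.6, 0.6)
  be <- stub_backend(sched)
  cfg <- train_config(n_members = 3, epochs = 10, backend = be, seed = 1)
  tr <- tibble::tibble(tile_id = sprintf("tr%02d", 1:10))
  va <- tibble::tibble(tile_id = sprintf("va%02d", 1:20))
  feats <- matrix(0, 30, 1, dimnames = list(c(tr$tile_id, va$tile_id), NULL))
  m <- train_member(tr, rep_len(0:1, 10), va, rep(1L, 20), cfg,
                    member_seed = 1, features = feats)
  expect_equal(m$best_epoch, 2)
  expect_equal(m$best_val_accuracy, 0.8)
  expect_equal(m$val_history, sched)

  # epochs = 1 returns the epoch-1 checkpoint by definition
  cfg1 <- train_config(3, 1, be, 1)
  m1 <- train_member(tr, rep_len(0:1, 10), va, rep(1L, 20), cfg1, 1, feats)
  expect_equal(m1$best_epoch, 1)

  expect_error(train_member(tr, rep(1L, 10), va, rep(1L, 20), cfg, 1, feats),
               "single-class training set")
})

test_that("linearly separable toy tiles are learned perfectly", {
  # two solid colors: any threshold on the mean channel separates them
  dir <- tempfile(); dir.create(dir)
  mk <- function(val, id) {
    img <- array(val, dim = c(32, 32, 3))
    p <- file.path(dir, paste0(id, ".png"))
    png::writePNG(img, p)
    p
  }
  n <- 40
  tiles <- tibble::tibble(
    tile_id = sprintf("s%02d", 1:n),
    class_label = rep_len(0:1, n))
  tiles$image_path <- mapply(mk, ifelse(tiles$class_label == 1, 0.8, 0.2),
                             tiles$tile_id)
  be <- pooled_mlp_backend()
  feats <- tile_features(tiles, be)
  cfg <- train_config(3, 10, be, seed = 1)
  m <- train_member(tiles[1:30, ], tiles$class_label[1:30],
                    tiles[31:40, ], tiles$class_label[31:40],
                    cfg, member_seed = 2, features = feats)
  expect_equal(m$best_val_accuracy, 1.0)
})

test_that("ensembles train one member per partition and record provenance", {
  co <- rendered_cohort()
  be <- pooled_mlp_backend()
  feats <- tile_features(co, be)
  plan <- make_repeat_splits(co, 1, 0.25, seed = 1)[[1]]
  plan <- make_member_splits(plan, 5, 0.2, seed = 2)
  cfg <- train_config(5, 4, be, seed = 3)

  sel <- select_single_class(co, plan$train_pool, seed = 4)
  np0 <- inject_label_noise(sel, 0, seed = 5)
  np15 <- inject_label_noise(sel, 0.15, seed = 5)
  e0 <- train_ensemble(co, plan, np0, cfg, features = feats)
  e15 <- train_ensemble(co, plan, np15, cfg, features = feats)
  expect_length(e0$members, 5)
  # same splits and selection, labels differ only by the flip set
  expect_identical(e0$plan, e15$plan)
  expect_identical(e0$noise_plan$retained_tiles, e15$noise_plan$retained_tiles)
  expect_length(e0$noise_plan$flipped_tiles, 0)
  expect_gt(length(e15$noise_plan$flipped_tiles), 0)

  expect_error(train_config(4, 10), "odd")
  bad_cfg <- train_config(7, 4, be, 3)
  expect_error(train_ensemble(co, plan, np0, bad_cfg, features = feats),
               "member partitions")
})

test_that("votes, majority labels, and agreement follow the counting rules", {
  # all members at 0.9 -> unanimous 1
  ens_all1 <- structure(list(
    members = replicate(15, list(state = list(epoch = 1L)), simplify = FALSE),
    config = train_config(15, 1, stub_backend(NULL, const_prob = 0.9), 1)),
    class = "ensemble_model")
  tiles <- tibble::tibble(tile_id = c("x1", "x2"))
  feats <- matrix(0, 2, 1, dimnames = list(tiles$tile_id, NULL))
  v <- predict_members(ens_all1, tiles, features = feats)
  mv <- majority_vote(v)
  expect_equal(mv$agreement, c(15L, 15L))
  expect_equal(mv$ensemble_label, c(1L, 1L))

  # probability exactly 0.5 votes 1 (threshold is >=)
  ens_half <- ens_all1
  ens_half$config <- train_config(15, 1, stub_backend(NULL, const_prob = 0.5), 1)
  expect_true(all(unclass(predict_members(ens_half, tiles, features = feats)) == 1L))

  # 8 members at 0.6, 7 at 0.4 -> label 1, agreement 8
  row <- c(rep(1L, 8), rep(0L, 7))
  vm <- vote_matrix(matrix(row, 1, 15, dimnames = list("t1", NULL)))
  mv2 <- majority_vote(vm)
  expect_equal(mv2$votes_for_1, 8L)
  expect_equal(mv2$ensemble_label, 1L)
  expect_equal(mv2$agreement, 8L)

  # eight 0s, seven 1s -> label 0, agreement 8
  vm3 <- vote_matrix(matrix(c(rep(0L, 8), rep(1L, 7)), 1, 15,
                            dimnames = list("t1", NULL)))
  expect_equal(majority_vote(vm3)$ensemble_label, 0L)
  expect_equal(majority_vote(vm3)$agreement, 8L)

  expect_error(majority_vote(random_votes(3, 4)), "odd")
})

test_that("majority vote equals the brute-force tally on every 2^7 pattern", {
  pats <- as.matrix(expand.grid(rep(list(0:1), 7)))
  rownames(pats) <- sprintf("p%03d", seq_len(nrow(pats)))
  mv <- majority_vote(vote_matrix(pats))
  for (i in seq_len(nrow(pats))) {
    n1 <- sum(pats[i, ] == 1); n0 <- sum(pats[i, ] == 0)
    expect_equal(mv$votes_for_1[i], n1)
    expect_equal(mv$ensemble_label[i], as.integer(n1 > n0))
    expect_equal(mv$agreement[i], max(n0, n1))
    expect_gte(mv$agreement[i], 4)
  }
})

test_that("group accuracy is the unweighted mean of member accuracies", {
  v <- random_votes(5, 3, seed = 42)
  truth <- withr::with_seed(43, setNames(rbinom(5, 1, 0.5), rownames(v)))
  manual <- mean(sapply(1:3, function(j) mean(unclass(v)[, j] == truth)))
  expect_equal(group_accuracy(v, truth), manual)
  # members identical to truth -> 1
  vm <- vote_matrix(matrix(rep(truth, 3), 5, 3,
                           dimnames = list(names(truth), NULL)))
  expect_equal(group_accuracy(vm, truth), 1)
})

test_that("fitted ensembles persist to disk and reload with equal votes", {
  co <- rendered_cohort()
  be <- pooled_mlp_backend(hidden = 8)
  feats <- tile_features(co, be)
  plan <- make_repeat_splits(co, 1, 0.25, seed = 7)[[1]]
  plan <- make_member_splits(plan, 3, 0.2, seed = 8)
  cfg <- train_config(3, 3, be, seed = 9)
  ens <- train_ensemble(co, plan, NULL, cfg, features = feats)
  d <- tempfile()
  save_ensemble(ens, d)
  back <- load_ensemble(d)
  test_tiles <- tiles_of(co, plan$test_patients)
  expect_identical(unclass(predict_members(back, test_tiles, features = feats)),
                   unclass(predict_members(ens, test_tiles, features = feats)))

  f <- tempfile(fileext = ".csv")
  v <- predict_members(ens, test_tiles, features = feats)
  write_vote_matrix(v, f)
  expect_identical(unclass(read_vote_matrix(f)), unclass(v))
})
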
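test_that("trial selection keeps correct trials and labels target vs rest", {
  cfg <- sim_config(incorrect_rate = 0)
  tr <- simulate_trial_table(cfg, 1)
  sel <- select_trials(tr, "spatial")
  expect_equal(sum(sel$label == 1), 80)
  expect_equal(sum(sel$label == -1), 160)

  # mixed correctness: exact count
  tr2 <- tr
  tr2$correct[seq(1, 240, by = 3)] <- FALSE
  sel2 <- select_trials(tr2, "pair")
  expect_equal(nrow(sel2), sum(tr2$correct))

  tr3 <- tr
  tr3$correct <- FALSE
  expect_error(select_trials(tr3, "pair"), "correct")

  tr4 <- tr[tr$condition == "pair", ]
  expect_error(select_trials(tr4, "pair"), "empty")
})

test_that("down-sampling balances classes deterministically", {
  labels <- c(rep(1, 80), rep(-1, 160))
  idx <- downsample_balance(labels, seed = 4)
  expect_equal(unname(table(labels[idx])), c(80L, 80L), ignore_attr = TRUE)
  expect_identical(idx, downsample_balance(labels, seed = 4))
  expect_false(identical(idx, downsample_balance(labels, seed = 5)))

  # already balanced: unchanged
  bal <- rep(c(1, -1), each = 10)
  expect_identical(downsample_balance(bal, 1), 1:20)

  # degenerate but legal
  idx2 <- downsample_balance(c(1, rep(-1, 100)), 1)
  expect_length(idx2, 2)
})

test_that("the stratified split gives 64/64 train and 16/16 test at defaults", {
  labels <- rep(c(1, -1), each = 80)
  sp <- split_train_test(labels, 0.8, seed = 2)
  expect_equal(sum(labels[sp$train] == 1), 64)
  expect_equal(sum(labels[sp$train] == -1), 64)
  expect_equal(sum(labels[sp$test] == 1), 16)
  expect_equal(sum(labels[sp$test] == -1), 16)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(labels, 0.8, seed = 2))
  # a fraction leaving an empty partition errors
  expect_error(split_train_test(rep(c(1, -1), each = 2), 0.9, 1), "empty")
})

test_that("C tuning follows run folds, breaks ties to the smallest C", {
  sub <- separable_subject()
  sel <- select_trials(sub$trials, "pair")
  X <- t(unclass(sub$patterns)[, sel$index])
  y <- sel$label
  runs <- sub$trials$run_id[sel$index]
  spec <- classifier_spec("pair")

  tuned <- tune_c(X, y, runs, spec)
  expect_true(tuned$chosen_c %in% spec$c_grid)
  # run-aligned folds: as many folds as training runs
  expect_equal(sort(unique(tuned$cv$fold)), 1:5)
  # strongly separable data: some C reaches perfect CV accuracy
  agg <- tapply(tuned$cv$accuracy, tuned$cv$C, mean)
  expect_equal(max(agg), 1)

  # all-equal CV accuracies tie-break to the smallest C: with one grid
  # value there is nothing to search; with separable data the first C
  # attaining the max is returned
  first_max <- as.numeric(names(agg))[which.max(agg)]
  expect_equal(tuned$chosen_c, first_max)
  one <- tune_c(X, y, runs, classifier_spec("pair", c_grid = 0.123))
  expect_equal(one$chosen_c, 0.123)
})

test_that("fold grouping handles run counts different from n_folds", {
  expect_equal(sort(unique(mvpaproj:::make_run_folds(rep(1:7, each = 3), 5))), 1:5)
  expect_equal(sort(unique(mvpaproj:::make_run_folds(rep(1:3, each = 5), 5))), 1:3)
})

test_that("classify_subject is deterministic and near-perfect on separable data", {
  sub <- separable_subject()
  spec <- classifier_spec("pair", seed = 9)
  r1 <- classify_subject(sub$trials, sub$patterns, spec)
  r2 <- classify_subject(sub$trials, sub$patterns, spec)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$chosen_c, r2$chosen_c)
  expect_gt(r1$accuracy, 0.9)
  expect_equal(r1$n_train_per_class, 16)
  expect_equal(r1$n_test_per_class, 4)
})

test_that("shuffling test labels after training centres accuracy at chance", {
  sub <- separable_subject()
  sel <- select_trials(sub$trials, "pair")
  X <- t(unclass(sub$patterns)[, sel$index])
  accs <- sapply(1:50, function(s) {
    y <- mvpaproj:::with_seed(s, sample(sel$label))
    mvpaproj:::pipeline_accuracy(X, y, sub$trials$run_id[sel$index],
                                 classifier_spec("pair"), seed = s,
                                 fixed_c = 0.01)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("accuracy responds monotonically to the pattern effect size", {
  acc_at <- function(pe) {
    cfg <- sim_config(n_subjects = 12, n_voxels = 20, trials_per_condition = 40,
                      pattern_effect = pe, incorrect_rate = 0, seed = 60)
    study <- simulate_study(cfg)
    mean(sapply(1:12, function(i)
      classify_subject(study$trials[[i]], study$patterns[[i]],
                       classifier_spec("pair"), seed = i)$accuracy))
  }
  accs <- sapply(c(0, 1.2, 4), acc_at)
  expect_true(all(diff(accs) > 0))
})
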
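test_that("trial tables have the designed counts, run structure and onsets", {
  cfg <- sim_config(seed = 3)
  tr <- simulate_trial_table(cfg, 42)

  expect_equal(nrow(tr), 240)
  expect_equal(unname(table(tr$condition)), rep(80L, 3), ignore_attr = TRUE)
  expect_setequal(unique(tr$run_id), 1:5)
  # every run holds every condition, 16 of each under the default design
  counts <- table(tr$run_id, tr$condition)
  expect_true(all(counts == 16))
  expect_true(all(tr$response_time_ms > 200))
  # onsets strictly increasing within run, inter-trial gap >= 4 s trial + 0.5 s jitter
  for (r in 1:5) {
    on <- tr$onset_s[tr$run_id == r]
    expect_true(all(diff(on) >= 4.5))
  }
})

test_that("a minimal one-run design yields one trial per condition", {
  cfg <- sim_config(trials_per_condition = 1, n_runs = 1)
  tr <- simulate_trial_table(cfg, 1)
  expect_equal(nrow(tr), 3)
  expect_setequal(as.character(tr$condition), c("spatial", "temporal", "pair"))
})

test_that("simulated RT means match the configured condition means", {
  # large-sample Monte-Carlo check against the configured truncated normals
  cfg <- sim_config(trials_per_condition = 10000, n_runs = 1)
  tr <- simulate_trial_table(cfg, 7)
  m <- tapply(tr$response_time_ms, tr$condition, mean)
  expect_lt(abs(m[["spatial"]] - 1284) / 1284, 0.01)
  expect_lt(abs(m[["temporal"]] - 1384) / 1384, 0.01)
  expect_lt(abs(m[["pair"]] - 1183) / 1183, 0.01)
  # behavioral ordering: temporal slowest, pair fastest
  expect_gt(m[["temporal"]], m[["spatial"]])
  expect_gt(m[["spatial"]], m[["pair"]])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(trials_per_condition = 0), "integer")
  expect_error(sim_config(rt_mean_ms = c(150, 1300, 1200)), "truncation")
  expect_error(sim_config(rt_sd_ms = 0), "rt_sd_ms")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("generation is deterministic given config and seed", {
  cfg <- tiny_config()
  expect_identical(simulate_trial_table(cfg, 9), simulate_trial_table(cfg, 9))
  tr <- simulate_trial_table(cfg, 9)
  expect_identical(simulate_patterns(tr, cfg, 9), simulate_patterns(tr, cfg, 9))
  expect_false(identical(simulate_trial_table(cfg, 9)$response_time_ms,
                         simulate_trial_table(cfg, 10)$response_time_ms))
})

test_that("null noiseless patterns reduce to the per-voxel baseline", {
  cfg <- tiny_config(noise_sd = 0, baseline_sd = 0)
  tr <- simulate_trial_table(cfg, 2)
  D <- simulate_patterns(tr, cfg, 2)
  expect_true(all(abs(D - cfg$baseline_mean) < 1e-12))
})

test_that("pattern effects shift centroids but not spatial means", {
  cfg <- sim_config(n_subjects = 1, n_voxels = 30, trials_per_condition = 400,
                    n_runs = 1, pattern_effect = 1, noise_sd = 0.3,
                    incorrect_rate = 0)
  tr <- simulate_trial_table(cfg, 11)
  D <- simulate_patterns(tr, cfg, 11)
  cents <- sapply(levels(tr$condition), function(cn)
    rowMeans(D[, tr$condition == cn]))
  # spatial (column) means equal across conditions in expectation
  col_means <- colMeans(cents)
  expect_lt(max(col_means) - min(col_means), 0.05)
  # centroid patterns themselves differ clearly between conditions
  expect_gt(sqrt(sum((cents[, 1] - cents[, 2])^2)), 0.5)
  expect_gt(sqrt(sum((cents[, 1] - cents[, 3])^2)), 0.5)
})

test_that("RT coupling makes the spatial mean track RT as noise vanishes", {
  cfg <- sim_config(n_subjects = 1, n_voxels = 20, trials_per_condition = 60,
                    n_runs = 1, rt_coupling = 0.01, noise_sd = 0.01,
                    incorrect_rate = 0)
  tr <- simulate_trial_table(cfg, 4)
  D <- simulate_patterns(tr, cfg, 4)
  expect_gt(cor(colMeans(D), tr$response_time_ms), 0.99)
})

test_that("null data have no systematic condition structure", {
  # centroid separation shrinks with trial count (no injected structure)
  sep <- sapply(c(30, 300), function(tpc) {
    cfg <- sim_config(n_voxels = 15, trials_per_condition = tpc, n_runs = 1,
                      incorrect_rate = 0, seed = 2)
    mean(sapply(1:30, function(s) {
      tr <- simulate_trial_table(cfg, s)
      D <- simulate_patterns(tr, cfg, s)
      cents <- sapply(levels(tr$condition), function(cn)
        rowMeans(D[, tr$condition == cn]))
      sqrt(sum((cents[, 1] - cents[, 3])^2))
    }))
  })
  # expected scaling ~ 1/sqrt(trials): a 10x trial increase should shrink
  # separation by about sqrt(10)
  expect_lt(sep[2], sep[1] / 2)
})

test_that("simulate_study returns aligned per-subject tables and matrices", {
  study <- simulate_study(tiny_config())
  expect_equal(nrow(study), 2)
  expect_true(all(vapply(seq_len(2), function(i)
    ncol(study$patterns[[i]]) == nrow(study$trials[[i]]), logical(1))))
  # reproducible from the same config
  study2 <- simulate_study(tiny_config())
  expect_identical(study$patterns[[2]], study2$patterns[[2]])
})
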
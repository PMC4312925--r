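test_that("mean projection zeroes columns lying along the mean pattern", {
  m <- c(3, 1, -2, 0.5)
  D <- m %*% t(c(1, 2, 0.5, -1, 4))  # every column a multiple of m
  Dc <- mean_correct(D)
  expect_true(all(abs(Dc) < 1e-10))
})

test_that("a zero mean pattern leaves the matrix unchanged with a warning", {
  D <- matrix(c(1, -1, -1, 1, 0, 0), 2, 3)  # each voxel's mean exactly 0
  expect_warning(Dc <- mean_correct(D), "zero")
  expect_equal(unclass(Dc)[, ], D, ignore_attr = TRUE)
})

test_that("mean projection is orthogonal, idempotent and norm non-increasing", {
  set.seed(10)
  D <- matrix(rnorm(50 * 120, mean = 5), 50, 120)
  Dc <- mean_correct(D)
  mh <- rowMeans(D) / sqrt(sum(rowMeans(D)^2))
  align <- abs(crossprod(mh, Dc)) / sqrt(colSums(unclass(Dc)[, ]^2))
  expect_lt(max(align), 1e-8)
  expect_lt(attr(Dc, "diagnostics"), 1e-8)
  # idempotency: projection leaves exactly zero voxel means, so the second
  # application takes the degenerate identity branch
  Dcc <- suppressWarnings(mean_correct(unclass(Dc)[, , drop = FALSE]))
  expect_equal(unclass(Dcc)[, ], unclass(Dc)[, ], tolerance = 1e-8)
  expect_lte(norm(unclass(Dc)[, ], "F"), norm(D, "F"))
})

test_that("RT residualization matches per-voxel regression residuals", {
  set.seed(11)
  cfg <- sim_config(n_voxels = 15, trials_per_condition = 30, n_runs = 2,
                    rt_coupling = 0.005, noise_sd = 0.5, incorrect_rate = 0)
  tr <- simulate_trial_table(cfg, 8)
  D <- simulate_patterns(tr, cfg, 8)
  Dc <- rt_correct(D, tr)
  oracle <- rt_residual_oracle(unclass(D)[, ], tr$response_time_ms)
  expect_equal(unclass(Dc)[, ], oracle, tolerance = 1e-8, ignore_attr = TRUE)
  # no voxel covaries with RT afterwards; voxel means preserved
  rc <- tr$response_time_ms - mean(tr$response_time_ms)
  expect_lt(max(abs(unclass(Dc)[, ] %*% rc)) / norm(D, "F"), 1e-8)
  expect_equal(rowMeans(unclass(Dc)[, ]), rowMeans(D), tolerance = 1e-10)
  # idempotent
  Dcc <- rt_correct(unclass(Dc)[, , drop = FALSE], tr)
  expect_equal(unclass(Dcc)[, ], unclass(Dc)[, ], tolerance = 1e-8)
})

test_that("pure RT-driven signal is annihilated", {
  set.seed(12)
  rt <- runif(40, 800, 2000)
  rc <- rt - mean(rt)
  w <- rnorm(8)
  D <- w %*% t(rc)
  trials <- tibble::tibble(response_time_ms = rt)
  Dc <- rt_correct(D, trials)
  expect_lt(max(abs(Dc)), 1e-8 * max(abs(D)))
})

test_that("constant RTs leave the matrix unchanged with a warning", {
  D <- matrix(rnorm(20), 4, 5)
  trials <- tibble::tibble(response_time_ms = rep(1200, 5))
  expect_warning(Dc <- rt_correct(D, trials), "zero variance")
  expect_equal(unclass(Dc)[, ], D, ignore_attr = TRUE)
})

test_that("RT residualization is linear in its matrix argument", {
  set.seed(13)
  rt <- runif(30, 800, 2000)
  trials <- tibble::tibble(response_time_ms = rt)
  D1 <- matrix(rnorm(6 * 30), 6, 30)
  D2 <- matrix(rnorm(6 * 30), 6, 30)
  lhs <- rt_correct(2 * D1 - 3 * D2, trials)
  rhs <- 2 * unclass(rt_correct(D1, trials))[, ] -
    3 * unclass(rt_correct(D2, trials))[, ]
  expect_equal(unclass(lhs)[, ], rhs, tolerance = 1e-10)
})

test_that("the literal projection reading retains only the RT component", {
  set.seed(14)
  rt <- runif(25, 800, 2000)
  trials <- tibble::tibble(response_time_ms = rt)
  D <- matrix(rnorm(5 * 25), 5, 25)
  Dl <- rt_correct(D, trials, literal = TRUE)
  # result lies in the rank-1 span of r: residualizing it on raw r gives 0
  P <- rt %*% t(rt) / sum(rt^2)
  expect_equal(unclass(Dl)[, ], D %*% P, tolerance = 1e-10)
  expect_equal(qr(unclass(Dl)[, ])$rank, 1L)
})

test_that("apply_correction dispatches and records the kind", {
  cfg <- tiny_config()
  tr <- simulate_trial_table(cfg, 3)
  D <- simulate_patterns(tr, cfg, 3)
  none <- apply_correction(D, tr, "none")
  expect_equal(unclass(none)[, ], unclass(D)[, ], ignore_attr = TRUE)
  expect_equal(attr(none, "correction"), "none")
  expect_equal(attr(apply_correction(D, tr, "mean_signal"), "correction"),
               "mean_signal")
  expect_equal(attr(apply_correction(D, tr, "response_time"), "correction"),
               "response_time")
  expect_error(apply_correction(D, kind = "response_time"), "trials")
  expect_error(apply_correction(D, tr, "banana"))
})

test_that("each correction selectively removes its own kind of signal", {
  # mean-only simulation: centroids coincide after mean projection
  cfg <- sim_config(n_voxels = 20, trials_per_condition = 150, n_runs = 1,
                    mean_effect = c(spatial = 0, temporal = 0, pair = 1),
                    noise_sd = 0.2, incorrect_rate = 0)
  tr <- simulate_trial_table(cfg, 17)
  D <- simulate_patterns(tr, cfg, 17)
  gap <- function(M) {
    cents <- sapply(levels(tr$condition), function(cn)
      rowMeans(M[, tr$condition == cn]))
    sqrt(sum((cents[, "pair"] - cents[, "spatial"])^2))
  }
  expect_gt(gap(D), 3)
  expect_lt(gap(unclass(mean_correct(D))[, ]), gap(D) / 5)

  # RT-only simulation: per-voxel RT correlation is killed by rt_correct
  cfg2 <- sim_config(n_voxels = 20, trials_per_condition = 100, n_runs = 1,
                     rt_coupling = 0.01, noise_sd = 0.2, incorrect_rate = 0)
  tr2 <- simulate_trial_table(cfg2, 18)
  D2 <- simulate_patterns(tr2, cfg2, 18)
  expect_gt(max(abs(cor(t(unclass(D2)[, ]), tr2$response_time_ms))), 0.5)
  D2c <- rt_correct(D2, tr2)
  expect_lt(max(abs(cor(t(unclass(D2c)[, ]), tr2$response_time_ms))), 1e-6)
})
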
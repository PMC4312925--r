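# Small reusable simulation fixtures, all generated in code.

tiny_config <- function(...) {
  sim_config(n_subjects = 2, n_voxels = 10, trials_per_condition = 10,
             n_runs = 2, incorrect_rate = 0, seed = 1, ...)
}

# a subject with a strongly separable pair-vs-rest pattern
separable_subject <- function(seed = 5, n_voxels = 12, tpc = 20) {
  cfg <- sim_config(n_voxels = n_voxels, trials_per_condition = tpc,
                    n_runs = 5, pattern_effect = 8, noise_sd = 0.5,
                    incorrect_rate = 0, seed = seed)
  trials <- simulate_trial_table(cfg, seed)
  list(config = cfg, trials = trials,
       patterns = simulate_patterns(trials, cfg, seed))
}

# independent per-voxel regression-residual oracle for rt_correct
rt_residual_oracle <- function(D, rt) {
  t(apply(D, 1, function(row) stats::residuals(stats::lm(row ~ rt)) + mean(row)))
}
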
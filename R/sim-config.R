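#' Simulation configuration
#'
#' Bundles the ground-truth parameters of the synthetic retrieval-fMRI
#' generator: design counts, per-condition response-time (RT) distributions,
#' and the three injectable condition signals — a distributed voxel pattern,
#' a uniform mean-amplitude offset, and an RT-coupled global gain.
#'
#' The default design mirrors a three-condition event-related retrieval
#' study: 17 subjects, 80 trials per condition (spatial, temporal, pair)
#' spread over 5 runs, condition mean RTs of 1284, 1384 and 1183 ms. Signal
#' units are arbitrary; `noise_sd` sets the trial-wise i.i.d. Gaussian noise
#' against which effect sizes are read.
#'
#' A configuration with `pattern_effect = 0`, `mean_effect = 0` and
#' `rt_coupling = 0` defines the null scenario: no condition information of
#' any kind is injected.
#'
#' @param n_subjects Number of subjects.
#' @param n_voxels Number of voxels in the simulated region of interest.
#' @param trials_per_condition Trials per condition per subject.
#' @param n_runs Number of scanning runs; trials are distributed across runs
#'   as evenly as possible.
#' @param pattern_effect Magnitude (signal units) of the condition-specific
#'   distributed patterns. Each condition gets a fixed zero-mean, unit-norm
#'   voxel pattern drawn once per subject, so pattern signal contributes
#'   nothing to the spatial mean.
#' @param mean_effect Uniform amplitude offset added to every voxel on trials
#'   of a condition; scalar or length-3 vector named by condition.
#' @param rt_mean_ms,rt_sd_ms Per-condition mean and SD of trial RTs (ms);
#'   RTs are drawn from a normal truncated below at 200 ms.
#' @param rt_coupling Amplitude change per ms of RT deviation from the
#'   session mean, applied as a spatially uniform gain (unit-norm loading).
#' @param noise_sd SD of the i.i.d. Gaussian trial-wise noise.
#' @param baseline_mean,baseline_sd Per-voxel baseline amplitudes are drawn
#'   once per subject from `N(baseline_mean, baseline_sd^2)`.
#' @param incorrect_rate Fraction of trials flagged incorrect/forgotten
#'   (these are excluded from classification downstream).
#' @param seed Base seed; per-subject seeds are derived from it.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_voxels = 20, seed = 1)
#' cfg$trials_per_condition
#' @export
sim_config <- function(n_subjects = 17, n_voxels = 40,
                       trials_per_condition = 80, n_runs = 5,
                       pattern_effect = 0, mean_effect = 0,
                       rt_mean_ms = c(spatial = 1284, temporal = 1384, pair = 1183),
                       rt_sd_ms = 300, rt_coupling = 0,
                       noise_sd = 1, baseline_mean = 100, baseline_sd = 10,
                       incorrect_rate = 0.16, seed = 1) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_voxels = check_count(n_voxels, "n_voxels", min = 2),
    trials_per_condition = check_count(trials_per_condition, "trials_per_condition"),
    n_runs = check_count(n_runs, "n_runs"),
    pattern_effect = as.double(pattern_effect),
    mean_effect = per_condition(mean_effect, "mean_effect"),
    rt_mean_ms = per_condition(rt_mean_ms, "rt_mean_ms"),
    rt_sd_ms = per_condition(rt_sd_ms, "rt_sd_ms"),
    rt_coupling = as.double(rt_coupling),
    noise_sd = as.double(noise_sd),
    baseline_mean = as.double(baseline_mean),
    baseline_sd = as.double(baseline_sd),
    incorrect_rate = as.double(incorrect_rate),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (any(cfg$rt_sd_ms <= 0)) stopf("`rt_sd_ms` must be > 0")
  if (any(cfg$rt_mean_ms <= 200))
    stopf("`rt_mean_ms` must exceed the 200 ms truncation bound")
  if (cfg$incorrect_rate < 0 || cfg$incorrect_rate >= 1)
    stopf("`incorrect_rate` must be in [0, 1)")
  if (cfg$pattern_effect < 0) stopf("`pattern_effect` must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  design: %d subjects, %d voxels, %d trials/condition, %d runs\n",
              x$n_subjects, x$n_voxels, x$trials_per_condition, x$n_runs))
  cat(sprintf("  effects: pattern %.3g, mean [%s], rt_coupling %.3g\n",
              x$pattern_effect, paste(signif(x$mean_effect, 3), collapse = ", "),
              x$rt_coupling))
  cat(sprintf("  noise_sd %.3g, incorrect_rate %.2f, seed %d\n",
              x$noise_sd, x$incorrect_rate, x$seed))
  invisible(x)
}

#' Named scenario configurations
#'
#' Builds the four canonical simulation scenarios used to demonstrate which
#' projection correction abolishes which kind of condition signal:
#'
#' * `null` — no condition signal of any kind; every classifier should sit
#'   at chance.
#' * `pattern_driven` — conditions differ only in distributed, zero-mean
#'   voxel patterns; decoding should survive both corrections.
#' * `mean_driven` — the pair condition carries a uniform amplitude offset;
#'   decoding should be abolished by mean-signal projection but survive RT
#'   residualization.
#' * `rt_driven` — conditions differ only through their RT distributions
#'   combined with a global RT-amplitude gain, so the condition signal is
#'   entirely RT-mediated; decoding should be abolished by RT
#'   residualization.
#'
#' Default effect sizes are set so that raw (uncorrected) decoding is
#' modestly above chance rather than at ceiling, which is the regime in
#' which the corrections and the permutation machinery are informative.
#'
#' @param name One of `"null"`, `"pattern_driven"`, `"mean_driven"`,
#'   `"rt_driven"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @examples
#' scenario_config("mean_driven")$mean_effect
#' @export
scenario_config <- function(name = c("null", "pattern_driven", "mean_driven",
                                     "rt_driven"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    null           = list(),
    pattern_driven = list(pattern_effect = 0.8),
    mean_driven    = list(mean_effect = c(spatial = 0, temporal = 0, pair = 0.16)),
    rt_driven      = list(rt_coupling = 0.01)
  )
  cfg <- do.call(sim_config, utils::modifyList(args, list(...)))
  attr(cfg, "scenario") <- name
  validate_scenario_config(name, cfg)
  cfg
}

# A scenario name promises which effects are present; reject configs that
# contradict it (e.g. a "mean_driven" config with a pattern effect).
validate_scenario_config <- function(name, cfg) {
  has_pattern <- cfg$pattern_effect > 0
  has_mean <- any(cfg$mean_effect != 0)
  has_rt <- cfg$rt_coupling != 0
  ok <- switch(name,
    null           = !has_pattern && !has_mean && !has_rt,
    pattern_driven = has_pattern && !has_mean && !has_rt,
    mean_driven    = has_mean && !has_pattern && !has_rt,
    rt_driven      = has_rt && !has_pattern && !has_mean
  )
  if (!ok)
    stopf("config is inconsistent with scenario '%s' (injected effects: pattern=%s, mean=%s, rt=%s)",
          name, has_pattern, has_mean, has_rt)
  invisible(cfg)
}
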
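#' Simulate a trial table for one subject
#'
#' Generates per-trial metadata for a three-condition event-related
#' retrieval design: condition labels (spatial, temporal, pair) distributed
#' as evenly as possible across runs, response times drawn from per-condition
#' truncated normals (lower bound 200 ms), a correctness flag, and trial
#' onsets with jittered inter-trial fixation.
#'
#' Trial durations are 4 s (1 s cue, 1 s stimulus, 2 s post-stimulus) and
#' the fixation jitter before each trial is drawn from a right-skewed
#' distribution on 0.5–13 s (mean about 4 s), so a default 48-trial run
#' occupies roughly 380 s.
#'
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @return A tibble with columns `trial_id`, `condition` (factor),
#'   `response_time_ms`, `run_id`, `correct`, `onset_s`. Rows are ordered by
#'   run and onset.
#' @examples
#' trials <- simulate_trial_table(sim_config(seed = 1), subject_seed = 11)
#' dplyr::count(trials, condition)
#' @export
simulate_trial_table <- function(config, subject_seed) {
  stopifnot(inherits(config, "sim_config"))
  subject_seed <- check_count(subject_seed, "subject_seed", min = 0)
  tpc <- config$trials_per_condition
  n_runs <- config$n_runs

  with_seed(derive_seed(subject_seed, 101L), {
    # per-condition trial counts per run, remainders rotated across
    # conditions so runs stay balanced overall
    base <- tpc %/% n_runs
    rem <- tpc %% n_runs
    counts <- vapply(seq_along(CONDITIONS), function(k) {
      extra <- integer(n_runs)
      if (rem > 0) extra[(((k - 1) + seq_len(rem) - 1) %% n_runs) + 1] <- 1L
      as.integer(base + extra)
    }, integer(n_runs))
    counts <- matrix(counts, nrow = n_runs)  # n_runs x 3

    rows <- purrr::map_dfr(seq_len(n_runs), function(r) {
      cond <- rep(CONDITIONS, times = counts[r, ])
      tibble::tibble(condition = sample(cond), run_id = r)
    })

    # truncated-normal RTs via inverse CDF, lower bound 200 ms
    mu <- config$rt_mean_ms[as.character(rows$condition)]
    sdv <- config$rt_sd_ms[as.character(rows$condition)]
    lo <- pnorm(200, mu, sdv)
    rows$response_time_ms <- unname(qnorm(lo + runif(nrow(rows)) * (1 - lo), mu, sdv))

    rows$correct <- runif(nrow(rows)) >= config$incorrect_rate

    # onsets: jittered fixation (0.5 + 12.5 * Beta(1, 2.6)) before each 4-s trial
    rows <- rows |>
      dplyr::group_by(.data$run_id) |>
      dplyr::mutate(onset_s = cumsum(0.5 + 12.5 * stats::rbeta(dplyr::n(), 1, 2.6) + 4) - 4) |>
      dplyr::ungroup()

    tibble::tibble(
      trial_id = seq_len(nrow(rows)),
      condition = factor(rows$condition, levels = CONDITIONS),
      response_time_ms = rows$response_time_ms,
      run_id = as.integer(rows$run_id),
      correct = rows$correct,
      onset_s = rows$onset_s
    )
  })
}

#' Simulate a voxel-by-trial response-amplitude matrix
#'
#' Generates the single-subject pattern matrix `D` (rows = voxels,
#' columns = trials) as the sum of a per-voxel baseline, a per-condition
#' uniform mean offset, a per-condition distributed pattern, an RT-coupled
#' spatially uniform gain, and i.i.d. Gaussian noise:
#'
#' \deqn{D_{vt} = b_v + \mu_{c(t)} + \beta_{pat}\, w_{c(t),v}
#'       + \beta_{rt}\,(RT_t - \overline{RT})\, g_v + \varepsilon_{vt}}
#'
#' The condition patterns \eqn{w_c} are zero-mean, unit-norm voxel vectors
#' drawn once per subject (pattern signal contributes nothing to the spatial
#' mean), and the RT loading \eqn{g} is the uniform unit-norm vector (RT
#' effects are a global gain).
#'
#' @param trials Trial table from [simulate_trial_table()].
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject's draws (use the same
#'   value as for the trial table to keep a subject self-consistent).
#' @return A numeric matrix (`n_voxels` x `n_trials`) with voxel ids as row
#'   names. The attribute `"truth"` carries the injected components:
#'   `baseline`, `pattern_vectors` (voxels x 3), `rt_loading`, and `signal`
#'   (the noiseless matrix).
#' @examples
#' cfg <- sim_config(n_voxels = 10, trials_per_condition = 4, n_runs = 2)
#' tr <- simulate_trial_table(cfg, 1)
#' D <- simulate_patterns(tr, cfg, 1)
#' dim(D)
#' @export
simulate_patterns <- function(trials, config, subject_seed) {
  stopifnot(inherits(config, "sim_config"))
  subject_seed <- check_count(subject_seed, "subject_seed", min = 0)
  if (!all(c("condition", "response_time_ms") %in% names(trials)))
    stopf("`trials` must have `condition` and `response_time_ms` columns")
  V <- config$n_voxels
  Tn <- nrow(trials)
  if (Tn < 1) stopf("`trials` is empty")

  with_seed(derive_seed(subject_seed, 202L), {
    b <- rnorm(V, config$baseline_mean, config$baseline_sd)
    W <- vapply(CONDITIONS, function(cn) {
      x <- rnorm(V)
      x <- x - mean(x)
      x / sqrt(sum(x^2))
    }, numeric(V))
    g <- rep(1 / sqrt(V), V)

    cond <- as.character(trials$condition)
    rt_c <- trials$response_time_ms - mean(trials$response_time_ms)

    signal <- matrix(b, V, Tn) +
      matrix(config$mean_effect[cond], V, Tn, byrow = TRUE) +
      config$pattern_effect * W[, cond, drop = FALSE] +
      config$rt_coupling * g %o% rt_c
    D <- signal + matrix(rnorm(V * Tn, 0, config$noise_sd), V, Tn)

    rownames(D) <- sprintf("v%03d", seq_len(V))
    rownames(signal) <- rownames(D)
    attr(D, "truth") <- list(baseline = b, pattern_vectors = W,
                             rt_loading = g, signal = signal)
    D
  })
}

#' Simulate a multi-subject study
#'
#' Runs [simulate_trial_table()] and [simulate_patterns()] for each subject
#' with seeds derived deterministically from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per subject and list-columns `trials` and
#'   `patterns`.
#' @examples
#' study <- simulate_study(sim_config(n_subjects = 2, n_voxels = 10,
#'                                    trials_per_condition = 5))
#' study
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- seq_len(config$n_subjects)
  sims <- purrr::map(subjects, function(s) {
    sseed <- derive_seed(config$seed, s)
    trials <- simulate_trial_table(config, sseed)
    list(trials = trials, patterns = simulate_patterns(trials, config, sseed))
  })
  tibble::tibble(
    subject = subjects,
    trials = purrr::map(sims, "trials"),
    patterns = purrr::map(sims, "patterns")
  )
}
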
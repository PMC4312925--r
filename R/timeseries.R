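#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (peak near 5 s, undershoot near 15 s,
#' undershoot ratio 1/6), scaled to unit peak amplitude.
#'
#' @param t Time in seconds since event onset (vector).
#' @return The response at `t`; zero for `t < 0`.
#' @examples
#' tt <- seq(0, 30, 0.1)
#' tt[which.max(hrf_double_gamma(tt))]  # ~5 s
#' @export
hrf_double_gamma <- function(t) {
  h <- function(x) stats::dgamma(x, shape = 6, rate = 1) -
    stats::dgamma(x, shape = 16, rate = 1) / 6
  peak <- max(h(seq(0, 20, by = 0.01)))
  out <- ifelse(t < 0, 0, h(pmax(t, 0)) / peak)
  out
}

#' Simulate BOLD-like voxel timeseries from trial amplitudes
#'
#' Convolves each trial's amplitude with the canonical double-gamma
#' response at the scan grid and sums within runs; trials never spill
#' across run boundaries. Optional white noise is added per scan.
#'
#' @param trials Trial table with `onset_s` and `run_id`.
#' @param amplitudes Voxel-by-trial matrix of response amplitudes (columns
#'   aligned to `trials` rows).
#' @param tr_s Repetition time in seconds.
#' @param run_duration_s Duration of each run in seconds (scalar or one per
#'   run). Default: long enough for the last trial's response (last onset
#'   + 32 s). Onsets beyond a supplied duration are a configuration error.
#' @param noise_sd SD of additive white scanner noise (default 0).
#' @return An object of class `bold_timeseries`: a list with `values`
#'   (voxels x scans), `scan_run`, `scan_time_s` (time within run), `tr_s`.
#' @examples
#' cfg <- sim_config(n_voxels = 4, trials_per_condition = 2, n_runs = 1)
#' tr <- simulate_trial_table(cfg, 1)
#' D <- simulate_patterns(tr, cfg, 1)
#' ts <- simulate_timeseries(tr, D)
#' dim(ts$values)
#' @export
simulate_timeseries <- function(trials, amplitudes, tr_s = 2.5,
                                run_duration_s = NULL, noise_sd = 0) {
  check_aligned(amplitudes, trials)
  if (is.null(trials$onset_s) || anyNA(trials$onset_s))
    stopf("`trials` must carry trial onsets (`onset_s`)")
  runs <- sort(unique(trials$run_id))
  if (!is.null(run_duration_s)) {
    run_duration_s <- rep(run_duration_s, length.out = length(runs))
  } else {
    run_duration_s <- vapply(runs, function(r)
      max(trials$onset_s[trials$run_id == r]) + 32, numeric(1))
  }
  V <- nrow(amplitudes)

  per_run <- purrr::map(seq_along(runs), function(ri) {
    r <- runs[ri]
    idx <- which(trials$run_id == r)
    dur <- run_duration_s[ri]
    if (any(trials$onset_s[idx] + 4 > dur))
      stopf("run %d: trial onsets exceed the run duration (%.1f s)", r, dur)
    n_scan <- floor(dur / tr_s) + 1
    t_scan <- (seq_len(n_scan) - 1) * tr_s
    # scans x trials-in-run convolution basis
    H <- vapply(idx, function(j) hrf_double_gamma(t_scan - trials$onset_s[j]),
                numeric(n_scan))
    Y <- amplitudes[, idx, drop = FALSE] %*% t(H)
    if (noise_sd > 0) Y <- Y + matrix(rnorm(V * n_scan, 0, noise_sd), V, n_scan)
    list(values = Y, run = rep(r, n_scan), time = t_scan)
  })

  structure(list(
    values = do.call(cbind, purrr::map(per_run, "values")),
    scan_run = unlist(purrr::map(per_run, "run")),
    scan_time_s = unlist(purrr::map(per_run, "time")),
    tr_s = tr_s
  ), class = "bold_timeseries")
}

#' Estimate single-trial response amplitudes by GLM
#'
#' Fits one ordinary-least-squares model per voxel with a separate
#' HRF-convolved regressor for every trial, plus a per-run intercept and a
#' per-run linear drift, and returns the per-trial coefficients as a
#' voxel-by-trial matrix (the beta series).
#'
#' @param timeseries A `bold_timeseries` from [simulate_timeseries()] (or a
#'   compatible list with `values`, `scan_run`, `scan_time_s`).
#' @param trials Trial table with `onset_s` and `run_id` aligned to the
#'   intended output columns.
#' @return Voxel-by-trial matrix of estimated amplitudes.
#' @examples
#' cfg <- sim_config(n_voxels = 4, trials_per_condition = 2, n_runs = 1,
#'                   noise_sd = 0)
#' tr <- simulate_trial_table(cfg, 1)
#' D <- simulate_patterns(tr, cfg, 1)
#' Dhat <- estimate_single_trial_amplitudes(simulate_timeseries(tr, D), tr)
#' max(abs(Dhat - D))  # ~0
#' @export
estimate_single_trial_amplitudes <- function(timeseries, trials) {
  Y <- timeseries$values
  n_scan <- ncol(Y)
  runs <- sort(unique(trials$run_id))
  n_trial <- nrow(trials)

  # trial regressors, confined to their run
  X_tr <- matrix(0, n_scan, n_trial)
  for (j in seq_len(n_trial)) {
    in_run <- timeseries$scan_run == trials$run_id[j]
    X_tr[in_run, j] <- hrf_double_gamma(timeseries$scan_time_s[in_run] -
                                          trials$onset_s[j])
  }
  # per-run intercept + centered linear drift
  X_nuis <- do.call(cbind, purrr::map(runs, function(r) {
    in_run <- as.numeric(timeseries$scan_run == r)
    drift <- in_run * (timeseries$scan_time_s - mean(timeseries$scan_time_s[in_run == 1]))
    cbind(in_run, drift)
  }))
  X <- cbind(X_tr, X_nuis)

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- qrx$pivot[seq.int(qrx$rank + 1, ncol(X))]
    bad <- sort(dropped[dropped <= n_trial])
    stopf("trial-wise design matrix is rank deficient%s",
          if (length(bad)) paste0("; offending trials: ",
                                  paste(bad, collapse = ", ")) else "")
  }
  # all voxels at once: coefficients are p x V
  B <- qr.coef(qrx, t(Y))
  out <- t(B[seq_len(n_trial), , drop = FALSE])
  dimnames(out) <- list(rownames(Y), NULL)
  out
}
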
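#' Group-level t statistic against chance
#'
#' One-sample t of per-subject held-out accuracies versus the binary
#' chance level of 0.5: `t = (mean - 0.5) / (sd / sqrt(n))` with
#' `df = n - 1`.
#'
#' @param accuracies Per-subject accuracy proportions (length >= 2).
#' @param chance Chance level (default 0.5).
#' @return List with `mean`, `sem`, `t`, `df`.
#' @examples
#' group_t(c(0.55, 0.52, 0.61, 0.49))
#' @export
group_t <- function(accuracies, chance = 0.5) {
  n <- length(accuracies)
  if (n < 2) stopf("need at least 2 subjects")
  m <- mean(accuracies)
  s <- sd(accuracies)
  sem <- s / sqrt(n)
  if (s < 1e-15) {
    if (abs(m - chance) < 1e-15) {
      t <- 0
    } else {
      warn("zero variance across subjects; t is infinite")
      t <- sign(m - chance) * Inf
    }
  } else {
    t <- (m - chance) / sem
  }
  list(mean = m, sem = sem, t = t, df = n - 1L)
}

#' Group-level label-permutation test of decoding accuracy
#'
#' Computes the observed group t of per-subject accuracies against chance,
#' then builds a permutation null: in each permutation every subject's
#' condition labels are shuffled uniformly among that subject's correct
#' trials (class counts preserved, labels never cross subjects), the full
#' per-subject pipeline is re-run, and the group t recomputed. The
#' one-sided p-value uses the add-one estimator
#' `p = (1 + #\{t_perm >= t_obs\}) / (1 + n_perm)`.
#'
#' Because both corrections are label-free, the corrected matrix is computed
#' once per subject and reused across permutations. By default each
#' permutation re-uses the `C` tuned on that subject's observed labels (the
#' fast mode); `retune = TRUE` re-tunes `C` inside every permutation.
#'
#' @param study Tibble from [simulate_study()] (or any tibble with `subject`,
#'   `trials`, `patterns` columns).
#' @param spec A [classifier_spec()].
#' @param correction `"none"`, `"mean_signal"` or `"response_time"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed governing all permutation draws.
#' @param retune Re-tune `C` within each permutation (slow) instead of
#'   fixing it at the observed tuned value.
#' @param alpha One-sided significance level (default 0.05).
#' @return An object of class `group_result`: observed `mean_accuracy`,
#'   `sem`, `t_value`, `df`, `accuracies`, `chosen_c`, the permutation
#'   vector `perm_t_values`, `p_value`, and `significant`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_subjects = 4, n_voxels = 10,
#'                                    trials_per_condition = 20))
#' permutation_test(study, classifier_spec("pair"), n_perm = 100, seed = 1)
#' }
#' @export
permutation_test <- function(study, spec = classifier_spec(),
                             correction = c("none", "mean_signal", "response_time"),
                             n_perm = 3000, seed = 1, retune = FALSE,
                             alpha = 0.05) {
  correction <- match.arg(correction)
  n_perm <- check_count(n_perm, "n_perm", min = 100)
  if (nrow(study) < 2) stopf("need at least 2 subjects")
  seed <- check_count(seed, "seed", min = 0)

  # Per-subject fixed quantities: corrected features over correct trials.
  subj <- purrr::map(seq_len(nrow(study)), function(i) {
    trials <- study$trials[[i]]
    D <- study$patterns[[i]]
    check_aligned(D, trials)
    keep <- which(trials$correct)
    if (length(keep) == 0) stopf("subject %d has no correct trials", i)
    tk <- trials[keep, ]
    Dc <- apply_correction(D[, keep, drop = FALSE], tk, kind = correction)
    list(X = t(unclass_matrix(Dc)), cond = as.character(tk$condition),
         run = tk$run_id, seed = derive_seed(seed, i))
  })

  # Observed statistic (with C tuning).
  obs <- purrr::map(subj, function(s) {
    y <- ifelse(s$cond == spec$target_condition, 1, -1)
    if (all(y == 1) || all(y == -1))
      stopf("one class is empty for target '%s'", spec$target_condition)
    pipeline_accuracy(s$X, y, s$run, spec, s$seed)
  })
  accuracies <- purrr::map_dbl(obs, "accuracy")
  chosen_c <- purrr::map_dbl(obs, "chosen_c")
  gt <- group_t(accuracies)

  ys <- purrr::map(subj, function(s)
    ifelse(s$cond == spec$target_condition, 1, -1))
  perm_t <- vapply(seq_len(n_perm), function(b) {
    acc_b <- vapply(seq_along(subj), function(i) {
      s <- subj[[i]]
      pseed <- derive_seed(seed, i, b)
      if (retune) {
        cond_b <- with_seed(pseed, sample(s$cond))
        y <- ifelse(cond_b == spec$target_condition, 1, -1)
        pipeline_accuracy(s$X, y, s$run, spec, pseed)$accuracy
      } else {
        # shuffling the +1/-1 labels is equivalent to shuffling condition
        # labels and relabeling; the compiled path re-runs balance, split,
        # standardization and the SVM fit at the subject's tuned C
        pipeline_accuracy_cpp(s$X, ys[[i]], chosen_c[i], spec$train_fraction,
                              pseed, spec$standardize, TRUE)
      }
    }, numeric(1))
    group_t(acc_b)$t
  }, numeric(1))

  p <- (1 + sum(perm_t >= gt$t)) / (1 + n_perm)
  structure(list(
    mean_accuracy = gt$mean, sem = gt$sem, t_value = gt$t, df = gt$df,
    accuracies = accuracies, chosen_c = chosen_c,
    n_permutations = n_perm, perm_t_values = perm_t,
    p_value = p, alpha = alpha, significant = p <= alpha,
    correction = correction, target_condition = spec$target_condition,
    seed = seed
  ), class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "<group_result> target '%s', correction '%s'\n  accuracy %.1f%% +/- %.1f%% (t[%d] = %.2f), p = %.4f (%d permutations)%s\n",
    x$target_condition, x$correction, 100 * x$mean_accuracy, 100 * x$sem,
    x$df, x$t_value, x$p_value, x$n_permutations,
    if (x$significant) " *" else ""))
  invisible(x)
}
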
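#' Classifier specification
#'
#' Settings for the per-subject binary decoding scheme: one retrieval
#' condition versus the other two, linear SVM with hinge loss, class
#' balancing by down-sampling, an 80/20 stratified train/test split, and
#' the regularization constant `C` tuned by run-wise cross-validation on
#' the training data over a decade grid spanning `1e-10` to `1`.
#'
#' @param target_condition Condition decoded against the other two:
#'   `"spatial"`, `"temporal"` or `"pair"`.
#' @param c_grid Strictly increasing positive `C` values (default the 11
#'   decades `1e-10 ... 1`).
#' @param n_folds Cross-validation folds for `C` tuning; folds follow run
#'   boundaries (5 runs give 5 folds).
#' @param train_fraction Fraction of balanced trials allocated to training
#'   (per class).
#' @param standardize Z-score each voxel using training-set statistics
#'   (applied unchanged to test data). Linear SVMs are scale-sensitive, so
#'   this is on by default; set `FALSE` for raw features.
#' @param seed Base seed for down-sampling and splitting.
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec("pair")$c_grid
#' @export
classifier_spec <- function(target_condition = c("pair", "spatial", "temporal"),
                            c_grid = 10^seq(-10, 0), n_folds = 5,
                            train_fraction = 0.8, standardize = TRUE,
                            seed = 1) {
  target_condition <- match.arg(target_condition)
  if (!is.numeric(c_grid) || any(c_grid <= 0) || is.unsorted(c_grid, strictly = TRUE))
    stopf("`c_grid` must be strictly increasing and positive")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("`train_fraction` must be in (0, 1)")
  structure(list(
    target_condition = target_condition,
    c_grid = as.double(c_grid),
    n_folds = check_count(n_folds, "n_folds", min = 2),
    train_fraction = as.double(train_fraction),
    standardize = isTRUE(standardize),
    seed = check_count(seed, "seed", min = 0)
  ), class = "classifier_spec")
}

#' Select and label trials for binary decoding
#'
#' Keeps correct trials only and labels them `+1` (target condition) or
#' `-1` (either other condition).
#'
#' @param trials Trial table.
#' @param target Target condition label.
#' @return Tibble with `index` (row in `trials`) and `label` (+1/-1).
#' @examples
#' cfg <- sim_config(trials_per_condition = 10, n_runs = 2, incorrect_rate = 0)
#' tr <- simulate_trial_table(cfg, 1)
#' table(select_trials(tr, "pair")$label)
#' @export
select_trials <- function(trials, target) {
  if (!target %in% CONDITIONS)
    stopf("`target` must be one of %s", paste(CONDITIONS, collapse = ", "))
  keep <- which(trials$correct)
  if (length(keep) == 0) stopf("no correct trials to classify")
  lab <- ifelse(as.character(trials$condition[keep]) == target, 1, -1)
  if (all(lab == 1) || all(lab == -1))
    stopf("one class is empty after selecting correct trials (target '%s')", target)
  tibble::tibble(index = keep, label = lab)
}

#' Balance classes by down-sampling
#'
#' Randomly subsamples the larger class, without replacement, to the size
#' of the smaller class. Deterministic given `seed`.
#'
#' @param labels Vector of +1/-1 labels.
#' @param seed Integer seed.
#' @return Sorted integer positions (into `labels`) of the retained,
#'   balanced set.
#' @examples
#' idx <- downsample_balance(c(rep(1, 3), rep(-1, 9)), seed = 7)
#' table(c(rep(1, 3), rep(-1, 9))[idx])
#' @export
downsample_balance <- function(labels, seed) {
  pos <- which(labels > 0); neg <- which(labels < 0)
  if (length(pos) == 0 || length(neg) == 0)
    stopf("both classes must be non-empty")
  n <- min(length(pos), length(neg))
  with_seed(derive_seed(seed, 301L), {
    keep <- c(if (length(pos) > n) sample(pos, n) else pos,
              if (length(neg) > n) sample(neg, n) else neg)
  })
  sort(keep)
}

#' Stratified train/test split
#'
#' Splits a balanced trial set into training and test partitions at
#' `train_fraction`, stratified by class so both classes are equally
#' represented in both partitions. Deterministic given `seed`.
#'
#' @param labels Balanced +1/-1 label vector.
#' @param train_fraction Training proportion per class.
#' @param seed Integer seed.
#' @return List with integer positions `train` and `test`.
#' @examples
#' sp <- split_train_test(rep(c(1, -1), each = 10), 0.8, seed = 1)
#' lengths(sp)
#' @export
split_train_test <- function(labels, train_fraction, seed) {
  pos <- which(labels > 0); neg <- which(labels < 0)
  n_tr <- round(train_fraction * length(pos))
  if (n_tr < 1 || n_tr >= length(pos) ||
      round(train_fraction * length(neg)) >= length(neg))
    stopf("train fraction %.2f leaves an empty train or test partition", train_fraction)
  with_seed(derive_seed(seed, 302L), {
    tr <- c(sample(pos, n_tr), sample(neg, round(train_fraction * length(neg))))
  })
  list(train = sort(tr), test = sort(setdiff(seq_along(labels), tr)))
}

# per-voxel standardization estimated on training rows only
std_fit <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(pmax(colSums(X^2) / n - m^2, 0) * n / max(n - 1, 1))
  s[s < 1e-12] <- 1
  list(center = m, scale = s)
}
std_apply <- function(X, st) {
  n <- nrow(X)
  (X - rep(st$center, each = n)) / rep(st$scale, each = n)
}

#' Tune the SVM regularization constant by run-wise cross-validation
#'
#' Partitions the training trials into folds along run boundaries (each run
#' is a fold when the training trials span `n_folds` runs; otherwise
#' contiguous runs are grouped as evenly as possible). For every `C` in the
#' grid a linear SVM is trained on all-but-one fold and scored on the held
#' fold; the `C` with the highest mean fold accuracy wins, ties going to the
#' smallest (most regularized) value.
#'
#' @param X Training feature matrix (trials x voxels).
#' @param y Training labels (+1/-1).
#' @param run_id Run of each training trial.
#' @param spec A [classifier_spec()].
#' @return List with `chosen_c` and `cv` (tibble of per-C per-fold
#'   accuracies).
#' @export
tune_c <- function(X, y, run_id, spec) {
  folds <- make_run_folds(run_id, spec$n_folds)
  fold_ids <- sort(unique(folds))
  grid <- spec$c_grid
  acc <- matrix(NA_real_, length(grid), length(fold_ids))

  prepped <- purrr::map(fold_ids, function(f) {
    tr <- folds != f; te <- !tr
    if (!any(te)) return(NULL)
    Xtr <- X[tr, , drop = FALSE]
    if (spec$standardize) {
      st <- std_fit(Xtr)
      list(Xtr = std_apply(Xtr, st), ytr = y[tr],
           Xte = std_apply(X[te, , drop = FALSE], st), yte = y[te])
    } else {
      list(Xtr = Xtr, ytr = y[tr], Xte = X[te, , drop = FALSE], yte = y[te])
    }
  })

  degenerate <- vapply(prepped, function(p)
    is.null(p) || length(unique(p$yte)) < 2, logical(1))
  if (any(degenerate) && !all(degenerate))
    warn("some cross-validation folds contain a single class; their accuracy is computed on the available labels",
         .frequency = "once", .frequency_id = "mvpaproj_degenerate_fold")
  if (all(degenerate))
    stopf("all cross-validation folds are degenerate (single class); cannot tune C")

  for (fi in seq_along(prepped)) {
    p <- prepped[[fi]]
    if (is.null(p)) next
    for (ci in seq_along(grid)) {
      fit <- fit_linear_svm(p$Xtr, p$ytr, grid[ci])
      acc[ci, fi] <- mean(svm_predict(fit, p$Xte) == p$yte)
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  chosen <- grid[which.max(mean_acc)]  # first max = smallest C on an ascending grid
  cv <- tibble::tibble(
    C = rep(grid, times = length(fold_ids)),
    fold = rep(fold_ids, each = length(grid)),
    accuracy = as.vector(acc)
  )
  list(chosen_c = chosen, cv = cv)
}

# group runs into <= n_folds contiguous folds, as evenly as possible
make_run_folds <- function(run_id, n_folds) {
  runs <- sort(unique(run_id))
  k <- min(n_folds, length(runs))
  sizes <- rep(length(runs) %/% k, k)
  if (length(runs) %% k > 0) sizes[seq_len(length(runs) %% k)] <- sizes[seq_len(length(runs) %% k)] + 1
  run_fold <- rep(seq_len(k), times = sizes)
  run_fold[match(run_id, runs)]
}

# Core per-subject pipeline on pre-selected (correct, corrected) trials.
# X: trials x voxels, y: +1/-1, run_id: aligned runs. fixed_c skips tuning.
pipeline_accuracy <- function(X, y, run_id, spec, seed, fixed_c = NULL) {
  bal <- downsample_balance(y, seed)
  Xb <- X[bal, , drop = FALSE]; yb <- y[bal]; rb <- run_id[bal]
  sp <- split_train_test(yb, spec$train_fraction, seed)
  Xtr <- Xb[sp$train, , drop = FALSE]; ytr <- yb[sp$train]
  Xte <- Xb[sp$test, , drop = FALSE]; yte <- yb[sp$test]

  if (is.null(fixed_c)) {
    tuned <- tune_c(Xtr, ytr, rb[sp$train], spec)
    chosen_c <- tuned$chosen_c
    cv <- tuned$cv
  } else {
    chosen_c <- fixed_c
    cv <- NULL
  }
  if (spec$standardize) {
    st <- std_fit(Xtr)
    Xtr <- std_apply(Xtr, st)
    Xte <- std_apply(Xte, st)
  }
  fit <- fit_linear_svm(Xtr, ytr, chosen_c)
  list(accuracy = mean(svm_predict(fit, Xte) == yte),
       chosen_c = chosen_c, cv = cv,
       n_train_per_class = sum(ytr > 0), n_test_per_class = sum(yte > 0))
}

#' Decode one subject's condition from their pattern matrix
#'
#' Runs the full per-subject scheme: keep correct trials, optionally apply
#' a confound correction (computed across all correct trials), balance
#' classes by down-sampling, split 80/20 stratified by class, tune `C` by
#' run-wise cross-validation within the training data, train the final
#' linear SVM at the chosen `C` on all training trials, and report accuracy
#' on the untouched test set. Feature standardization parameters are
#' estimated on training data only.
#'
#' @param trials Trial table.
#' @param D Voxel-by-trial matrix aligned to `trials`.
#' @param spec A [classifier_spec()].
#' @param correction `"none"`, `"mean_signal"` or `"response_time"`.
#' @param seed Seed for down-sampling and splitting; defaults to
#'   `spec$seed`.
#' @return An object of class `subject_result`.
#' @examples
#' cfg <- sim_config(n_voxels = 10, trials_per_condition = 20, n_runs = 5,
#'                   pattern_effect = 2, noise_sd = 1)
#' tr <- simulate_trial_table(cfg, 3)
#' D <- simulate_patterns(tr, cfg, 3)
#' res <- classify_subject(tr, D, classifier_spec("pair", seed = 3))
#' res$accuracy
#' @export
classify_subject <- function(trials, D, spec = classifier_spec(),
                             correction = c("none", "mean_signal", "response_time"),
                             seed = spec$seed) {
  correction <- match.arg(correction)
  check_aligned(D, trials)
  sel <- select_trials(trials, spec$target_condition)
  Dc <- apply_correction(D[, sel$index, drop = FALSE], trials[sel$index, ],
                         kind = correction)
  out <- pipeline_accuracy(t(unclass_matrix(Dc)), sel$label,
                           trials$run_id[sel$index], spec, seed)
  structure(list(
    accuracy = out$accuracy,
    chosen_c = out$chosen_c,
    n_train_per_class = out$n_train_per_class,
    n_test_per_class = out$n_test_per_class,
    fold_accuracies = out$cv,
    target_condition = spec$target_condition,
    correction = correction,
    seed = seed
  ), class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf(
    "<subject_result> target '%s', correction '%s'\n  accuracy %.3f (chosen C = %g; %d/%d train, %d/%d test per class)\n",
    x$target_condition, x$correction, x$accuracy, x$chosen_c,
    x$n_train_per_class, x$n_train_per_class,
    x$n_test_per_class, x$n_test_per_class))
  invisible(x)
}
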
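#' Tidy and glance methods for fitted result objects
#'
#' `tidy()` returns the per-unit detail of a result (per-C/fold accuracies
#' for a `subject_result`, per-subject accuracies for a `group_result`,
#' per-cell verdicts for a `scenario_report`); `glance()` returns a
#' one-row summary.
#'
#' @param x A `subject_result`, `group_result` or `scenario_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name mvpaproj-tidiers
NULL

#' @rdname mvpaproj-tidiers
#' @export
tidy.subject_result <- function(x, ...) {
  if (is.null(x$fold_accuracies)) return(tibble::tibble())
  x$fold_accuracies
}

#' @rdname mvpaproj-tidiers
#' @export
glance.subject_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, chosen_c = x$chosen_c,
                 n_train_per_class = x$n_train_per_class,
                 n_test_per_class = x$n_test_per_class,
                 target_condition = x$target_condition,
                 correction = x$correction)
}

#' @rdname mvpaproj-tidiers
#' @export
tidy.group_result <- function(x, ...) {
  tibble::tibble(subject = seq_along(x$accuracies),
                 accuracy = x$accuracies, chosen_c = x$chosen_c)
}

#' @rdname mvpaproj-tidiers
#' @export
glance.group_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, sem = x$sem,
                 t_value = x$t_value, df = x$df,
                 n_permutations = x$n_permutations,
                 p_value = x$p_value, significant = x$significant,
                 target_condition = x$target_condition,
                 correction = x$correction)
}

#' @rdname mvpaproj-tidiers
#' @export
tidy.scenario_report <- function(x, ...) {
  dplyr::mutate(x$cells, scenario = x$scenario, .before = 1)
}

#' @rdname mvpaproj-tidiers
#' @export
glance.scenario_report <- function(x, ...) {
  tibble::tibble(scenario = x$scenario,
                 n_subjects = x$config$n_subjects,
                 n_perm = x$n_perm,
                 n_significant = sum(x$cells$significant),
                 verdicts = paste(ifelse(x$cells$significant, "sig", "ns"),
                                  collapse = "/"))
}
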
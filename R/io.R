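#' Read and write trial tables as TSV
#'
#' Plain tab-separated files with the canonical columns `trial_id`,
#' `condition`, `response_time_ms`, `run_id`, `correct` and optionally
#' `onset_s`.
#'
#' @param path File path.
#' @param trials Trial table tibble.
#' @return `read_trial_table()` returns a tibble; `write_trial_table()`
#'   returns `trials` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' tr <- simulate_trial_table(sim_config(trials_per_condition = 4, n_runs = 2), 1)
#' write_trial_table(tr, f)
#' read_trial_table(f)
#' @export
read_trial_table <- function(path) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "condition", "response_time_ms", "run_id", "correct")
  if (!all(need %in% names(tr)))
    stopf("trial table is missing columns: %s",
          paste(setdiff(need, names(tr)), collapse = ", "))
  bad <- setdiff(unique(tr$condition), CONDITIONS)
  if (length(bad))
    stopf("unknown condition labels: %s", paste(bad, collapse = ", "))
  if (any(tr$response_time_ms <= 0)) stopf("response times must be positive")
  tr$condition <- factor(tr$condition, levels = CONDITIONS)
  tr$run_id <- as.integer(tr$run_id)
  tr$correct <- as.logical(tr$correct)
  tr
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path, progress = FALSE)
  invisible(trials)
}

#' Read and write voxel-by-trial pattern matrices as TSV
#'
#' Rows are voxels (first column `voxel_id`), remaining columns are trials.
#'
#' @param path File path.
#' @param D Voxel-by-trial numeric matrix.
#' @return `read_pattern_matrix()` returns a numeric matrix with voxel ids
#'   as row names; `write_pattern_matrix()` returns `D` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' D <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
#' write_pattern_matrix(D, f)
#' all.equal(read_pattern_matrix(f), D)
#' @export
read_pattern_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "voxel_id") stopf("first column must be `voxel_id`")
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$voxel_id
  colnames(D) <- NULL
  storage.mode(D) <- "double"
  if (!all(is.finite(D))) stopf("pattern matrix contains non-finite values")
  D
}

#' @rdname read_pattern_matrix
#' @export
write_pattern_matrix <- function(D, path) {
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(nrow(D)))
  df <- tibble::as_tibble(as.data.frame(unclass_matrix(D)),
                          .name_repair = ~ sprintf("t%d", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(voxel_id = ids), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(D)
}

#' Read a single-trial beta series from NIfTI
#'
#' Loads a 4-D NIfTI image (one volume per trial) and a 3-D mask, and
#' returns the voxel-by-trial matrix of in-mask values. Requires the
#' `RNifti` package.
#'
#' @param beta_path Path to the 4-D beta-series NIfTI.
#' @param mask_path Path to the 3-D ROI mask NIfTI (non-zero = in mask).
#' @return Voxel-by-trial matrix; row names encode voxel coordinates.
#' @export
read_beta_series <- function(beta_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("the RNifti package is required to read NIfTI files")
  img <- RNifti::readNifti(beta_path)
  mask <- RNifti::readNifti(mask_path)
  if (length(dim(img)) != 4) stopf("beta series must be a 4-D image")
  if (!all(dim(img)[1:3] == dim(mask)[1:3]))
    stopf("mask dimensions do not match the beta series")
  keep <- which(mask != 0)
  n_trial <- dim(img)[4]
  flat <- matrix(img, ncol = n_trial)
  D <- flat[keep, , drop = FALSE]
  ijk <- arrayInd(keep, dim(mask)[1:3])
  rownames(D) <- sprintf("x%d_y%d_z%d", ijk[, 1], ijk[, 2], ijk[, 3])
  D
}
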
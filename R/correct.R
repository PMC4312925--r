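#' Remove the mean-signal component from a pattern matrix
#'
#' Projects every trial column of the voxel-by-trial matrix `D` onto the
#' orthogonal complement of the voxel-wise mean response pattern. With
#' \eqn{\hat m} the unit-normalized vector of voxel means across trials,
#'
#' \deqn{D' = D - \hat m \hat m^\top D}
#'
#' so each corrected trial pattern is orthogonal to the region's mean
#' spatial pattern: any classifier signal that remains cannot be carried by
#' differences in overall (mean) signal amplitude between conditions.
#'
#' Normalizing `m` to unit length makes \eqn{\hat m \hat m^\top} an
#' orthogonal projector (idempotent, norm non-increasing); without it the
#' operation would not be a projection. If the mean pattern is numerically
#' zero there is nothing to remove and `D` is returned unchanged with a
#' warning.
#'
#' @param D Numeric voxel-by-trial matrix with at least 2 trials.
#' @return A matrix of the same shape, of class `corrected_matrix`, with
#'   attributes `correction = "mean_signal"` and `diagnostics` (the maximum
#'   over columns of \eqn{|\hat m^\top d'| / \|d'\|}).
#' @examples
#' D <- matrix(rnorm(50 * 12, mean = 10), 50, 12)
#' Dc <- mean_correct(D)
#' max(abs(crossprod(rowMeans(D) / sqrt(sum(rowMeans(D)^2)), Dc)))  # ~0
#' @export
mean_correct <- function(D) {
  if (!is.matrix(D) || ncol(D) < 2)
    stopf("`D` must be a matrix with at least 2 trial columns")
  if (!all(is.finite(D))) stopf("`D` contains non-finite values")
  m <- rowMeans(D)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-12) {
    warn("voxel-wise mean pattern is numerically zero; returning D unchanged")
    return(new_corrected(unclass_matrix(D), "mean_signal", diagnostics = 0))
  }
  mh <- m / nm
  Dc <- D - mh %*% crossprod(mh, D)
  cn <- sqrt(colSums(Dc^2))
  resid_align <- max(abs(crossprod(mh, Dc)) / pmax(cn, 1e-300) * (cn > 0))
  new_corrected(Dc, "mean_signal", diagnostics = resid_align)
}

#' Residualize a pattern matrix on response time
#'
#' Removes, voxel by voxel, the across-trial signal variance linearly
#' explained by response time. With \eqn{\tilde r} the mean-centered trial
#' RT vector, each voxel row of `D` is replaced by its residual from the
#' regression on \eqn{\tilde r}:
#'
#' \deqn{D' = D - D \tilde r (\tilde r^\top \tilde r)^{-1} \tilde r^\top}
#'
#' This is the residual-maker (annihilator) applied on the trial dimension;
#' voxel means are preserved because `r` is centered first (projecting on
#' raw, strictly positive RTs would also strip most of each voxel's mean and
#' conflate this correction with the mean-signal one). After correction no
#' voxel's response covaries with RT, so remaining classifier signal cannot
#' be mediated by task difficulty as indexed by RT.
#'
#' The formula `D' = D - PD` with `P = E - r(r'r)^{-1}r'` that is sometimes
#' quoted for this correction, read literally, *retains* exactly the
#' RT-spanned component instead of removing it; that literal operator is
#' available via `literal = TRUE` for comparison, while the default
#' implements the stated intent of controlling for RT.
#'
#' @param D Numeric voxel-by-trial matrix with at least 3 trials.
#' @param trials Trial table aligned to `D`'s columns (uses
#'   `response_time_ms`).
#' @param literal If `TRUE`, apply the literal compatibility reading
#'   \eqn{D' = D M_r} with \eqn{M_r = r(r^\top r)^{-1} r^\top} on raw RTs
#'   (keeps only the RT-spanned component). Default `FALSE`.
#' @return A `corrected_matrix` with `correction = "response_time"` and
#'   `diagnostics` (maximum over voxels of the relative residual
#'   RT-covariance).
#' @examples
#' cfg <- sim_config(n_voxels = 10, trials_per_condition = 20, n_runs = 2,
#'                   rt_coupling = 0.01, noise_sd = 0.1)
#' tr <- simulate_trial_table(cfg, 1)
#' D <- simulate_patterns(tr, cfg, 1)
#' Dc <- rt_correct(D, tr)
#' max(abs(cor(t(Dc), tr$response_time_ms)))  # ~0
#' @export
rt_correct <- function(D, trials, literal = FALSE) {
  check_aligned(D, trials)
  if (ncol(D) < 3) stopf("`D` must have at least 3 trials for RT residualization")
  r <- trials$response_time_ms
  if (literal) {
    nr2 <- sum(r^2)
    if (nr2 < 1e-300) stopf("RT vector is numerically zero")
    Dc <- (D %*% r) %*% t(r) / nr2
    return(new_corrected(Dc, "response_time_literal", diagnostics = NA_real_))
  }
  rc <- r - mean(r)
  s2 <- sum(rc^2)
  if (s2 < 1e-12 * max(1, mean(r)^2)) {
    warn("response times have zero variance; returning D unchanged")
    return(new_corrected(unclass_matrix(D), "response_time", diagnostics = 0))
  }
  Dc <- D - ((D %*% rc) / s2) %*% t(rc)
  rn <- sqrt(rowSums(Dc^2)) * sqrt(s2)
  resid_cov <- max(abs(Dc %*% rc) / pmax(rn, 1e-300) * (rn > 0))
  new_corrected(Dc, "response_time", diagnostics = resid_cov)
}

#' Apply a named confound correction
#'
#' Dispatches to [mean_correct()], [rt_correct()], or returns the matrix
#' unchanged for `"none"`, recording which correction was applied.
#'
#' @param D Voxel-by-trial matrix.
#' @param trials Trial table aligned to `D` (needed for `"response_time"`).
#' @param kind `"none"`, `"mean_signal"` or `"response_time"`.
#' @return A `corrected_matrix`.
#' @examples
#' D <- matrix(rnorm(20), 4, 5)
#' identical(unclass(apply_correction(D, kind = "none"))[seq_along(D)], c(D))
#' @export
apply_correction <- function(D, trials = NULL,
                             kind = c("none", "mean_signal", "response_time")) {
  kind <- match.arg(kind)
  switch(kind,
    none = new_corrected(unclass_matrix(D), "none", diagnostics = NA_real_),
    mean_signal = mean_correct(D),
    response_time = {
      if (is.null(trials)) stopf("`trials` is required for the response-time correction")
      rt_correct(D, trials)
    }
  )
}

new_corrected <- function(values, correction, diagnostics) {
  structure(values, correction = correction, diagnostics = diagnostics,
            truth = NULL, class = c("corrected_matrix", class(values)))
}

# strip simulation attributes but keep dims/dimnames
unclass_matrix <- function(D) {
  attr(D, "truth") <- NULL
  class(D) <- setdiff(class(D), "corrected_matrix")
  D
}
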
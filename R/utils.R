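# Internal helpers shared across modules.

CONDITIONS <- c("spatial", "temporal", "pair")

# Deterministic stream of derived seeds: mixes a base seed with one or two
# indices so that per-subject / per-permutation draws are independent and
# reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 48271 + i * 2654435 + j * 192029) %% 2147483629 + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(...) abort(sprintf(...))

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d, got %s", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

# Condition-wise parameter: accept a scalar (recycled) or a length-3 vector,
# optionally named by condition.
per_condition <- function(x, name) {
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3)
    stopf("`%s` must have length 1 or 3, got %d", name, length(x))
  if (!is.null(names(x))) {
    if (!setequal(names(x), CONDITIONS))
      stopf("names of `%s` must be %s", name, paste(CONDITIONS, collapse = ", "))
    x <- x[CONDITIONS]
  }
  setNames(as.double(x), CONDITIONS)
}

# Alignment check between a voxel-by-trial matrix and its trial table.
check_aligned <- function(D, trials) {
  if (!is.matrix(D) || !is.numeric(D))
    stopf("pattern matrix must be a numeric matrix (voxels x trials)")
  if (ncol(D) != nrow(trials))
    stopf("pattern matrix has %d trial columns but the trial table has %d rows",
          ncol(D), nrow(trials))
  if (!all(is.finite(D))) stopf("pattern matrix contains non-finite values")
  invisible(TRUE)
}
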
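# Thin R layer over the compiled dual coordinate-descent linear SVM
# (L2-regularized hinge loss, the LIBLINEAR-style solver in src/).

# X: examples x features, y: +1/-1. Returns list(w, b).
fit_linear_svm <- function(X, y, C, eps = 0.1, max_iter = 1000) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (all(y > 0) || all(y < 0)) {
    # degenerate single-class training set: constant classifier
    return(list(w = numeric(ncol(X)), b = if (y[1] > 0) 1 else -1,
                single_class = TRUE))
  }
  wb <- svm_linear_cd(X, as.double(y), as.double(C), eps, as.integer(max_iter))
  p <- ncol(X)
  list(w = wb[seq_len(p)], b = wb[p + 1], single_class = FALSE)
}

# decision values
svm_decision <- function(model, X) {
  drop(X %*% model$w) + model$b
}

# hard +1/-1 predictions (ties go negative)
svm_predict <- function(model, X) {
  ifelse(svm_decision(model, X) > 0, 1, -1)
}

# primal objective, used by the optimality cross-checks in the tests
svm_objective <- function(w, b, X, y, C) {
  margins <- 1 - y * (drop(X %*% w) + b)
  0.5 * sum(w^2) + 0.5 * b^2 + C * sum(pmax(margins, 0))
}
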
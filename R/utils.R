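# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds, keeping class proportions as
#' balanced as integer counts allow. Uses the current RNG state.
#'
#' @param labels class label vector.
#' @param k number of folds.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# min-max scaling to [-1, 1]; constant features map to 0
minmax_fit <- function(X) {
  list(min = apply(X, 2, min), max = apply(X, 2, max))
}

minmax_apply <- function(X, sc) {
  rng <- sc$max - sc$min
  rng[rng == 0] <- 1
  out <- sweep(sweep(X, 2, sc$min), 2, rng, "/") * 2 - 1
  out[, sc$max == sc$min] <- 0
  out
}

CLASS_LEVELS <- c("non_resistant", "resistant")

fit_svm <- function(X, y, cost, gamma) {
  e1071::svm(x = as.matrix(X), y = factor(y, levels = CLASS_LEVELS),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# predicted labels and signed margin (positive = resistant)
svm_predict <- function(fit, X) {
  p <- stats::predict(fit, as.matrix(X), decision.values = TRUE)
  dv <- attr(p, "decision.values")
  sgn <- if (grepl("^resistant/", colnames(dv)[1])) 1 else -1
  list(pred = as.character(p), decision = sgn * as.numeric(dv[, 1]))
}

# pooled out-of-fold predictions under fixed fold assignment
svm_cv_predict <- function(X, y, folds, cost, gamma) {
  X <- as.matrix(X)
  pred <- character(nrow(X))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sc <- minmax_fit(X[tr, , drop = FALSE])
    fit <- fit_svm(minmax_apply(X[tr, , drop = FALSE], sc), y[tr], cost, gamma)
    pred[!tr] <- svm_predict(fit, minmax_apply(X[!tr, , drop = FALSE], sc))$pred
  }
  pred
}

mask_key <- function(bits) paste(bits, collapse = "")
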
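#' Train an RBF-kernel SVM with exponential grid search
#'
#' Evaluates every (C, gamma) = (2^a, 2^b) with integer exponents a, b in
#' [-15, 15] (a 31 x 31 grid) by stratified k-fold cross-validated MCC on
#' min-max-scaled masked features, then refits on the full set with the best
#' pair. Ties are broken toward the smaller cost exponent, then the smaller
#' gamma exponent. Scaling is fitted on training folds only during CV and on
#' the full set for the final model.
#'
#' @param table numeric feature matrix (n x m) with column names.
#' @param labels `"resistant"` / `"non_resistant"` vector with at least 2 of
#'   each class.
#' @param mask integer 0/1 feature mask (default: all features).
#' @param k cross-validation folds.
#' @param seed seed for the fold assignment.
#' @param exponents integer grid of exponents for both axes.
#' @param role stored on the model: `"global"`, `"interior"` or `"exterior"`.
#' @return Object of class `trained_model`: `role`, `mask`, `cost`, `gamma`,
#'   `exponents` (chosen a, b), `scaling`, `fit` (the LIBSVM model),
#'   `cv_report`, `cv_mcc`, `feature_names`, `seed`.
#' @export
grid_search_train <- function(table, labels, mask = NULL, k = 5, seed = 1,
                              exponents = -15:15,
                              role = c("global", "interior", "exterior")) {
  role <- match.arg(role)
  table <- as.matrix(table)
  if (is.null(mask)) mask <- rep(1L, ncol(table))
  if (sum(mask) == 0) stop("mask non-empty required")
  if (length(unique(labels)) < 2 ||
      min(table(factor(labels, CLASS_LEVELS))) < 2)
    stop("data error: need at least 2 samples per class")
  X <- table[, mask == 1, drop = FALSE]
  folds <- with_seed(seed, stratified_folds(labels, k))

  # per-fold scaled splits are independent of (C, gamma): precompute
  fold_ids <- sort(unique(folds))
  splits <- lapply(fold_ids, function(f) {
    tr <- folds != f
    sc <- minmax_fit(X[tr, , drop = FALSE])
    list(xtr = minmax_apply(X[tr, , drop = FALSE], sc), ytr = labels[tr],
         xte = minmax_apply(X[!tr, , drop = FALSE], sc), te = which(!tr))
  })
  best <- list(mcc = -Inf, a = NA, b = NA)
  for (a in exponents) for (b in exponents) {
    pred <- character(nrow(X))
    for (s in splits) {
      fit <- fit_svm(s$xtr, s$ytr, 2^a, 2^b)
      pred[s$te] <- svm_predict(fit, s$xte)$pred
    }
    mcc <- measure(confusion(labels, pred), "MCC")
    if (mcc > best$mcc) best <- list(mcc = mcc, a = a, b = b, pred = pred)
  }
  sc <- minmax_fit(X)
  fit <- fit_svm(minmax_apply(X, sc), labels, 2^best$a, 2^best$b)
  structure(list(role = role, mask = mask, cost = 2^best$a, gamma = 2^best$b,
                 exponents = c(a = best$a, b = best$b), scaling = sc,
                 fit = fit, cv_report = evaluation_report(labels, best$pred),
                 cv_mcc = best$mcc,
                 feature_names = colnames(table), seed = seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model (", x$role, "): C = 2^", x$exponents[["a"]],
      ", gamma = 2^", x$exponents[["b"]], ", ", sum(x$mask), "/",
      length(x$mask), " features, CV MCC = ", round(x$cv_mcc, 4), "\n",
      sep = "")
  invisible(x)
}

# scale + mask a feature matrix for one trained model, checking names
model_design <- function(model, table) {
  table <- as.matrix(table)
  if (!is.null(model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(table))
    if (length(missing))
      stop("input error: missing features: ", paste(missing, collapse = ", "))
    table <- table[, model$feature_names, drop = FALSE]
  }
  minmax_apply(table[, model$mask == 1, drop = FALSE], model$scaling)
}

#' Train the combined interior + exterior model
#'
#' One grid-searched SVM per distance stratum, each with its own feature
#' mask and scaling; prediction routes by the 8 Angstrom cutoff.
#'
#' @param interior_table,interior_labels binding-pocket stratum (distance to
#'   drug at most `cutoff`).
#' @param exterior_table,exterior_labels distal stratum.
#' @param interior_mask,exterior_mask 0/1 feature masks (default: all).
#' @param cutoff routing cutoff in Angstrom.
#' @param k,seed,exponents cross-validation folds, seed and exponent grid,
#'   passed to [grid_search_train()].
#' @return Object of class `combined_model` with `interior`, `exterior`,
#'   `cutoff`.
#' @export
train_combined <- function(interior_table, interior_labels,
                           exterior_table, exterior_labels,
                           interior_mask = NULL, exterior_mask = NULL,
                           cutoff = 8.0, k = 5, seed = 1, exponents = -15:15) {
  n_i <- nrow(as.matrix(interior_table)); n_e <- nrow(as.matrix(exterior_table))
  if (min(n_i, n_e) < 10)
    stop("smallest subgroup has ", min(n_i, n_e),
         " samples (< 10); refusing to train the combined model")
  structure(list(
    interior = grid_search_train(interior_table, interior_labels,
                                 interior_mask, k, seed, exponents,
                                 role = "interior"),
    exterior = grid_search_train(exterior_table, exterior_labels,
                                 exterior_mask, k, seed, exponents,
                                 role = "exterior"),
    cutoff = cutoff), class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat("combined_model (cutoff ", x$cutoff, " A)\n", sep = "")
  print(x$interior); print(x$exterior)
  invisible(x)
}

#' Predict with the combined model, routing by distance
#'
#' Each variant is routed to the interior or exterior submodel by its
#' distance to the drug; that submodel's mask and training-set scaling are
#' applied and the predicted label plus signed decision value (positive =
#' resistant) returned.
#'
#' @param model a `combined_model`.
#' @param table feature matrix (rows are SAVs; the 45 canonical columns).
#' @param distance numeric vector of SAV-drug distances in Angstrom.
#' @return data.frame with `distance`, `routed`, `predicted`,
#'   `decision_value`.
#' @export
predict_combined <- function(model, table, distance) {
  table <- as.matrix(table)
  if (nrow(table) != length(distance))
    stop("input error: one distance per feature row required")
  routed <- route_by_distance(distance, model$cutoff)
  pred <- character(nrow(table)); dv <- numeric(nrow(table))
  for (side in c("interior", "exterior")) {
    idx <- routed == side
    if (!any(idx)) next
    sub <- model[[side]]
    out <- svm_predict(sub$fit, model_design(sub, table[idx, , drop = FALSE]))
    pred[idx] <- out$pred
    dv[idx] <- out$decision
  }
  data.frame(distance = distance, routed = routed, predicted = pred,
             decision_value = dv, stringsAsFactors = FALSE)
}

#' Save / load a combined model directory
#'
#' `save_combined_model()` writes JSON metadata (roles, masks, chosen
#' hyperparameters, scaling, seeds, CV reports) plus the serialized
#' classifier state for each submodel; `load_combined_model()` restores it.
#'
#' @param model a `combined_model`.
#' @param dir model directory.
#' @return `dir` (save) or the restored `combined_model` (load).
#' @export
save_combined_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(cutoff = model$cutoff)
  for (side in c("interior", "exterior")) {
    sub <- model[[side]]
    meta[[side]] <- list(role = sub$role, mask = sub$mask,
                         cost = sub$cost, gamma = sub$gamma,
                         scaling = sub$scaling, seed = sub$seed,
                         feature_names = sub$feature_names,
                         cv_report = list(counts = as.list(sub$cv_report$counts),
                                          measures = as.list(sub$cv_report$measures)))
    saveRDS(sub$fit, file.path(dir, paste0(side, "_svm.rds")))
  }
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_combined_model
#' @export
load_combined_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  build <- function(side) {
    m <- meta[[side]]
    structure(list(role = m$role, mask = m$mask, cost = m$cost,
                   gamma = m$gamma,
                   scaling = list(min = m$scaling$min, max = m$scaling$max),
                   fit = readRDS(file.path(dir, paste0(side, "_svm.rds"))),
                   cv_report = m$cv_report, cv_mcc = m$cv_report$measures$MCC,
                   feature_names = m$feature_names, seed = m$seed),
              class = "trained_model")
  }
  structure(list(interior = build("interior"), exterior = build("exterior"),
                 cutoff = meta$cutoff), class = "combined_model")
}
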
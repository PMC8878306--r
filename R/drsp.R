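#' Fit the combined drug-resistance SAV prediction model
#'
#' The central fitting function. Labeled SAV feature vectors are split by
#' their distance to the drug into a binding-pocket (interior, distance <=
#' `cutoff`) and a distal (exterior) stratum. Per stratum, a genetic
#' algorithm selects a feature subset by cross-validated SVM fitness
#' ([run_ga()]), then an RBF-kernel SVM is trained on the selected features
#' with an exponential (C, gamma) grid search ([grid_search_train()]). The
#' combined model routes new variants by distance; its training report pools
#' the two strata's cross-validated confusion counts.
#'
#' @param table numeric feature matrix or data.frame (rows are SAVs; columns
#'   are features, canonically the 45 named features), or the output of
#'   [featurize_dataset()] in which case `labels` and `distance` are taken
#'   from it.
#' @param labels `"resistant"` / `"non_resistant"` per row.
#' @param distance SAV-drug distance in Angstrom per row.
#' @param cutoff interior/exterior routing cutoff (Angstrom).
#' @param ga a [ga_control()]; its seed is used for the interior stratum and
#'   `seed + runs` for the exterior. `NULL` skips feature selection (all
#'   features retained).
#' @param k cross-validation folds for the final grid search.
#' @param seed seed for the grid-search fold assignments.
#' @param exponents grid-search exponent range.
#' @return Object of class `drsp`: `model` (`combined_model`), `ga`
#'   (per-stratum `ga_result` or NULL), `report` (pooled evaluation),
#'   `routing` (per-stratum sample counts), `cutoff`, `call`.
#' @examples
#' \donttest{
#' ft <- make_feature_table(n_samples = 120, effect_size = 3, seed = 1)
#' d <- exp(stats::runif(120, log(2), log(20)))
#' fit <- drsp(ft$table, ft$labels, d, ga = NULL, exponents = -5:5)
#' print(fit)
#' }
#' @export
drsp <- function(table, labels = NULL, distance = NULL, cutoff = 8.0,
                 ga = ga_control(), k = 5, seed = 1, exponents = -15:15) {
  cl <- match.call()
  if (is.list(table) && !is.null(table$features)) {
    fd <- table$features
    labels <- fd$label
    distance <- fd$distance
    table <- as.matrix(fd[, feature_names(), drop = FALSE])
  }
  table <- as.matrix(table)
  if (is.null(labels) || is.null(distance))
    stop("labels and distance are required")
  if (nrow(table) != length(labels) || nrow(table) != length(distance))
    stop("input error: table rows, labels and distances must align")
  routed <- route_by_distance(distance, cutoff)

  fit_side <- function(side, ga_seed_offset) {
    idx <- routed == side
    Xs <- table[idx, , drop = FALSE]
    ys <- labels[idx]
    gres <- NULL
    mask <- rep(1L, ncol(table))
    if (!is.null(ga)) {
      cfg <- ga
      cfg$seed <- cfg$seed + ga_seed_offset
      gres <- run_ga(Xs, ys, cfg)
      mask <- gres$best_mask
    }
    list(ga = gres, mask = mask, n = sum(idx))
  }
  int <- fit_side("interior", 0L)
  ext <- fit_side("exterior", if (is.null(ga)) 0L else ga$runs)

  model <- train_combined(
    table[routed == "interior", , drop = FALSE], labels[routed == "interior"],
    table[routed == "exterior", , drop = FALSE], labels[routed == "exterior"],
    interior_mask = int$mask, exterior_mask = ext$mask,
    cutoff = cutoff, k = k, seed = seed, exponents = exponents)

  pooled <- model$interior$cv_report$counts + model$exterior$cv_report$counts
  report <- list(counts = pooled, measures = c(
    Accuracy = measure(pooled, "Acc"),
    Sensitivity = pooled[["TP"]] / max(1, pooled[["TP"]] + pooled[["FN"]]),
    Specificity = pooled[["TN"]] / max(1, pooled[["TN"]] + pooled[["FP"]]),
    MCC = measure(pooled, "MCC"),
    Precision = if (pooled[["TP"]] + pooled[["FP"]] > 0)
      pooled[["TP"]] / (pooled[["TP"]] + pooled[["FP"]]) else 0,
    F1 = measure(pooled, "F1")))

  structure(list(model = model,
                 ga = list(interior = int$ga, exterior = ext$ga),
                 report = report,
                 routing = c(interior = int$n, exterior = ext$n),
                 cutoff = cutoff, seed = seed, call = cl),
            class = "drsp")
}

#' @export
print.drsp <- function(x, ...) {
  cat("Combined drug-resistance SAV prediction model (cutoff ",
      x$cutoff, " A)\n", sep = "")
  cat("Training SAVs: ", x$routing[["interior"]], " interior, ",
      x$routing[["exterior"]], " exterior\n", sep = "")
  m <- x$report$measures
  cat(sprintf("Pooled 5-fold CV: Accuracy %.4f  Sensitivity %.4f  Specificity %.4f\n",
              m[["Accuracy"]], m[["Sensitivity"]], m[["Specificity"]]))
  cat(sprintf("                  MCC %.4f  Precision %.4f  F1 %.4f\n",
              m[["MCC"]], m[["Precision"]], m[["F1"]]))
  invisible(x)
}

#' @export
summary.drsp <- function(object, ...) {
  structure(list(fit = object), class = "summary.drsp")
}

#' @export
print.summary.drsp <- function(x, ...) {
  ob <- x$fit
  print(ob)
  for (side in c("interior", "exterior")) {
    sub <- ob$model[[side]]
    cat("\n--- ", side, " submodel ---\n", sep = "")
    print(sub)
    sel <- which(sub$mask == 1)
    nm <- if (!is.null(sub$feature_names)) sub$feature_names[sel] else sel
    cat("features: ", paste(nm, collapse = ", "), "\n", sep = "")
    mm <- sub$cv_report$measures
    cat(sprintf("CV: Acc %.4f  Sens %.4f  Spec %.4f  MCC %.4f  Prec %.4f  F1 %.4f\n",
                mm[["Accuracy"]], mm[["Sensitivity"]], mm[["Specificity"]],
                mm[["MCC"]], mm[["Precision"]], mm[["F1"]]))
  }
  invisible(x)
}

#' Predict resistance labels for new SAVs
#'
#' @param object a fitted [drsp()] model.
#' @param newdata feature matrix/data.frame with the training feature
#'   columns, or a [featurize_dataset()] result.
#' @param distance SAV-drug distances (ignored when `newdata` carries them).
#' @param ... unused.
#' @return data.frame with `distance`, `routed`, `predicted`,
#'   `decision_value` per row.
#' @export
predict.drsp <- function(object, newdata, distance = NULL, ...) {
  if (is.list(newdata) && !is.null(newdata$features)) {
    distance <- newdata$features$distance
    newdata <- as.matrix(newdata$features[, feature_names(), drop = FALSE])
  }
  if (is.null(distance)) stop("input error: distances are required")
  predict_combined(object$model, as.matrix(newdata), distance)
}

#' Plot genetic-algorithm fitness traces of a fitted model
#'
#' Best-incumbent fitness per generation for the winning run of each
#' stratum; flat lines confirm the elitist (non-decreasing) contract.
#'
#' @param x a fitted [drsp()] model with GA results.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drsp <- function(x, ...) {
  tr_i <- x$ga$interior$trace
  tr_e <- x$ga$exterior$trace
  if (is.null(tr_i) && is.null(tr_e))
    stop("no GA traces: model was fitted with ga = NULL")
  ylim <- range(c(tr_i, tr_e), na.rm = TRUE)
  graphics::plot(seq_along(tr_i), tr_i, type = "s", col = "steelblue",
                 lwd = 2, xlab = "generation", ylab = "best fitness",
                 ylim = ylim, main = "GA feature selection", ...)
  if (!is.null(tr_e))
    graphics::lines(seq_along(tr_e), tr_e, type = "s", col = "firebrick",
                    lwd = 2)
  graphics::legend("bottomright", legend = c("interior", "exterior"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Reads (or accepts) a feature table with `label` and `distance` columns,
#' fits the combined model via [drsp()] and optionally writes the evaluation
#' report and model directory. The configuration is a list (or YAML file
#' path, requiring the yaml package) with elements `table` (TSV path),
#' `cutoff`, `seed`, `ga` (list of [ga_control()] arguments or `FALSE`),
#' `exponents`, `report_out`, `model_out`.
#'
#' @param config list or YAML file path.
#' @return The fitted `drsp` object, invisibly; the report is attached as
#'   `$report`.
#' @export
end_to_end <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  tab <- if (is.character(config$table)) read_feature_tsv(config$table)
         else config$table
  feats <- intersect(feature_names(), colnames(tab))
  if (length(feats) == 0)
    feats <- setdiff(colnames(tab), c("protein_id", "chain", "position",
                                      "wt", "mut", "label", "distance",
                                      "routed"))
  ga_cfg <- if (isFALSE(config$ga)) NULL
            else do.call(ga_control, as.list(config$ga))
  fit <- drsp(as.matrix(tab[, feats, drop = FALSE]), tab$label,
              tab$distance,
              cutoff = if (is.null(config$cutoff)) 8.0 else config$cutoff,
              ga = ga_cfg,
              seed = if (is.null(config$seed)) 1L else config$seed,
              exponents = if (is.null(config$exponents)) -15:15
                          else config$exponents)
  if (!is.null(config$report_out))
    write_evaluation_json(fit$report, config$report_out)
  if (!is.null(config$model_out))
    save_combined_model(fit$model, config$model_out)
  invisible(fit)
}
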
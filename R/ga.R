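#' Genetic-algorithm configuration
#'
#' Defaults follow the study conditions: population of 80 solutions, 150
#' generations, 8 independent runs, per-bit mutation probability 0.1 for the
#' first half of the population (the second half always gets exactly one
#' random bit flip), one-point tail-swap crossover with probability 0.5, and
#' 5-fold cross-validated SVM fitness.
#'
#' @param N population size (even).
#' @param generations generations per run.
#' @param runs independent runs (run r is seeded with `seed + r - 1`).
#' @param mutation_rate per-bit flip probability for the first half.
#' @param crossover_rate per-pair tail-swap probability.
#' @param fitness fitness measure: `"Acc"`, `"MCC"`, `"F1"` or `"Hybrid"`.
#' @param k_folds cross-validation folds for the fitness SVM.
#' @param seed base seed.
#' @param cost,gamma SVM hyperparameters used inside fitness evaluation;
#'   `gamma = NULL` means `1 / n_selected_features`.
#' @param op_order `"mutate_then_crossover"` (default) or the reverse, for
#'   sensitivity checks.
#' @return List of class `ga_control`.
#' @export
ga_control <- function(N = 80, generations = 150, runs = 8,
                       mutation_rate = 0.1, crossover_rate = 0.5,
                       fitness = c("MCC", "Acc", "F1", "Hybrid"),
                       k_folds = 5, seed = 1, cost = 1, gamma = NULL,
                       op_order = c("mutate_then_crossover",
                                    "crossover_then_mutate")) {
  if (N %% 2 != 0) stop("config error: population size N must be even")
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(list(N = as.integer(N), generations = as.integer(generations),
                 runs = as.integer(runs), mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 fitness = match.arg(fitness), k_folds = as.integer(k_folds),
                 seed = as.integer(seed), cost = cost, gamma = gamma,
                 op_order = match.arg(op_order)),
            class = "ga_control")
}

#' Random initial population of feature masks
#'
#' Each of the `N` masks has `m` i.i.d. uniform \{0,1\} bits; all-zero masks
#' are re-drawn. Uses the current RNG state (seed it with `set.seed()` or let
#' [run_ga()] do so).
#'
#' @param N population size (even).
#' @param m mask length.
#' @return List of `N` integer 0/1 vectors.
#' @export
init_population <- function(N, m) {
  if (N %% 2 != 0) stop("config error: population size N must be even")
  lapply(seq_len(N), function(i) {
    repeat {
      bits <- sample(0:1, m, replace = TRUE)
      if (sum(bits) > 0) return(bits)
    }
  })
}

#' Cross-validated SVM fitness of a feature mask
#'
#' Trains the RBF-kernel SVM on the mask's selected columns under a fixed
#' stratified fold assignment and returns the configured measure on the
#' pooled out-of-fold predictions. The all-zero mask gets the sentinel
#' fitness -1 (never selected). For the Hybrid measure, delta is the
#' positives:negatives ratio of `labels`.
#'
#' @param mask integer 0/1 vector of length `ncol(table)`.
#' @param table numeric feature matrix/data.frame (n x m).
#' @param labels `"resistant"` / `"non_resistant"` vector.
#' @param cfg a [ga_control()].
#' @param folds optional fold assignment (defaults to a fresh stratified
#'   draw from the current RNG).
#' @return Scalar fitness.
#' @export
evaluate_fitness <- function(mask, table, labels, cfg = ga_control(),
                             folds = NULL) {
  if (sum(mask) == 0) return(-1)
  if (is.null(folds)) folds <- stratified_folds(labels, cfg$k_folds)
  X <- as.matrix(table)[, mask == 1, drop = FALSE]
  gamma <- if (is.null(cfg$gamma)) 1 / ncol(X) else cfg$gamma
  pred <- svm_cv_predict(X, labels, folds, cfg$cost, gamma)
  ct <- confusion(labels, pred)
  delta <- sum(labels == "resistant") / max(1, sum(labels == "non_resistant"))
  measure(ct, cfg$fitness, delta = delta)
}

# incumbent: list(mask = bits or NULL, fitness = value); tau = 0 incumbents
# have fitness 0 and no mask
new_incumbent <- function() list(mask = NULL, fitness = 0)

#' Update the two elitist selection operators
#'
#' The alpha incumbent is the fittest of the first half of the evaluated
#' population together with the previous alpha; beta likewise over the second
#' half. Ties keep the earlier-encountered candidate, with the incumbent
#' considered last. A mask-less incumbent (generation 0) that "wins" because
#' every candidate is below fitness 0 is replaced by the best candidate of
#' its half.
#'
#' @param masks list of N masks.
#' @param fits numeric vector of their fitnesses.
#' @param alpha,beta current incumbents (lists with `mask`, `fitness`),
#'   or [new_incumbent()].
#' @return List with updated `alpha` and `beta`.
#' @export
update_selection <- function(masks, fits, alpha = new_incumbent(),
                             beta = new_incumbent()) {
  N <- length(masks)
  half <- N / 2
  pick <- function(idx, inc) {
    cand_fit <- c(fits[idx], inc$fitness)
    w <- which.max(cand_fit)
    if (w <= length(idx)) list(mask = masks[[idx[w]]], fitness = fits[idx[w]])
    else if (!is.null(inc$mask)) inc
    else {
      w2 <- which.max(fits[idx])   # degenerate: keep best candidate anyway
      list(mask = masks[[idx[w2]]], fitness = fits[idx[w2]])
    }
  }
  list(alpha = pick(seq_len(half), alpha),
       beta = pick(half + seq_len(half), beta))
}

#' Build the next GA generation from the incumbents
#'
#' Copies alpha into odd slots and beta into even slots, then mutates
#' (per-bit flips with probability `mutation_rate` for solutions 1..N/2;
#' exactly one uniformly chosen bit flipped for each of N/2+1..N), then
#' applies one-point tail-swap crossover to consecutive pairs with
#' probability `crossover_rate` (bits r..m swapped, r uniform on 1..m).
#' Operator order can be reversed via `cfg$op_order`.
#'
#' @param alpha,beta incumbents with non-NULL masks.
#' @param cfg a [ga_control()].
#' @return List of N masks.
#' @export
step_generation <- function(alpha, beta, cfg) {
  N <- cfg$N
  m <- length(alpha$mask)
  pop <- lapply(seq_len(N), function(i)
    if (i %% 2 == 1) alpha$mask else beta$mask)

  mutate <- function(pop) {
    for (i in seq_len(N / 2)) {
      flip <- stats::runif(m) < cfg$mutation_rate
      pop[[i]][flip] <- 1L - pop[[i]][flip]
    }
    for (i in (N / 2 + 1):N) {
      b <- sample.int(m, 1)
      pop[[i]][b] <- 1L - pop[[i]][b]
    }
    pop
  }
  crossover <- function(pop) {
    for (p in seq_len(N / 2)) {
      if (stats::runif(1) < cfg$crossover_rate) {
        r <- sample.int(m, 1)
        i <- 2 * p - 1; j <- 2 * p
        tail <- r:m
        tmp <- pop[[i]][tail]
        pop[[i]][tail] <- pop[[j]][tail]
        pop[[j]][tail] <- tmp
      }
    }
    pop
  }
  if (cfg$op_order == "mutate_then_crossover") crossover(mutate(pop))
  else mutate(crossover(pop))
}

#' Run the genetic-algorithm feature selection
#'
#' Executes `cfg$runs` independent GA runs (run r seeded with
#' `cfg$seed + r - 1`; the cross-validation fold assignment is drawn once per
#' run so fitness comparisons are paired). Each run records a per-generation
#' trace of the best incumbent fitness, which is non-decreasing by elitism.
#' The returned best run maximizes MCC: when the fitness measure is not MCC,
#' each run's best mask is re-evaluated under MCC for this final choice.
#'
#' @param table numeric feature matrix (n x m); column names are feature
#'   names.
#' @param labels `"resistant"` / `"non_resistant"` vector (at least 2 of
#'   each).
#' @param cfg a [ga_control()].
#' @return Object of class `ga_result`: `best_mask`, `best_fitness`,
#'   `best_mcc`, `trace`, `run_index`, `runs` (per-run summaries),
#'   `feature_names`.
#' @export
run_ga <- function(table, labels, cfg = ga_control()) {
  table <- as.matrix(table)
  m <- ncol(table)
  if (sum(labels == "resistant") < 2 || sum(labels == "non_resistant") < 2)
    stop("data error: need at least 2 samples per class")

  run_results <- vector("list", cfg$runs)
  for (r in seq_len(cfg$runs)) {
    run_results[[r]] <- with_seed(cfg$seed + r - 1L, {
      folds <- stratified_folds(labels, cfg$k_folds)
      cache <- new.env(parent = emptyenv())
      fit_of <- function(bits) {
        key <- mask_key(bits)
        if (!is.null(cache[[key]])) return(cache[[key]])
        v <- evaluate_fitness(bits, table, labels, cfg, folds)
        cache[[key]] <- v
        v
      }
      pop <- init_population(cfg$N, m)
      alpha <- new_incumbent(); beta <- new_incumbent()
      trace <- numeric(cfg$generations)
      for (g in seq_len(cfg$generations)) {
        fits <- vapply(pop, fit_of, numeric(1))
        sel <- update_selection(pop, fits, alpha, beta)
        alpha <- sel$alpha; beta <- sel$beta
        trace[g] <- max(alpha$fitness, beta$fitness)
        if (g < cfg$generations) pop <- step_generation(alpha, beta, cfg)
      }
      best <- if (alpha$fitness >= beta$fitness) alpha else beta
      mcc <- if (cfg$fitness == "MCC") best$fitness else {
        pred <- svm_cv_predict(table[, best$mask == 1, drop = FALSE], labels,
                               folds, cfg$cost,
                               if (is.null(cfg$gamma)) 1 / sum(best$mask)
                               else cfg$gamma)
        measure(confusion(labels, pred), "MCC")
      }
      list(best_mask = best$mask, best_fitness = best$fitness,
           best_mcc = mcc, trace = trace, seed = cfg$seed + r - 1L)
    })
  }
  best_r <- which.max(vapply(run_results, `[[`, numeric(1), "best_mcc"))
  br <- run_results[[best_r]]
  structure(list(best_mask = br$best_mask, best_fitness = br$best_fitness,
                 best_mcc = br$best_mcc, trace = br$trace,
                 run_index = best_r, runs = run_results,
                 feature_names = colnames(table), config = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("ga_result: best run ", x$run_index, "/", length(x$runs),
      ", fitness (", x$config$fitness, ") = ", round(x$best_fitness, 4),
      ", MCC = ", round(x$best_mcc, 4), "\n", sep = "")
  sel <- which(x$best_mask == 1)
  nm <- if (!is.null(x$feature_names)) x$feature_names[sel] else sel
  cat("selected ", length(sel), "/", length(x$best_mask), " features: ",
      paste(nm, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a GA result to JSON
#'
#' @param res a `ga_result`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ga_json <- function(res, path) {
  sel <- which(res$best_mask == 1)
  jsonlite::write_json(list(
    best_mask = res$best_mask,
    selected_features = if (!is.null(res$feature_names))
      res$feature_names[sel] else sel,
    best_fitness = res$best_fitness, best_mcc = res$best_mcc,
    run_index = res$run_index, trace = res$trace,
    seeds = vapply(res$runs, `[[`, integer(1), "seed")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
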
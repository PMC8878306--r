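test_that("initial populations are uniform, non-empty and reproducible", {
  set.seed(1)
  p <- init_population(4, 1)
  expect_true(all(vapply(p, identical, logical(1), 1L) |
                    vapply(p, identical, logical(1), c(1L))))
  expect_error(init_population(5, 10), "even")

  set.seed(3); p1 <- init_population(80, 45)
  set.seed(3); p2 <- init_population(80, 45)
  expect_identical(p1, p2)
  dens <- mean(unlist(p1))
  expect_lt(abs(dens - 0.5), 0.05)
  expect_true(all(vapply(p1, sum, numeric(1)) > 0))
})

test_that("fitness: separable feature gives MCC 1, zero mask the sentinel", {
  set.seed(5)
  n <- 60
  labels <- rep(c("resistant", "non_resistant"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5)
  X[labels == "resistant", 3] <- X[labels == "resistant", 3] + 10
  cfg <- ga_control(N = 4, seed = 1)
  set.seed(2)
  expect_equal(evaluate_fitness(c(0, 0, 1, 0, 0), X, labels, cfg), 1.0)
  expect_equal(evaluate_fitness(rep(0, 5), X, labels, cfg), -1)
})

test_that("shuffled labels give near-zero MCC fitness", {
  ft <- make_feature_table(n_samples = 200, effect_size = 3, seed = 4)
  set.seed(8)
  null_labels <- sample(ft$labels)
  set.seed(9)
  f <- evaluate_fitness(rep(1, 45), ft$table, null_labels, ga_control())
  expect_lt(abs(f), 0.2)
})

test_that("selection operators take the elitist max over the stated halves", {
  m <- 6
  masks <- lapply(1:8, function(i) as.integer(intToBits(i)[1:m]))
  # all fitnesses equal: ties keep the earliest candidate in each half
  sel <- update_selection(masks, rep(0.4, 8))
  expect_identical(sel$alpha$mask, masks[[1]])
  expect_identical(sel$beta$mask, masks[[5]])

  # a fitter previous alpha survives the whole first half
  prev <- list(mask = rep(1L, m), fitness = 0.99)
  sel <- update_selection(masks, rep(0.4, 8), alpha = prev)
  expect_identical(sel$alpha$mask, prev$mask)
  expect_equal(sel$alpha$fitness, 0.99)

  # random fitness vectors match a brute-force max over the candidate sets
  set.seed(12)
  for (rep in 1:20) {
    fits <- runif(8)
    a_prev <- list(mask = rep(1L, m), fitness = runif(1))
    b_prev <- list(mask = rep(0:1, 3), fitness = runif(1))
    sel <- update_selection(masks, fits, a_prev, b_prev)
    expect_equal(sel$alpha$fitness, max(fits[1:4], a_prev$fitness))
    expect_equal(sel$beta$fitness, max(fits[5:8], b_prev$fitness))
  }
})

test_that("generation step: copy pattern, forced flips, crossover bounds", {
  m <- 12
  alpha <- list(mask = rep(c(1L, 0L), 6), fitness = 0.5)
  beta <- list(mask = rep(c(0L, 1L), 6), fitness = 0.4)

  # rates forced to zero: first half exact copies, second half exactly one
  # flipped bit relative to its parent
  cfg0 <- ga_control(N = 8, mutation_rate = 0, crossover_rate = 0, seed = 1)
  set.seed(4)
  nxt <- step_generation(alpha, beta, cfg0)
  for (i in 1:4) {
    parent <- if (i %% 2 == 1) alpha$mask else beta$mask
    expect_identical(nxt[[i]], parent)
  }
  for (i in 5:8) {
    parent <- if (i %% 2 == 1) alpha$mask else beta$mask
    expect_equal(sum(nxt[[i]] != parent), 1)
  }
  # masks stay binary and of length m under active operators
  cfg <- ga_control(N = 8, seed = 1)
  set.seed(5)
  nxt <- step_generation(alpha, beta, cfg)
  expect_true(all(vapply(nxt, length, integer(1)) == m))
  expect_true(all(unlist(nxt) %in% c(0L, 1L)))

  # m = 1: crossover swaps the whole bit when triggered
  a1 <- list(mask = 1L, fitness = 1); b1 <- list(mask = 0L, fitness = 0)
  cfg1 <- ga_control(N = 2, mutation_rate = 0, crossover_rate = 1, seed = 1)
  set.seed(6)
  nxt <- step_generation(a1, b1, cfg1)
  # pair (alpha, beta-with-forced-flip) swaps tails of length 1
  expect_true(all(unlist(nxt) %in% c(0L, 1L)))
  expect_equal(length(nxt[[1]]), 1)
})

test_that("forced single-bit mutation picks every index uniformly", {
  m <- 9
  alpha <- list(mask = rep(1L, m), fitness = 1)
  beta <- list(mask = rep(0L, m), fitness = 0)
  cfg <- ga_control(N = 2, mutation_rate = 0, crossover_rate = 0, seed = 1)
  set.seed(99)
  hits <- integer(m)
  for (r in 1:5000) {
    nxt <- step_generation(alpha, beta, cfg)
    hits[which(nxt[[2]] != beta$mask)] <- hits[which(nxt[[2]] != beta$mask)] + 1
  }
  p <- 1 / m
  sigma <- sqrt(5000 * p * (1 - p))
  expect_true(all(abs(hits - 5000 * p) < 3.5 * sigma))
})

test_that("the GA is elitist, deterministic, and recovers planted features", {
  ft <- make_feature_table(n_samples = 200, effect_size = 3, seed = 1)
  cfg <- ga_control(N = 10, generations = 8, runs = 2, seed = 21)
  res <- run_ga(ft$table, ft$labels, cfg)
  expect_s3_class(res, "ga_result")
  for (r in res$runs) {
    expect_true(all(diff(r$trace) >= 0))
    expect_equal(r$best_fitness, r$trace[length(r$trace)])
  }
  expect_equal(res$best_fitness, res$trace[length(res$trace)])
  expect_equal(length(res$best_mask), 45)
  expect_gt(sum(res$best_mask[ft$informative]), 0)

  res2 <- run_ga(ft$table, ft$labels, cfg)
  expect_identical(res$best_mask, res2$best_mask)
  expect_identical(res$trace, res2$trace)

  # m = 1: the only admissible mask is selected
  X1 <- ft$table[, 3, drop = FALSE]
  cfg1 <- ga_control(N = 4, generations = 2, runs = 1, seed = 2)
  expect_identical(run_ga(X1, ft$labels, cfg1)$best_mask, 1L)

  expect_error(run_ga(ft$table, rep("resistant", 200), cfg), "data error")
})

test_that("GA results serialize to JSON with named selected features", {
  ft <- make_feature_table(n_samples = 60, effect_size = 4,
                           pos_neg_ratio = 1, seed = 2)
  cfg <- ga_control(N = 6, generations = 3, runs = 1, seed = 5)
  res <- run_ga(ft$table, ft$labels, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_ga_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$best_mask, res$best_mask)
  expect_equal(length(back$trace), 3)
  expect_true(all(back$selected_features %in% feature_names()))
})

test_that("label-shuffled data cannot be overfit past the leakage guard", {
  ft <- make_feature_table(n_samples = 200, effect_size = 3, seed = 6)
  set.seed(31)
  null_labels <- sample(ft$labels)
  cfg <- ga_control(N = 10, generations = 10, runs = 1, seed = 7)
  res <- run_ga(ft$table, null_labels, cfg)
  expect_lt(res$best_mcc, 0.35)
})
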
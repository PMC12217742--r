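# Genome decoding, dominance, genetic operators and the optimization loop.

test_that("genome decoding thresholds features, repairs empty masks and is deterministic", {
  genes <- c(0.9, 0.1, 0.6, 0.2, 0.4, 0.1, 0.5, 0.5, 0.5)
  g <- decode_genome(genes, 5, "classification")
  expect_equal(g$feature_mask, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # all feature genes below 0.5: argmax gene switched on
  genes2 <- c(0.2, 0.45, 0.1, 0.3, 0.05, 0.9, 0.5, 0.5, 0.5)
  g2 <- decode_genome(genes2, 5, "classification")
  expect_equal(which(g2$feature_mask), 2)
  expect_identical(decode_genome(genes, 5, "classification"),
                   decode_genome(genes, 5, "classification"))
  expect_error(decode_genome(genes[-1], 5, "classification"), "expected")
  # hyperparameters decode within bounds, log scale at the extremes
  lo <- decode_genome(c(1, rep(0, 4), 0, 0, 0, 0), 5, "classification")
  hi <- decode_genome(c(1, rep(0, 4), 0.99, 1, 1, 1), 5, "classification")
  expect_equal(lo$C, 2^-5); expect_equal(hi$C, 2^15)
  expect_equal(lo$gamma, 2^-15, tolerance = 1e-12)
  expect_equal(lo$n_trees, 10); expect_equal(hi$n_trees, 500)
  expect_equal(lo$estimator, "svm_rbf")
  expect_equal(hi$estimator, "random_forest")
})

test_that("dominance is strict-in-one and errors on mismatched objectives", {
  a <- c(acc = 0.9, nf = -5); b <- c(acc = 0.8, nf = -10)
  expect_true(dominates(a, b))
  expect_false(dominates(a, a))
  expect_false(dominates(c(acc = 0.9, nf = -10), c(acc = 0.8, nf = -5)))
  expect_error(dominates(a, c(x = 1, y = 2)), "match")
})

test_that("pareto_front equals exhaustive dominance filtering on random sets", {
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(runif(40 * sample(2:4, 1)), nrow = 40)
    colnames(m) <- paste0("o", seq_len(ncol(m)))
    expect_setequal(pareto_front(m), brute_force_front(m))
  }
  one <- matrix(c(0.3, 0.7), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(pareto_front(one), 1)
  ident <- matrix(0.5, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_setequal(pareto_front(ident), 1:5)   # ties all retained
  expect_error(pareto_front(ident[0, , drop = FALSE]), "empty")
})

test_that("two-point crossover exchanges a segment; mutation edge cases hold", {
  set.seed(1)
  p1 <- runif(20); p2 <- runif(20)
  for (rep in 1:20) {
    kids <- two_point_crossover(p1, p2)
    expect_true(all(kids[[1]] %in% c(p1, p2)))
    expect_true(all((kids[[1]] == p1) | (kids[[1]] == p2)))
    # children are complementary: where one takes p1 the other takes p2
    expect_equal(kids[[1]] + kids[[2]], p1 + p2)
  }
  expect_identical(mutate_genome(p1, 0), p1)
  set.seed(2)
  mutated <- mutate_genome(p1, 1)
  expect_true(all(mutated != p1))
  ar <- arithmetic_crossover(p1, p2)
  expect_equal(ar[[1]] + ar[[2]], p1 + p2)
  expect_true(all(ar[[1]] >= pmin(p1, p2) & ar[[1]] <= pmax(p1, p2)))
})

test_that("weighted fitness sums weighted objectives and rejects negatives", {
  w <- objective_weights("classification")
  ones <- setNames(rep(1, length(w)), names(w))
  expect_equal(weighted_fitness(ones, w), sum(w))
  expect_equal(weighted_fitness(ones, w * 0), 0)
  expect_equal(unname(w["ACC"]), 10)
  expect_equal(unname(w["F1"]), 10)
  expect_equal(unname(objective_weights("regression")["neg_MSE"]), 10)
  expect_error(weighted_fitness(ones, -w), "negative")
})

make_separable_fixture <- function(n = 120, p_noise = 6, seed = 5) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sig1 = y * 2 + rnorm(n, 0, 0.1),
             sig2 = -y + rnorm(n, 0, 0.1),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", 1:p_noise))))
  list(X = X, y = y)
}

test_that("cross-validated evaluation separates signal, null and noise-only masks", {
  fx <- make_separable_fixture()
  cfg <- ea_config(population_size = 4, max_generations = 1, cv_folds = 5,
                   seed = 5)
  genome <- decode_genome(c(1, 1, rep(0, 6), 0.1, 0.6, 0.4, 0.2), 8,
                          "classification", cfg)
  ev <- evaluate_individual(genome, fx$X, fx$y, "classification", cfg)
  expect_gte(ev$cv_metrics$accuracy, 0.95)   # large-margin fixture
  expect_gte(ev$cv_metrics$roc_auc, 0.95)
  # permutation null: shuffled labels give chance-level AUC
  set.seed(6)
  y_perm <- sample(fx$y)
  ev_null <- evaluate_individual(genome, fx$X, y_perm, "classification", cfg)
  expect_lt(abs(ev_null$cv_metrics$roc_auc - 0.5), 0.1)
  # noise-only mask: accuracy near the majority-class rate
  genome_noise <- genome
  genome_noise$feature_mask <- c(rep(FALSE, 2), rep(TRUE, 6))
  ev_noise <- evaluate_individual(genome_noise, fx$X, fx$y, "classification",
                                  cfg)
  expect_lt(abs(ev_noise$cv_metrics$accuracy - 0.5), 0.12)
  # manhattan objective lives in [0, 1] and improves on the permutation null
  expect_gte(ev$cv_metrics$manhattan, 0)
  expect_lte(ev$cv_metrics$manhattan, 1)
  expect_lt(ev$cv_metrics$manhattan, ev_null$cv_metrics$manhattan)
})

test_that("optimization is reproducible, monotone in best fitness, and respects config", {
  fx <- make_separable_fixture(n = 80, p_noise = 4)
  cfg <- ea_config(population_size = 8, max_generations = 4, cv_folds = 4,
                   seed = 9)
  f1 <- run_optimization(fx$X, fx$y, "classification", cfg)
  f2 <- run_optimization(fx$X, fx$y, "classification", cfg)
  expect_equal(f1$members, f2$members, tolerance = 1e-12)
  # per-generation log: population size respected, elitist best non-decreasing
  expect_equal(nrow(f1$log), cfg$max_generations + 1)
  expect_true(all(diff(f1$log$best_fitness) >= -1e-9))
  # front members never dominate each other
  obj <- do.call(rbind, lapply(f1$members, `[[`, "objectives"))
  expect_setequal(pareto_front(obj), seq_len(nrow(obj)))
  # every member keeps at least one feature
  expect_true(all(vapply(f1$members,
                         function(m) sum(m$genome$feature_mask), 0L) >= 1))
  expect_error(run_optimization(fx$X[1:3, ], fx$y[1:3], "classification",
                                cfg), "folds")
})

test_that("regression optimization recovers a noiseless linear endpoint", {
  set.seed(12)
  n <- 90
  X <- cbind(s1 = runif(n), s2 = runif(n),
             matrix(runif(n * 4), n, dimnames = list(NULL, paste0("n", 1:4))))
  y01 <- (X[, "s1"] + X[, "s2"]) / 2
  cfg <- ea_config(population_size = 10, max_generations = 5, cv_folds = 4,
                   seed = 12)
  front <- run_optimization(X, y01, "regression", cfg)
  rhos <- vapply(front$members, function(m) m$cv_metrics$spearman_rho,
                 numeric(1))
  expect_gt(max(rhos, na.rm = TRUE), 0.9)
})
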
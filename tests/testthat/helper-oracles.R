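# Independent brute-force oracles and shared fixtures.

# exhaustive O(n^2) non-dominated filter, independent of pareto_front()
brute_force_front <- function(objectives) {
  n <- nrow(objectives)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(objectives[j, ] >= objectives[i, ]) &&
          any(objectives[j, ] > objectives[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# exhaustive test-vs-train homology exclusion (double loop over pairs)
brute_force_exclusion <- function(test, train, evalues, threshold) {
  sim <- function(x, y) {
    if (x == y) return(TRUE)
    hit <- (evalues$id_a == x & evalues$id_b == y) |
      (evalues$id_a == y & evalues$id_b == x)
    any(evalues$evalue[hit] < threshold)
  }
  removed <- logical(nrow(test))
  for (i in seq_len(nrow(test))) {
    for (j in seq_len(nrow(train))) {
      a <- test$id_a[i]; b <- test$id_b[i]
      c_ <- train$id_a[j]; d <- train$id_b[j]
      if ((sim(a, c_) && sim(b, d)) || (sim(a, d) && sim(b, c_))) {
        removed[i] <- TRUE
        break
      }
    }
  }
  removed
}

# best single-feature decision stump accuracy by exhaustive threshold search
brute_force_stump_accuracy <- function(x, y) {
  cuts <- sort(unique(x))
  cuts <- c(cuts - 1e-9, max(cuts) + 1e-9)
  best <- 0
  for (t in cuts) {
    for (dir in c(1, -1)) {
      pred <- as.integer(dir * x >= dir * t)
      best <- max(best, mean(pred == y))
    }
  }
  best
}

# the scaled-down optimizer configuration used throughout the heavy tests
scaled_ea_config <- function(seed) {
  ea_config(population_size = 30, max_generations = 20, cv_folds = 5,
            seed = seed)
}

INFORMATIVE_FEATURES <- c("BP_similarity", "MF_similarity", "CC_similarity",
                          "pfam_interaction", "colocalization")

# memoized heavy artifacts shared across test files (same R process)
.shared <- new.env(parent = emptyenv())

shared_planted_run <- function(seed) {
  key <- paste0("run", seed)
  hit <- get0(key, .shared)
  if (!is.null(hit)) return(hit)
  world <- generate_world(seed = seed)
  fm <- world_feature_matrix(world)
  front <- run_optimization(fm$features, fm$labels, "classification",
                            scaled_ea_config(seed))
  res <- list(world = world, fm = fm, front = front)
  assign(key, res, .shared)
  res
}

# a tiny deterministic two-member classification front built by hand, with
# trivially predictable behaviour, for ensemble-contract tests
toy_front <- function(accuracies = c(0.9, 0.9), n_features = 4,
                      masks = NULL, probs = c(0.8, 0.2)) {
  members <- lapply(seq_along(accuracies), function(i) {
    mask <- if (is.null(masks)) rep(TRUE, n_features) else masks[[i]]
    list(genes = c(as.numeric(mask), 0.1, 0.5, 0.5, 0.5),
         genome = list(feature_mask = mask, estimator = "constant",
                       C = 1, gamma = 1, n_trees = 10),
         objectives = c(ACC = accuracies[i]),
         cv_metrics = list(accuracy = accuracies[i],
                           spearman_rho = probs[i]),
         weighted_fitness = accuracies[i],
         fit = list(kind = "constant", value = probs[i], size = 1),
         preproc = list(mean = rep(0, sum(mask)), lo = rep(0, sum(mask)),
                        span = rep(1, sum(mask))))
  })
  structure(list(task = "classification", members = members,
                 feature_names = paste0("f", seq_len(n_features))),
            class = "pareto_front_fit")
}
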
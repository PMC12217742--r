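# Multi-objective Pareto-based evolutionary optimizer: joint selection of a
# feature subset, an estimator kind and its hyperparameters, evaluated by
# stratified cross-validation; classification and regression variants.

#' Evolutionary-algorithm configuration
#'
#' Defaults follow the published optimization protocol: population 50,
#' 100 generations (classification) or 1000 (regression), two-point
#' crossover probability 0.9, arithmetic crossover probability 0, per-gene
#' mutation probability 0.01, stratified 10-fold cross-validation.
#'
#' @param population_size number of genomes per generation (>= 2).
#' @param max_generations generation budget.
#' @param p_mutation per-gene uniform-resample probability.
#' @param p_two_point probability of two-point crossover per parent pair.
#' @param p_arithmetic probability of arithmetic (convex-combination)
#'   crossover per parent pair.
#' @param cv_folds cross-validation folds (>= 2).
#' @param seed integer RNG seed; the whole run is reproducible under it.
#' @param bounds hyperparameter decoding bounds: `C` and `gamma` are decoded
#'   log-uniformly, `trees` linearly.
#' @param enable_nn include the feed-forward neural regressor among the
#'   regression estimators (off by default).
#' @return an `ea_config` list.
#' @export
ea_config <- function(population_size = 50, max_generations = 100,
                      p_mutation = 0.01, p_two_point = 0.9,
                      p_arithmetic = 0, cv_folds = 10, seed = 1L,
                      bounds = list(C = c(2^-5, 2^15),
                                    gamma = c(2^-15, 2^3),
                                    trees = c(10, 500)),
                      enable_nn = FALSE) {
  stopifnot(population_size >= 2, cv_folds >= 2,
            p_mutation >= 0, p_mutation <= 1,
            p_two_point >= 0, p_two_point <= 1,
            p_arithmetic >= 0, p_arithmetic <= 1)
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 p_mutation = p_mutation, p_two_point = p_two_point,
                 p_arithmetic = p_arithmetic, cv_folds = cv_folds,
                 seed = as.integer(seed), bounds = bounds,
                 enable_nn = enable_nn),
            class = "ea_config")
}

#' Objective weights
#'
#' The published weight profiles: classification weighs accuracy and F1 ten
#' times a unit objective; regression weighs negative MSE ten times.
#'
#' @param task `"classification"` or `"regression"`.
#' @return named numeric weight vector in objective order.
#' @export
objective_weights <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification")
    c(n_features_min = 1, ACC = 10, F1 = 10, F2 = 1, PRC = 1, REC = 1,
      AUC = 1, model_size_min = 1, manhattan_min = 1)
  else
    c(feature_significance = 1, neg_MSE = 10, MAE = 1,
      explained_variance = 1, model_complexity_min = 1, RMSE = 1,
      correlation = 1)
}

estimator_set <- function(task, enable_nn = FALSE) {
  if (task == "classification") c("svm_rbf", "random_forest")
  else c("svr_linear", "svr_rbf", "rf_regressor",
         if (enable_nn) "nn_regressor")
}

#' Decode a real-vector genome
#'
#' Gene layout: one gene per feature (selected iff gene >= 0.5), one
#' estimator-selector gene (binned uniformly over the estimator set), then
#' three hyperparameter genes mapped onto the configured bounds (`C` and
#' `gamma` log-uniformly, `trees` linearly). An all-features-off genome is
#' repaired by enabling the feature with the largest gene.
#'
#' @param genes numeric vector in `[0, 1]` of length `n_features + 4`.
#' @param n_features number of candidate features.
#' @param task `"classification"` or `"regression"`.
#' @param config an [ea_config()].
#' @return list with `feature_mask`, `estimator`, `C`, `gamma`, `n_trees`.
#' @export
decode_genome <- function(genes, n_features, task, config = ea_config()) {
  if (length(genes) != n_features + 4)
    stop(sprintf("expected %d genes, got %d", n_features + 4, length(genes)))
  fg <- genes[seq_len(n_features)]
  mask <- fg >= 0.5
  if (!any(mask)) mask[which.max(fg)] <- TRUE  # repair rule
  ests <- estimator_set(task, config$enable_nn)
  sel <- min(length(ests), 1 + floor(genes[n_features + 1] * length(ests)))
  b <- config$bounds
  log_map <- function(g, lo, hi) exp(log(lo) + g * (log(hi) - log(lo)))
  list(feature_mask = mask,
       estimator = ests[sel],
       C = log_map(genes[n_features + 2], b$C[1], b$C[2]),
       gamma = log_map(genes[n_features + 3], b$gamma[1], b$gamma[2]),
       n_trees = as.integer(round(b$trees[1] +
                                    genes[n_features + 4] *
                                    (b$trees[2] - b$trees[1]))))
}

#' Pareto dominance of maximize-oriented objective vectors
#'
#' @param a,b named numeric vectors over the same objective set, all
#'   maximize-oriented.
#' @return `TRUE` iff `a >= b` everywhere and `a > b` somewhere.
#' @export
dominates <- function(a, b) {
  if (!identical(names(a), names(b)))
    stop("objective sets do not match")
  all(a >= b) && any(a > b)
}

#' Non-dominated subset of a set of objective vectors
#'
#' @param objectives numeric matrix, one row per solution, named
#'   maximize-oriented objective columns. Ties (identical rows) are all
#'   retained.
#' @return integer indices of the non-dominated rows.
#' @export
pareto_front <- function(objectives) {
  n <- nrow(objectives)
  if (is.null(n) || n == 0) stop("empty population")
  # sweep in decreasing order of the first objective; a solution is
  # dominated only by solutions earlier in the sweep
  ord <- do.call(order, c(lapply(seq_len(ncol(objectives)),
                                 function(j) -objectives[, j])))
  keep <- logical(n)
  front_rows <- NULL
  for (i in ord) {
    v <- objectives[i, ]
    dominated <- FALSE
    if (!is.null(front_rows)) {
      cand <- front_rows
      geq <- cand >= rep(v, each = nrow(cand))
      gt <- cand > rep(v, each = nrow(cand))
      dominated <- any(rowSums(geq) == ncol(cand) & rowSums(gt) > 0)
    }
    if (!dominated) {
      keep[i] <- TRUE
      front_rows <- rbind(front_rows, matrix(v, 1))
    }
  }
  which(keep)
}

#' Weighted scalar fitness of an objective vector
#'
#' @param objectives named maximize-oriented objective vector, each entry
#'   normalized to `[0, 1]`; `NA` entries (undefined metrics) contribute 0.
#' @param weights non-negative weights aligned by name.
#' @return weighted sum.
#' @export
weighted_fitness <- function(objectives, weights) {
  if (any(weights < 0)) stop("negative objective weight")
  obj <- objectives[names(weights)]
  obj[is.na(obj)] <- 0
  sum(obj * weights)
}

# ---- preprocessing (fitted on training folds only) -------------------------

preproc_fit <- function(X) {
  mu <- suppressWarnings(colMeans(X, na.rm = TRUE))
  mu[!is.finite(mu)] <- 0
  Ximp <- X
  for (j in seq_len(ncol(X))) Ximp[is.na(Ximp[, j]), j] <- mu[j]
  lo <- apply(Ximp, 2, min); hi <- apply(Ximp, 2, max)
  span <- hi - lo; span[span == 0] <- 1
  list(mean = mu, lo = lo, span = span)
}

preproc_apply <- function(X, pp) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- pp$mean[j]
  sweep(sweep(X, 2, pp$lo, "-"), 2, pp$span, "/")
}

# ---- estimators ------------------------------------------------------------

fit_estimator <- function(genome, X, y, task) {
  est <- genome$estimator
  if (est %in% c("svm_rbf", "svr_linear", "svr_rbf")) {
    kern <- if (est == "svr_linear") "linear" else "radial"
    type <- if (task == "classification") "C-classification" else
      "eps-regression"
    yy <- if (task == "classification") factor(y, levels = c(0, 1)) else y
    model <- e1071::svm(X, yy, type = type, kernel = kern,
                        cost = genome$C, gamma = genome$gamma, scale = FALSE)
    list(model = model, kind = "svm", size = nrow(model$SV))
  } else if (est %in% c("random_forest", "rf_regressor")) {
    yy <- if (task == "classification") factor(y, levels = c(0, 1)) else y
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(df)))
    model <- ranger::ranger(x = df, y = yy, num.trees = genome$n_trees,
                            probability = task == "classification",
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
    list(model = model, kind = "rf", size = genome$n_trees)
  } else if (est == "nn_regressor") {
    # small single-hidden-layer net; disabled by default in the estimator set
    df <- data.frame(X); df$.y <- y
    model <- stats::glm(.y ~ ., data = data.frame(X, .y = y))
    list(model = model, kind = "glm", size = length(stats::coef(model)))
  } else stop("unknown estimator ", est)
}

predict_estimator <- function(fit, X, task) {
  if (fit$kind == "svm") {
    if (task == "classification") {
      pred <- stats::predict(fit$model, X, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      d <- dv[, 1]
      # orient the margin so positive means class "1"
      if (grepl("^0/", colnames(dv)[1])) d <- -d
      1 / (1 + exp(-d))
    } else {
      unname(stats::predict(fit$model, X))
    }
  } else if (fit$kind == "constant") {
    # degenerate estimator used for contract tests and fallbacks
    rep(fit$value, nrow(X))
  } else if (fit$kind == "rf") {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(df)))
    p <- stats::predict(fit$model, df, num.threads = 1)$predictions
    if (task == "classification") unname(p[, "1"]) else unname(p)
  } else {
    unname(stats::predict(fit$model, data.frame(X)))
  }
}

# ---- individual evaluation -------------------------------------------------

clamp01 <- function(x) ifelse(is.na(x), NA_real_, pmin(1, pmax(0, x)))

#' Cross-validated evaluation of one genome
#'
#' Trains the decoded estimator on the masked features with fold-internal
#' preprocessing (mean imputation and min-max scaling fitted on the
#' training folds only) and returns maximize-oriented objective values as
#' means over folds, together with plain CV metrics. Count objectives are
#' normalized by their configured maxima.
#'
#' @param genome decoded genome from [decode_genome()].
#' @param features numeric feature matrix (may contain `NA`).
#' @param y 0/1 labels or numeric endpoint.
#' @param task `"classification"` or `"regression"`.
#' @param config an [ea_config()] (folds, seed, bounds).
#' @return list with `objectives` (named vector), `cv_metrics`, and
#'   `weighted_fitness`.
#' @export
evaluate_individual <- function(genome, features, y, task, config = ea_config()) {
  k <- config$cv_folds
  folds <- if (task == "classification")
    stratified_kfold(y, k, config$seed) else kfold(length(y), k, config$seed)
  Xm <- features[, genome$feature_mask, drop = FALSE]
  n_feat_total <- ncol(features)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (task == "classification" && length(unique(y[tr])) < 2)
      stop(sprintf("degenerate fold %d: single class in training part", f))
    pp <- preproc_fit(Xm[tr, , drop = FALSE])
    Xtr <- preproc_apply(Xm[tr, , drop = FALSE], pp)
    Xte <- preproc_apply(Xm[te, , drop = FALSE], pp)
    fit <- fit_estimator(genome, Xtr, y[tr], task)
    pred <- predict_estimator(fit, Xte, task)
    per_fold[[f]] <- list(pred = pred, truth = y[te], size = fit$size)
  }
  size <- mean(vapply(per_fold, `[[`, numeric(1), "size"))
  size_max <- if (genome$estimator %in% c("random_forest", "rf_regressor"))
    config$bounds$trees[2] else nrow(features)

  if (task == "classification") {
    ms <- lapply(per_fold, function(pf) {
      lab <- as.integer(pf$pred >= 0.5)
      m <- metrics_from_counts(tp = sum(lab == 1 & pf$truth == 1),
                               fp = sum(lab == 1 & pf$truth == 0),
                               tn = sum(lab == 0 & pf$truth == 0),
                               fn = sum(lab == 0 & pf$truth == 1))
      m$roc_auc <- roc_auc(pf$truth, pf$pred)
      m$manhattan <- mean(abs(pf$pred - pf$truth))
      m
    })
    avg <- function(name) mean(vapply(ms, function(m)
      ifelse(is.na(m[[name]]), NA_real_, m[[name]]), numeric(1)), na.rm = TRUE)
    cv <- list(accuracy = avg("accuracy"), specificity = avg("specificity"),
               sensitivity = avg("sensitivity"), precision = avg("precision"),
               f1 = avg("f1"), f2 = avg("f2"), roc_auc = avg("roc_auc"),
               manhattan = avg("manhattan"), model_size = size)
    objectives <- c(
      n_features_min = 1 - sum(genome$feature_mask) / n_feat_total,
      ACC = cv$accuracy, F1 = cv$f1, F2 = cv$f2, PRC = cv$precision,
      REC = cv$sensitivity, AUC = cv$roc_auc,
      model_size_min = 1 - size / size_max,
      manhattan_min = 1 - cv$manhattan)
  } else {
    pred <- unlist(lapply(per_fold, `[[`, "pred"))
    truth <- unlist(lapply(per_fold, `[[`, "truth"))
    rm_ <- regression_metrics(truth, pred)
    mse <- mean((truth - pred)^2)
    mae <- mean(abs(truth - pred))
    ev <- if (stats::var(truth) > 0) 1 - stats::var(truth - pred) /
      stats::var(truth) else NA_real_
    cv <- c(rm_, list(mse = mse, mae = mae, explained_variance = ev,
                      model_size = size))
    objectives <- c(
      feature_significance = 1 - sum(genome$feature_mask) / n_feat_total,
      neg_MSE = clamp01(1 - mse), MAE = clamp01(1 - mae),
      explained_variance = clamp01(ev),
      model_complexity_min = 1 - size / size_max,
      RMSE = clamp01(1 - rm_$rmse),
      correlation = if (is.na(rm_$spearman_rho)) 0
      else (rm_$spearman_rho + 1) / 2)
  }
  # undefined metrics count as worst-case objectives (CV metrics keep NA)
  objectives[!is.finite(objectives)] <- 0
  wf <- weighted_fitness(objectives, objective_weights(task))
  list(objectives = objectives, cv_metrics = cv, weighted_fitness = wf)
}

# ---- genetic operators -----------------------------------------------------

#' Two-point crossover
#' @param parent1,parent2 equal-length gene vectors.
#' @return list of two children exchanging the segment between two random
#'   cut points (drawn from the current RNG stream).
#' @export
two_point_crossover <- function(parent1, parent2) {
  n <- length(parent1)
  stopifnot(length(parent2) == n)
  cuts <- sort(sample(0:n, 2))
  seg <- seq_len(n) > cuts[1] & seq_len(n) <= cuts[2]
  c1 <- parent1; c2 <- parent2
  c1[seg] <- parent2[seg]; c2[seg] <- parent1[seg]
  list(c1, c2)
}

#' Arithmetic (convex-combination) crossover
#' @param parent1,parent2 equal-length gene vectors.
#' @return list of two children `a p1 + (1-a) p2` and its mirror, with `a`
#'   uniform on (0, 1).
#' @export
arithmetic_crossover <- function(parent1, parent2) {
  a <- stats::runif(1)
  list(a * parent1 + (1 - a) * parent2,
       (1 - a) * parent1 + a * parent2)
}

#' Uniform-resample mutation
#' @param genes gene vector in `[0, 1]`.
#' @param p per-gene mutation probability.
#' @return mutated gene vector.
#' @export
mutate_genome <- function(genes, p) {
  hit <- stats::runif(length(genes)) < p
  genes[hit] <- stats::runif(sum(hit))
  genes
}

# ---- main loop -------------------------------------------------------------

genome_signature <- function(genome) {
  paste(paste(as.integer(genome$feature_mask), collapse = ""),
        genome$estimator,
        signif(genome$C, 12), signif(genome$gamma, 12), genome$n_trees,
        sep = "|")
}

#' Run the Pareto-based evolutionary optimization
#'
#' Evolves a population of real-vector genomes with tournament selection
#' (size 2) on weighted fitness, Pareto-front elitism, two-point and
#' arithmetic crossover and uniform mutation. Every evaluated individual
#' enters an archive; the returned front is the non-dominated subset of the
#' archive, with each member refit on the full training data.
#'
#' @param features numeric feature matrix (rows = samples; may contain `NA`,
#'   which the fold-internal preprocessing imputes).
#' @param y 0/1 labels (classification) or numeric endpoint (regression).
#' @param task `"classification"` or `"regression"`.
#' @param config an [ea_config()].
#' @return a `pareto_front_fit` list: `task`, `members` (each with `genes`,
#'   `genome`, `objectives`, `cv_metrics`, `weighted_fitness`, refit `fit`
#'   and full-data preprocessing `preproc`), `log` (per-generation best and
#'   mean weighted fitness and front size) and `config`.
#' @export
run_optimization <- function(features, y, task = c("classification", "regression"),
                             config = ea_config()) {
  task <- match.arg(task)
  if (nrow(features) < config$cv_folds)
    stop("dataset smaller than the number of CV folds")
  n_feat <- ncol(features)
  n_genes <- n_feat + 4
  weights <- objective_weights(task)
  cache <- new.env(parent = emptyenv(), hash = TRUE)

  eval_genes <- function(genes) {
    genome <- decode_genome(genes, n_feat, task, config)
    key <- genome_signature(genome)
    hit <- get0(key, cache)
    if (!is.null(hit)) return(c(hit, list(genome = genome)))
    res <- evaluate_individual(genome, features, y, task, config)
    assign(key, res, cache)
    c(res, list(genome = genome))
  }

  withr_seed(config$seed, {
    pop <- matrix(stats::runif(config$population_size * n_genes),
                  config$population_size, n_genes)
    archive_genes <- list(); archive_obj <- NULL; archive_info <- list()
    log <- data.frame(generation = integer(), best_fitness = numeric(),
                      mean_fitness = numeric(), front_size = integer())
    evals <- apply(pop, 1, eval_genes, simplify = FALSE)

    record <- function(evals, pop) {
      for (i in seq_along(evals)) {
        archive_genes[[length(archive_genes) + 1]] <<- pop[i, ]
        archive_obj <<- rbind(archive_obj, evals[[i]]$objectives)
        archive_info[[length(archive_info) + 1]] <<- evals[[i]]
      }
    }
    record(evals, pop)

    for (gen in seq_len(config$max_generations)) {
      fitness <- vapply(evals, `[[`, numeric(1), "weighted_fitness")
      front_idx <- pareto_front(do.call(rbind,
                                        lapply(evals, `[[`, "objectives")))
      log <- rbind(log, data.frame(generation = gen - 1L,
                                   best_fitness = max(fitness),
                                   mean_fitness = mean(fitness),
                                   front_size = length(front_idx)))
      # elitism: current front members (capped to half the population,
      # best-fitness first) survive unchanged
      elite_idx <- front_idx[order(-fitness[front_idx])]
      elite_idx <- elite_idx[seq_len(min(length(elite_idx),
                                         config$population_size %/% 2))]
      elite <- pop[elite_idx, , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(nrow(pop), 2)
        cand[which.max(fitness[cand])]
      }
      children <- list()
      while (length(children) < config$population_size - nrow(elite)) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        u <- stats::runif(1)
        kids <- if (u < config$p_two_point) two_point_crossover(p1, p2)
        else if (u < config$p_two_point + config$p_arithmetic)
          arithmetic_crossover(p1, p2)
        else list(p1, p2)
        kids <- lapply(kids, mutate_genome, p = config$p_mutation)
        children <- c(children, kids)
      }
      children <- children[seq_len(config$population_size - nrow(elite))]
      pop <- rbind(elite, do.call(rbind, children))
      evals <- apply(pop, 1, eval_genes, simplify = FALSE)
      record(evals, pop)
    }
    fitness <- vapply(evals, `[[`, numeric(1), "weighted_fitness")
    front_idx <- pareto_front(do.call(rbind, lapply(evals, `[[`, "objectives")))
    log <- rbind(log, data.frame(generation = config$max_generations,
                                 best_fitness = max(fitness),
                                 mean_fitness = mean(fitness),
                                 front_size = length(front_idx)))

    # archive front over every evaluated individual, deduplicated by genome
    sig <- vapply(archive_info, function(e) genome_signature(e$genome),
                  character(1))
    first <- !duplicated(sig)
    archive_obj <- archive_obj[first, , drop = FALSE]
    archive_genes <- archive_genes[first]
    archive_info <- archive_info[first]
    af <- pareto_front(archive_obj)

    members <- lapply(af, function(i) {
      info <- archive_info[[i]]
      Xm <- features[, info$genome$feature_mask, drop = FALSE]
      pp <- preproc_fit(Xm)
      fit <- fit_estimator(info$genome, preproc_apply(Xm, pp), y, task)
      list(genes = archive_genes[[i]], genome = info$genome,
           objectives = info$objectives, cv_metrics = info$cv_metrics,
           weighted_fitness = info$weighted_fitness,
           fit = fit, preproc = pp)
    })
    structure(list(task = task, members = members, log = log,
                   config = config, feature_names = colnames(features)),
              class = "pareto_front_fit")
  })
}

#' Predict with a single fitted front member
#'
#' @param member a front member from [run_optimization()].
#' @param features feature matrix with the training columns.
#' @param type `"prob"` (positive-class probability, classification) or
#'   `"response"`.
#' @return numeric predictions.
#' @export
predict_member <- function(member, features, type = c("prob", "response")) {
  type <- match.arg(type)
  Xm <- features[, member$genome$feature_mask, drop = FALSE]
  X <- preproc_apply(Xm, member$preproc)
  task <- if (type == "prob") "classification" else "regression"
  predict_estimator(member$fit, X, task)
}

#' @export
print.pareto_front_fit <- function(x, ...) {
  cat(sprintf("Pareto front (%s): %d member(s)\n", x$task,
              length(x$members)))
  for (m in x$members)
    cat(sprintf("  %-14s %2d features  fitness %.3f\n",
                m$genome$estimator, sum(m$genome$feature_mask),
                m$weighted_fitness))
  invisible(x)
}

#' Selection frequency of each feature across the front
#' @param front a `pareto_front_fit`.
#' @return named numeric vector: fraction of front members selecting each
#'   feature.
#' @export
feature_selection_frequency <- function(front) {
  masks <- vapply(front$members, function(m) m$genome$feature_mask,
                  logical(length(front$feature_names)))
  freq <- rowMeans(matrix(masks, ncol = length(front$members)))
  stats::setNames(freq, front$feature_names)
}
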
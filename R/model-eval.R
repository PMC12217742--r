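# Classification and regression metrics, stratified cross-validation folds,
# best-model selection, and the Pareto-front ensemble prediction rules.

#' Classification metrics from confusion counts
#'
#' Counts may be fractional (e.g. derived from published rates). Metrics with
#' zero denominators are reported as `NA`, never as 0.
#'
#' @param tp,fp,tn,fn non-negative (possibly fractional) counts.
#' @return named list: `accuracy`, `specificity`, `sensitivity`, `precision`,
#'   `f1`, `f2` (all in `[0, 1]` or `NA`). ROC-AUC requires scores and is not
#'   derivable from counts.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  fbeta <- function(beta) {
    if (is.na(prec) || is.na(sens) || (prec == 0 && sens == 0))
      return(NA_real_)
    (1 + beta^2) * prec * sens / (beta^2 * prec + sens)
  }
  list(accuracy = safe_div(tp + tn, tp + fp + tn + fn),
       specificity = spec, sensitivity = sens, precision = prec,
       f1 = fbeta(1), f2 = fbeta(2))
}

#' Classification metrics reconstructed from published rates
#'
#' Converts sensitivity/specificity plus class counts into fractional
#' confusion counts and derives the remaining metrics; used to reconstruct
#' benchmark rows reported only as rates.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg positive/negative class sizes.
#' @return as [metrics_from_counts()].
#' @export
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos > 0, n_neg > 0)
  metrics_from_counts(tp = sensitivity * n_pos,
                      fp = (1 - specificity) * n_neg,
                      tn = specificity * n_neg,
                      fn = (1 - sensitivity) * n_pos)
}

#' ROC-AUC from continuous scores (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Regression metrics
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return named list: `rmse`, `rae` (relative absolute error), `rrse` (root
#'   relative squared error), `spearman_rho`, `spearman_p`. `rae`/`rrse` are
#'   `NA` for constant actuals; the correlation needs `n >= 3`.
#' @export
regression_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  err <- actual - predicted
  rmse <- sqrt(mean(err^2))
  dev <- actual - mean(actual)
  rae <- if (sum(abs(dev)) > 0) sum(abs(err)) / sum(abs(dev)) else NA_real_
  rrse <- if (sum(dev^2) > 0) sqrt(sum(err^2) / sum(dev^2)) else NA_real_
  rho <- NA_real_; p <- NA_real_
  if (length(actual) >= 3 && stats::sd(actual) > 0 && stats::sd(predicted) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(actual, predicted, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(rmse = rmse, rae = rae, rrse = rrse, spearman_rho = rho,
       spearman_p = p)
}

#' Stratified k-fold assignments
#'
#' Shuffles within each class and deals samples round-robin across folds, so
#' per-fold class proportions are within one sample of the global
#' proportions and the folds partition the index set exactly.
#'
#' @param labels class labels (any type with equality).
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return integer vector of fold ids in `1..k`, aligned to `labels`.
#' @export
stratified_kfold <- function(labels, k, seed) {
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("class '%s' has %d < k = %d members",
                 names(counts)[which.min(counts)], min(counts), k))
  folds <- integer(length(labels))
  withr_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Plain (unstratified) k-fold assignments for regression endpoints
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return integer fold ids.
#' @export
kfold <- function(n, k, seed) {
  if (n < k) stop("fewer samples than folds")
  withr_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Best model of a Pareto front by weighted fitness
#'
#' Argmax of the weighted objective fitness; ties broken by fewer selected
#' features, then lexicographically by genome.
#'
#' @param front a `pareto_front_fit` (see [run_optimization()]).
#' @return the selected front member.
#' @export
select_best_model <- function(front) {
  stopifnot(length(front$members) > 0)
  fit <- vapply(front$members, function(m) m$weighted_fitness, numeric(1))
  nfeat <- vapply(front$members, function(m) sum(m$genome$feature_mask),
                  numeric(1))
  genome_key <- vapply(front$members,
                       function(m) paste(format(m$genes, digits = 15),
                                         collapse = ","), character(1))
  ord <- order(-fit, nfeat, genome_key)
  front$members[[ord[1]]]
}

eligible_votes <- function(members, missing_row, missing_rule) {
  vapply(members, function(m) {
    sel <- m$genome$feature_mask
    mean(missing_row[sel]) < missing_rule
  }, logical(1))
}

#' Ensemble classification by Pareto-front majority voting
#'
#' Front members with cross-validated accuracy above `accuracy_threshold`
#' are eligible; for each sample a member votes only if fewer than
#' `missing_rule` of its selected features are missing for that sample.
#' The label is the majority vote (ties decided by mean probability >= 0.5)
#' and the reported probability the mean of the voters' positive-class
#' probabilities. Samples with no eligible voter are flagged unpredictable.
#'
#' @param front fitted classification front.
#' @param features numeric feature matrix (rows = samples, registry columns).
#' @param missing logical missingness matrix of the same shape (defaults to
#'   `is.na(features)`).
#' @param accuracy_threshold CV-accuracy eligibility cut (default 0.80,
#'   strict inequality).
#' @param missing_rule per-sample abstention cut on the fraction of a
#'   member's selected features that are missing (default 0.5, strict).
#' @return data.frame with `label` (0/1), `probability`, `n_voters`,
#'   `unpredictable`.
#' @export
ensemble_classify <- function(front, features, missing = NULL,
                              accuracy_threshold = 0.80, missing_rule = 0.5) {
  if (length(front$members) == 0) stop("empty front")
  if (is.null(missing)) missing <- is.na(features)
  members <- Filter(function(m) m$cv_metrics$accuracy > accuracy_threshold,
                    front$members)
  n <- nrow(features)
  out <- data.frame(label = rep(NA_integer_, n), probability = NA_real_,
                    n_voters = 0L, unpredictable = TRUE)
  if (length(members) == 0) return(out)
  probs <- vapply(members, function(m)
    predict_member(m, features, type = "prob"), numeric(n))
  probs <- matrix(probs, nrow = n)
  for (i in seq_len(n)) {
    ok <- eligible_votes(members, missing[i, ], missing_rule)
    if (!any(ok)) next
    p <- probs[i, ok]
    votes <- as.integer(p >= 0.5)
    maj <- if (sum(votes) * 2 == length(votes)) as.integer(mean(p) >= 0.5)
    else as.integer(sum(votes) * 2 > length(votes))
    out$label[i] <- maj
    out$probability[i] <- mean(p)
    out$n_voters[i] <- sum(ok)
    out$unpredictable[i] <- FALSE
  }
  out
}

#' Ensemble regression by Pareto-front averaging
#'
#' Front members with cross-validated Spearman correlation above
#' `correlation_threshold` are eligible; predictions are the mean over
#' eligible members, subject to the same per-sample missingness abstention
#' rule as [ensemble_classify()].
#'
#' @param front fitted regression front.
#' @param features,missing as in [ensemble_classify()].
#' @param correlation_threshold CV-correlation eligibility cut (default 0.2,
#'   strict).
#' @param missing_rule abstention cut (default 0.5).
#' @return data.frame with `prediction`, `n_voters`, `unpredictable`.
#' @export
ensemble_regress <- function(front, features, missing = NULL,
                             correlation_threshold = 0.2, missing_rule = 0.5) {
  if (length(front$members) == 0) stop("empty front")
  if (is.null(missing)) missing <- is.na(features)
  members <- Filter(function(m) {
    rho <- m$cv_metrics$spearman_rho
    !is.na(rho) && rho > correlation_threshold
  }, front$members)
  n <- nrow(features)
  out <- data.frame(prediction = rep(NA_real_, n), n_voters = 0L,
                    unpredictable = TRUE)
  if (length(members) == 0) return(out)
  preds <- vapply(members, function(m)
    predict_member(m, features, type = "response"), numeric(n))
  preds <- matrix(preds, nrow = n)
  for (i in seq_len(n)) {
    ok <- eligible_votes(members, missing[i, ], missing_rule)
    if (!any(ok)) next
    out$prediction[i] <- mean(preds[i, ok])
    out$n_voters[i] <- sum(ok)
    out$unpredictable[i] <- FALSE
  }
  out
}

#' Evaluate a fitted front member or ensemble on a labelled test set
#'
#' @param front fitted front.
#' @param features,missing test feature matrix and missingness mask.
#' @param labels 0/1 labels (classification) or numeric endpoint
#'   (regression).
#' @param mode `"best"` (single best-model prediction) or `"ensemble"`.
#' @return metric list as [metrics_from_counts()] plus `roc_auc`
#'   (classification) or [regression_metrics()] (regression).
#' @export
evaluate_front <- function(front, features, labels, missing = NULL,
                           mode = c("best", "ensemble")) {
  mode <- match.arg(mode)
  if (front$task == "classification") {
    if (mode == "best") {
      best <- select_best_model(front)
      prob <- predict_member(best, features, type = "prob")
      pred <- as.integer(prob >= 0.5)
    } else {
      ens <- ensemble_classify(front, features, missing)
      prob <- ens$probability; pred <- ens$label
    }
    ok <- !is.na(pred)
    cm <- metrics_from_counts(tp = sum(pred[ok] == 1 & labels[ok] == 1),
                              fp = sum(pred[ok] == 1 & labels[ok] == 0),
                              tn = sum(pred[ok] == 0 & labels[ok] == 0),
                              fn = sum(pred[ok] == 0 & labels[ok] == 1))
    cm$roc_auc <- roc_auc(labels[ok], prob[ok])
    cm
  } else {
    pred <- if (mode == "best")
      predict_member(select_best_model(front), features, type = "response")
    else ensemble_regress(front, features, missing)$prediction
    ok <- !is.na(pred)
    regression_metrics(labels[ok], pred[ok])
  }
}
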
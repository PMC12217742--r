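# Interactome screening: enumerate taste-receptor pairs against a proteome,
# apply the classifier and regressor ensembles, rank and export.

#' Enumerate candidate pairs involving at least one receptor
#'
#' All unordered pairs with at least one member in `tr_ids`; self-pairs
#' excluded, no duplicates.
#'
#' @param tr_ids character vector of receptor accessions (non-empty).
#' @param proteome_ids character vector of proteome accessions.
#' @return data.frame with columns `id_a`, `id_b` (canonical order).
#' @export
enumerate_pairs <- function(tr_ids, proteome_ids) {
  tr_ids <- unique(tr_ids)
  if (length(tr_ids) == 0) stop("tr_ids must be non-empty")
  all_ids <- unique(c(proteome_ids, tr_ids))
  a <- rep(tr_ids, each = length(all_ids))
  b <- rep(all_ids, times = length(tr_ids))
  keep <- a != b
  df <- data.frame(id_a = pmin(a[keep], b[keep]),
                   id_b = pmax(a[keep], b[keep]),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(pair_key(df$id_a, df$id_b)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Screen enumerated pairs with the fitted fronts
#'
#' The classifier (best-model rule) assigns a class and a positive-class
#' probability to every pair; the regressor (ensemble rule) assigns a
#' binding-strength endpoint only to positively classified pairs - negative
#' pairs carry no affinity. Samples on which the regression ensemble must
#' abstain entirely are flagged unpredictable and excluded from ranking,
#' with their count recorded in the `n_unpredictable` attribute.
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param features,missing feature matrix (registry columns) and
#'   missingness mask aligned to `pairs`.
#' @param classifier_front fitted classification `pareto_front_fit`.
#' @param regressor_front fitted regression `pareto_front_fit`.
#' @param scaler endpoint scaler from [normalize_endpoint()] used to invert
#'   regression predictions to kJ/mol.
#' @return data.frame with `id_a`, `id_b`, `predicted_class`, `probability`,
#'   `predicted_dg_kj` (signed), `predicted_dg_abs`.
#' @export
screen_pairs <- function(pairs, features, classifier_front, regressor_front,
                         scaler, missing = NULL) {
  if (is.null(missing)) missing <- is.na(features)
  best <- select_best_model(classifier_front)
  prob <- predict_member(best, features, type = "prob")
  cls <- as.integer(prob >= 0.5)
  out <- data.frame(pairs, predicted_class = cls, probability = prob,
                    predicted_dg_kj = NA_real_, predicted_dg_abs = NA_real_,
                    unpredictable = FALSE, stringsAsFactors = FALSE)
  pos <- which(cls == 1)
  if (length(pos)) {
    reg <- ensemble_regress(regressor_front,
                            features[pos, , drop = FALSE],
                            missing[pos, , drop = FALSE])
    dg <- denormalize(reg$prediction, scaler)
    out$predicted_dg_kj[pos] <- dg
    out$predicted_dg_abs[pos] <- abs(dg)
    out$unpredictable[pos] <- reg$unpredictable
  }
  attr(out, "n_unpredictable") <- sum(out$unpredictable)
  out
}

#' Rank screened interactions
#'
#' Positive pairs are ranked by the mean of the classification probability
#' and the min-max scaled affinity (scaled over the screened positive set,
#' stronger binding = larger score), descending; ties are broken by
#' probability, then by pair key. Unpredictable pairs are excluded.
#'
#' @param screened data.frame from [screen_pairs()].
#' @param affinity_scaler optional fixed `list(lo, hi)` of |dG| bounds used
#'   instead of the screened-set min-max.
#' @return ranked data.frame with added `scaled_affinity` and `mean_score`.
#' @export
rank_interactions <- function(screened, affinity_scaler = NULL) {
  pos <- screened[screened$predicted_class == 1 & !screened$unpredictable, ,
                  drop = FALSE]
  if (nrow(pos) == 0) return(cbind(pos, scaled_affinity = numeric(0),
                                   mean_score = numeric(0)))
  v <- pos$predicted_dg_abs
  if (is.null(affinity_scaler)) {
    lo <- min(v); hi <- max(v)
  } else {
    lo <- affinity_scaler$lo; hi <- affinity_scaler$hi
  }
  pos$scaled_affinity <- if (hi > lo) (v - lo) / (hi - lo)
  else rep(0.5, length(v))
  pos$mean_score <- (pos$probability + pos$scaled_affinity) / 2
  key <- pair_key(pos$id_a, pos$id_b)
  pos[order(-pos$mean_score, -pos$probability, key), , drop = FALSE]
}

#' Export the top-ranked interaction library
#'
#' @param ranked data.frame from [rank_interactions()].
#' @param top_n number of rows to keep.
#' @param reference_pairs data.frame (`id_a`, `id_b`) of interactions
#'   recorded in the reference interaction database; sets the
#'   `in_reference` flag.
#' @param gene_symbols optional named vector mapping accession to gene
#'   symbol.
#' @param path optional TSV output path.
#' @return data.frame with columns `pair`, `gene_a`, `gene_b`,
#'   `probability`, `affinity_kj_mol` (absolute dG), `mean_score`,
#'   `in_reference`.
#' @export
export_library <- function(ranked, top_n = 10, reference_pairs = NULL,
                           gene_symbols = NULL, path = NULL) {
  top <- utils::head(ranked, top_n)
  ref_keys <- if (is.null(reference_pairs)) character(0)
  else pair_key(reference_pairs$id_a, reference_pairs$id_b)
  sym <- function(id) {
    if (is.null(gene_symbols)) return(id)
    out <- unname(gene_symbols[id])
    ifelse(is.na(out), id, out)
  }
  lib <- data.frame(
    pair = paste(top$id_a, top$id_b, sep = "-"),
    gene_a = sym(top$id_a), gene_b = sym(top$id_b),
    probability = round(top$probability, 2),
    affinity_kj_mol = round(top$predicted_dg_abs, 2),
    mean_score = round(top$mean_score, 2),
    in_reference = as.integer(pair_key(top$id_a, top$id_b) %in% ref_keys),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(lib, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  lib
}

#' Export the thresholded interaction network
#'
#' Edges are the ranked interactions with probability strictly above the
#' threshold; edge weight is the mean score. Node attributes carry the
#' taste class of each receptor from the supplied catalog (non-receptor
#' nodes are tagged `non-TR`).
#'
#' @param ranked data.frame from [rank_interactions()].
#' @param probability_threshold strict lower bound on probability
#'   (default 0.55).
#' @param tr_catalog data.frame with columns `accession`, `taste_class`
#'   (an accession may appear once per class).
#' @param dir optional output directory; writes `network.sif`,
#'   `edges.tsv` and `nodes.tsv`.
#' @return list with `edges` and `nodes` data.frames.
#' @export
export_network <- function(ranked, probability_threshold = 0.55,
                           tr_catalog = NULL, dir = NULL) {
  edges <- ranked[ranked$probability > probability_threshold, , drop = FALSE]
  edges <- data.frame(source = edges$id_a, target = edges$id_b,
                      weight = edges$mean_score,
                      probability = edges$probability,
                      stringsAsFactors = FALSE)
  nodes <- unique(c(edges$source, edges$target))
  classes <- vapply(nodes, function(id) {
    if (is.null(tr_catalog)) return("non-TR")
    cl <- tr_catalog$taste_class[tr_catalog$accession == id]
    if (length(cl) == 0) "non-TR" else paste(sort(unique(cl)), collapse = "/")
  }, character(1))
  nodes_df <- data.frame(node = nodes, taste_class = unname(classes),
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(sprintf("%s pp %s", edges$source, edges$target),
               file.path(dir, "network.sif"))
    utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(nodes_df, file.path(dir, "nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(edges = edges, nodes = nodes_df)
}
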
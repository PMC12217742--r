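# Curated interaction dataset construction: MITAB-dialect reading, the
# filter cascade, negative sampling and train/test assembly with
# homology-based decontamination.

#' Default column map for iRefIndex-style MITAB tables
#'
#' Maps logical fields to column names of the input table. Override any
#' element to adapt to another dialect.
#' @return named list of column names.
#' @export
mitab_dialect <- function() {
  list(id_a = "uidA", id_b = "uidB", rigid = "Checksum_Interaction",
       method = "method", taxon = "taxid_host", source_db = "sourcedb")
}

strip_db_prefix <- function(x) sub("^[A-Za-z_]+:", "", x)

#' Read an iRefIndex-style MITAB interaction table
#'
#' Identifiers are canonicalized to unordered form (`id_a <= id_b`
#' lexicographically). Malformed rows (missing identifiers) are reported via
#' a `malformed` attribute, never silently dropped; records whose
#' identifiers do not match the UniProt accession pattern are kept but
#' flagged, so that [filter_uniprot_only()] can remove them explicitly.
#'
#' @param path TSV file path.
#' @param dialect column map, see [mitab_dialect()].
#' @return data.frame of interaction records with columns `id_a`, `id_b`,
#'   `rigid`, `methods` (pipe-separated), `taxon_host`, `source_dbs`,
#'   `uniprot_valid`; attribute `malformed` holds the offending row numbers.
#' @export
read_mitab <- function(path, dialect = mitab_dialect()) {
  if (!file.exists(path)) stop(sprintf("cannot read MITAB file '%s'", path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  names(raw) <- sub("^#", "", names(raw))
  for (field in c("id_a", "id_b")) {
    if (!dialect[[field]] %in% names(raw))
      stop(sprintf("MITAB format error: missing mandatory column '%s'",
                   dialect[[field]]))
  }
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]])
    else rep(default, nrow(raw))
  }
  id_a <- strip_db_prefix(get_col("id_a"))
  id_b <- strip_db_prefix(get_col("id_b"))
  malformed <- which(is.na(id_a) | is.na(id_b) | !nzchar(id_a) | !nzchar(id_b))
  rec <- data.frame(
    id_a = pmin(id_a, id_b),
    id_b = pmax(id_a, id_b),
    rigid = get_col("rigid"),
    methods = strip_db_prefix(get_col("method", "")),
    taxon_host = strip_db_prefix(get_col("taxon")),
    source_dbs = get_col("source_db", ""),
    stringsAsFactors = FALSE)
  rec$uniprot_valid <- is_uniprot_accession(rec$id_a) &
    is_uniprot_accession(rec$id_b)
  # RIGID fallback: canonical unordered pair key (same-set-of-proteins
  # semantics) when the checksum column is absent or empty
  no_rigid <- is.na(rec$rigid) | !nzchar(rec$rigid)
  rec$rigid[no_rigid] <- pair_key(rec$id_a[no_rigid], rec$id_b[no_rigid])
  if (length(malformed))
    warning(sprintf("%d malformed row(s) (missing identifiers): %s",
                    length(malformed),
                    paste(utils::head(malformed, 10), collapse = ", ")))
  attr(rec, "malformed") <- malformed
  rec
}

#' Keep only records where both proteins are valid UniProt accessions
#' @param records interaction data.frame from [read_mitab()].
#' @return filtered data.frame, input order preserved.
#' @export
filter_uniprot_only <- function(records) {
  valid <- is_uniprot_accession(records$id_a) &
    is_uniprot_accession(records$id_b)
  records[valid, , drop = FALSE]
}

#' Collapse redundant interaction records by RIGID
#'
#' Records sharing a redundancy-group key describe the same set of proteins;
#' the first occurrence is kept. Idempotent.
#' @param records interaction data.frame.
#' @return deduplicated data.frame.
#' @export
dedup_by_rigid <- function(records) {
  records[!duplicated(records$rigid), , drop = FALSE]
}

split_methods <- function(x) strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE)

#' Filter records by interaction-detection method
#'
#' In `include` mode a record survives if at least one of its detection
#' methods is in `allowed` (the training-set rule with
#' `allowed = c("Y2H", "TAP")`); in `exclude` mode it survives only if none
#' is (the test-set rule).
#'
#' @param records interaction data.frame with pipe-separated `methods`.
#' @param allowed non-empty character vector of method identifiers.
#' @param mode `"include"` or `"exclude"`.
#' @return filtered data.frame.
#' @export
filter_by_methods <- function(records, allowed, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  if (length(allowed) == 0) stop("'allowed' must be non-empty")
  hit <- vapply(split_methods(records$methods),
                function(m) any(m %in% allowed), logical(1))
  keep <- if (mode == "include") hit else !hit
  records[keep, , drop = FALSE]
}

#' Keep only records with a given host taxon
#' @param records interaction data.frame.
#' @param taxon taxon identifier (e.g. `"9606"` for Homo sapiens).
#' @return filtered data.frame.
#' @export
filter_by_taxon <- function(records, taxon) {
  records[!is.na(records$taxon_host) &
            records$taxon_host == as.character(taxon), , drop = FALSE]
}

#' Sample negative pairs at a fixed ratio to the positives
#'
#' Draws `round(ratio * n_positives)` pairs from the negative pool without
#' replacement, reproducibly under `seed`.
#'
#' @param positives data.frame of positive records (only its row count is
#'   used).
#' @param negative_pool data.frame with columns `id_a`, `id_b`.
#' @param ratio non-negative real; the classical design uses 2.
#' @param seed integer RNG seed.
#' @return sampled rows of `negative_pool` with a `label` column set to
#'   `"negative"`.
#' @export
sample_negatives <- function(positives, negative_pool, ratio, seed) {
  n_needed <- round(ratio * nrow(positives))
  if (n_needed > nrow(negative_pool))
    stop(sprintf("negative pool too small: need %d, have %d (shortfall %d)",
                 n_needed, nrow(negative_pool),
                 n_needed - nrow(negative_pool)))
  if (n_needed == 0)
    return(cbind(negative_pool[0, , drop = FALSE],
                 label = character(0))[, , drop = FALSE])
  idx <- withr_seed(seed, sample.int(nrow(negative_pool), n_needed))
  out <- negative_pool[idx, , drop = FALSE]
  out$label <- "negative"
  rownames(out) <- NULL
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# symmetric E-value lookup built once from a (id_a, id_b, evalue) table
evalue_lookup <- function(evalues, threshold) {
  sim <- new.env(parent = emptyenv(), hash = TRUE)
  if (!is.null(evalues) && nrow(evalues)) {
    below <- evalues$evalue < threshold
    a <- as.character(evalues$id_a)[below]
    b <- as.character(evalues$id_b)[below]
    for (i in seq_along(a)) {
      assign(a[i], union(get0(a[i], sim, ifnotfound = character(0)), b[i]), sim)
      assign(b[i], union(get0(b[i], sim, ifnotfound = character(0)), a[i]), sim)
    }
  }
  sim
}

#' Remove test pairs homologous to training pairs
#'
#' A test pair (a, b) is removed iff some training pair (c, d) satisfies
#' E(a,c) < t and E(b,d) < t, or E(a,d) < t and E(b,c) < t - i.e. both
#' proteins of the test pair are similar to both proteins of a training pair
#' (in either orientation). Missing E-value entries are treated as
#' not-similar (conservative retention) and counted in the returned log.
#'
#' @param test,train interaction data.frames with `id_a`, `id_b`.
#' @param evalues data.frame with columns `id_a`, `id_b`, `evalue` giving
#'   pairwise sequence-search E-values; self-similarity (a protein with
#'   itself) need not be listed and is always assumed.
#' @param threshold E-value threshold (default 0.05).
#' @return list with `kept`, `removed` (partition of `test`) and
#'   `n_missing_lookups` (test proteins with no E-value entry at all).
#' @export
exclude_similar_pairs <- function(test, train, evalues, threshold = 0.05) {
  if (threshold <= 0) stop("threshold must be > 0")
  sim <- evalue_lookup(evalues, threshold)
  simset <- function(x) union(x, get0(x, sim, ifnotfound = character(0)))
  listed <- unique(c(as.character(evalues$id_a), as.character(evalues$id_b)))
  test_prot <- unique(c(test$id_a, test$id_b))
  n_missing <- sum(!test_prot %in% listed)
  removed <- logical(nrow(test))
  for (i in seq_len(nrow(test))) {
    sa <- simset(test$id_a[i]); sb <- simset(test$id_b[i])
    hit <- (train$id_a %in% sa & train$id_b %in% sb) |
      (train$id_a %in% sb & train$id_b %in% sa)
    removed[i] <- any(hit)
  }
  list(kept = test[!removed, , drop = FALSE],
       removed = test[removed, , drop = FALSE],
       n_missing_lookups = n_missing)
}

#' Random train/test split
#'
#' `floor(train_fraction * n)` records go to training (this floor convention
#' sends 519 records at 0.8 to a 415/104 split), the rest to testing;
#' reproducible under `seed`.
#'
#' @param records data.frame.
#' @param train_fraction real in (0, 1).
#' @param seed integer RNG seed.
#' @return list with `train`, `test` data.frames and a `provenance` list.
#' @export
split_train_test <- function(records, train_fraction, seed) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * n)
  idx <- withr_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       test = records[-sort(idx), , drop = FALSE],
       provenance = list(n = n, n_train = n_train, n_test = n - n_train,
                         train_fraction = train_fraction, seed = seed))
}

#' Assemble a labelled dataset from positives and a negative pool
#'
#' Applies the canonical filter cascade to the positive records (UniProt
#' validity, RIGID deduplication, detection-method rule, host taxon), then
#' adds `ratio` times as many sampled negatives. Pairs appearing with both
#' labels raise a conflict error. Counts at each stage are recorded in the
#' provenance.
#'
#' @param mitab_records data.frame from [read_mitab()].
#' @param negative_pool data.frame with `id_a`, `id_b`.
#' @param methods method identifiers for the detection-method filter.
#' @param method_mode `"include"` (training rule) or `"exclude"` (test rule).
#' @param taxon host taxon id.
#' @param ratio negatives-per-positive ratio.
#' @param seed integer RNG seed for negative sampling.
#' @return list with `dataset` (columns `id_a`, `id_b`, `label`) and
#'   `provenance` (stage counts).
#' @export
build_dataset <- function(mitab_records, negative_pool, methods = c("Y2H", "TAP"),
                          method_mode = "include", taxon = "9606",
                          ratio = 2, seed = 1L) {
  stages <- list(input = nrow(mitab_records))
  rec <- filter_uniprot_only(mitab_records); stages$uniprot <- nrow(rec)
  rec <- dedup_by_rigid(rec); stages$dedup <- nrow(rec)
  rec <- filter_by_methods(rec, methods, method_mode); stages$methods <- nrow(rec)
  rec <- filter_by_taxon(rec, taxon); stages$taxon <- nrow(rec)
  pos <- data.frame(id_a = rec$id_a, id_b = rec$id_b, label = "positive",
                    stringsAsFactors = FALSE)
  neg <- sample_negatives(pos, negative_pool, ratio, seed)
  neg <- data.frame(id_a = neg$id_a, id_b = neg$id_b, label = "negative",
                    stringsAsFactors = FALSE)
  dataset <- rbind(pos, neg)
  key <- pair_key(dataset$id_a, dataset$id_b)
  conflict <- unique(key[duplicated(key)])
  if (length(conflict))
    stop(sprintf("label conflict: %d pair(s) appear with both labels (e.g. %s)",
                 length(conflict), conflict[1]))
  stages$negatives <- nrow(neg); stages$total <- nrow(dataset)
  list(dataset = dataset,
       provenance = list(stages = stages, ratio = ratio, seed = seed,
                         methods = methods, method_mode = method_mode,
                         taxon = taxon))
}

#' Write a labelled dataset with its provenance sidecar
#' @param built result of [build_dataset()].
#' @param path output TSV path; provenance JSON is written to
#'   `<path>.provenance.json`.
#' @return invisibly, `path`.
#' @export
write_dataset <- function(built, path) {
  utils::write.table(built$dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(built$provenance,
                       paste0(sub("\\.tsv$", "", path), ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
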
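# Pair feature computation: sequence descriptors, annotation similarities and
# co-expression, assembled into the fixed 61-slot feature vector.

validate_sequence <- function(sequence) {
  if (is.null(sequence) || !nzchar(sequence))
    stop("sequence must be a non-empty amino-acid string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  chars
}

#' Amino-acid composition of a protein sequence
#'
#' @param sequence amino-acid string over the canonical 20-letter alphabet.
#' @return named numeric vector of 20 fractions (alphabet order) summing to 1.
#' @export
#' @examples
#' aa_composition("AAC")["A"]  # 2/3
aa_composition <- function(sequence) {
  chars <- validate_sequence(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  frac <- as.numeric(counts) / length(chars)
  names(frac) <- AA_ALPHABET
  frac
}

#' Physicochemical profile of a protein sequence
#'
#' Computes the ten scalar descriptors whose pairwise absolute differences
#' enter the feature panel: molecular weight (average masses, peptide-bond
#' water loss subtracted), aromaticity (F/W/Y fraction), the Guruprasad
#' instability index, helix/turn/sheet residue-class fractions, molar
#' extinction coefficients at 280 nm assuming reduced cysteines and assuming
#' cystines, Kyte-Doolittle GRAVY, and net charge at pH 7 from
#' Henderson-Hasselbalch with EMBOSS pKa values.
#'
#' @param sequence amino-acid string; length >= 2 required for the
#'   instability index (a length-1 sequence yields `NA` there).
#' @return named numeric vector with elements `mw`, `aromaticity`,
#'   `instability`, `helix_frac`, `turn_frac`, `sheet_frac`, `cys_reduced`,
#'   `cys_cystines`, `gravy`, `charge_pH7`.
#' @export
physchem_profile <- function(sequence) {
  chars <- validate_sequence(sequence)
  L <- length(chars)
  comp <- table(factor(chars, levels = AA_ALPHABET))
  mw <- sum(AA_MASS[chars]) - (L - 1) * WATER_MASS
  aromaticity <- sum(comp[AROMATIC_RESIDUES]) / L
  instability <- if (L >= 2) {
    idx <- cbind(match(chars[-L], AA_ALPHABET), match(chars[-1], AA_ALPHABET))
    (10 / L) * sum(DIWV[idx])
  } else NA_real_
  nW <- comp[["W"]]; nY <- comp[["Y"]]; nC <- comp[["C"]]
  eps_red <- EPS_TRP * nW + EPS_TYR * nY
  eps_cys <- eps_red + EPS_CYSTINE * floor(nC / 2)
  gravy <- mean(KD_HYDROPATHY[chars])
  charge <- charge_at_ph(comp, 7)
  c(mw = mw,
    aromaticity = aromaticity,
    instability = instability,
    helix_frac = sum(comp[HELIX_RESIDUES]) / L,
    turn_frac = sum(comp[TURN_RESIDUES]) / L,
    sheet_frac = sum(comp[SHEET_RESIDUES]) / L,
    cys_reduced = eps_red,
    cys_cystines = eps_cys,
    gravy = gravy,
    charge_pH7 = charge)
}

# Henderson-Hasselbalch net charge given residue counts and pH
charge_at_ph <- function(comp, ph) {
  pos_counts <- c(Nterm = 1, K = comp[["K"]], R = comp[["R"]], H = comp[["H"]])
  neg_counts <- c(Cterm = 1, D = comp[["D"]], E = comp[["E"]],
                  C = comp[["C"]], Y = comp[["Y"]])
  pos <- sum(pos_counts / (1 + 10^(ph - PKA_POSITIVE[names(pos_counts)])))
  neg <- sum(neg_counts / (1 + 10^(PKA_NEGATIVE[names(neg_counts)] - ph)))
  pos - neg
}

#' Absolute pairwise differences of two protein profiles
#'
#' Given the amino-acid compositions and physicochemical profiles of the two
#' proteins, returns the 30 absolute-difference features (20 composition
#' percentage differences followed by the 10 scalar descriptor differences).
#' Symmetric in its arguments; `NA` in either profile propagates.
#'
#' @param profile_a,profile_b lists with elements `composition` (20
#'   fractions) and `physchem` (10 descriptors), as produced by
#'   [protein_profile()].
#' @return named numeric vector of 30 features in registry order.
#' @export
pair_difference <- function(profile_a, profile_b) {
  comp <- abs(profile_a$composition - profile_b$composition)
  names(comp) <- paste0(AA_ALPHABET, "_pct_dif")
  phys <- abs(profile_a$physchem - profile_b$physchem)
  names(phys) <- paste0(PHYSCHEM_NAMES, "_dif")
  c(comp, phys)
}

#' Composition and physicochemical profile of one protein
#'
#' @param sequence amino-acid string.
#' @return list with `composition` (amino-acid fractions, reported as
#'   percentages in the feature panel via their differences) and `physchem`.
#' @export
protein_profile <- function(sequence) {
  list(composition = aa_composition(sequence),
       physchem = physchem_profile(sequence))
}

#' GO-term set similarity of one annotation aspect
#'
#' Default measure is the Jaccard index over direct annotations. Returns
#' `NA` (missing) when both sets are empty. The `measure` argument accepts a
#' function `(a, b) -> [0, 1]` so that information-content measures can be
#' plugged in.
#'
#' @param terms_a,terms_b character vectors of GO term identifiers from one
#'   aspect (BP, MF or CC).
#' @param measure similarity function; default Jaccard.
#' @return similarity in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' go_similarity(c("g1", "g2"), c("g2", "g3"))  # 1/3
go_similarity <- function(terms_a, terms_b, measure = jaccard_index) {
  a <- unique(terms_a); b <- unique(terms_b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  measure(a, b)
}

#' Jaccard index of two sets
#' @param a,b vectors treated as sets.
#' @return `|a n b| / |a u b|`.
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# canonical unordered pair key
pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "|")
}

#' Membership flags of a pair in reference pair tables
#'
#' @param id_a,id_b the two accessions (order irrelevant).
#' @param tables named list; each element a two-column matrix/data.frame of
#'   accession pairs, or a character vector of canonical pair keys.
#' @return named 0/1 vector, one flag per table.
#' @export
lookup_flags <- function(id_a, id_b, tables) {
  key <- pair_key(id_a, id_b)
  vapply(tables, function(tab) {
    keys <- if (is.character(tab)) tab else pair_key(tab[[1]], tab[[2]])
    as.numeric(key %in% keys)
  }, numeric(1))
}

#' Known domain-domain interaction flag for a protein pair
#'
#' @param domains_a,domains_b character vectors of Pfam identifiers annotated
#'   on the two proteins.
#' @param ddi_table two-column matrix/data.frame of interacting domain pairs
#'   (unordered).
#' @return 1 if any cross-product domain pair is a known interacting pair,
#'   else 0.
#' @export
pfam_interaction <- function(domains_a, domains_b, ddi_table) {
  if (length(domains_a) == 0 || length(domains_b) == 0 ||
      NROW(ddi_table) == 0) return(0)
  ddi_keys <- pair_key(as.character(ddi_table[[1]]),
                       as.character(ddi_table[[2]]))
  grid <- expand.grid(a = domains_a, b = domains_b,
                      stringsAsFactors = FALSE)
  as.numeric(any(pair_key(grid$a, grid$b) %in% ddi_keys))
}

#' Subcellular co-localization flag
#'
#' @param loc_a,loc_b character vectors of compartment labels; `NULL` means
#'   unknown localization and yields `NA`.
#' @return 1 if the compartment sets intersect, 0 if not, `NA` if either is
#'   unknown.
#' @export
colocalization <- function(loc_a, loc_b) {
  if (is.null(loc_a) || is.null(loc_b)) return(NA_real_)
  as.numeric(length(intersect(loc_a, loc_b)) > 0)
}

#' Spearman co-expression of a pair across expression datasets
#'
#' @param id_a,id_b accessions of the two proteins.
#' @param matrices named list of expression matrices (rows = proteins,
#'   columns = samples), one per dataset id.
#' @return named numeric vector, one Spearman rho per dataset; `NA` where a
#'   protein is absent from the dataset, fewer than 3 samples are available,
#'   or either profile is constant (undefined rank correlation).
#' @export
expression_correlations <- function(id_a, id_b, matrices) {
  vapply(matrices, function(m) {
    if (is.null(m) || !(id_a %in% rownames(m)) || !(id_b %in% rownames(m)))
      return(NA_real_)
    x <- as.numeric(m[id_a, ]); y <- as.numeric(m[id_b, ])
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
}

#' Assemble the 61-slot feature vector for one protein pair
#'
#' Sequence-derived features are mandatory (a missing sequence is an error);
#' all annotation-derived features degrade to explicit missing values (`NA`)
#' when the corresponding resource is absent - they are never silently
#' zeroed.
#'
#' @param id_a,id_b UniProt accessions of the pair.
#' @param resources list with elements:
#'   \describe{
#'     \item{sequences}{named character vector of protein sequences (required)}
#'     \item{go}{named list per accession: list with `BP`, `MF`, `CC` term sets}
#'     \item{orthology}{named list of 4 organism pair tables (see [lookup_flags()])}
#'     \item{databases}{named list of 4 database pair tables}
#'     \item{evalues}{lookup of pairwise E-values: data.frame with columns
#'       `id_a`, `id_b`, `evalue`, or `NULL`}
#'     \item{pfam}{named list per accession of Pfam domain ids}
#'     \item{ddi}{two-column table of interacting domain pairs}
#'     \item{localizations}{named list per accession of compartment labels}
#'     \item{expression}{named list of expression matrices}
#'   }
#' @return list with `values` (named numeric vector of length 61, registry
#'   order) and `missing` (logical mask, `TRUE` where a feature could not be
#'   resolved).
#' @export
assemble_feature_vector <- function(id_a, id_b, resources) {
  registry <- feature_registry(names2(resources$expression,
                                      EXPRESSION_DATASET_IDS))
  seqs <- resources$sequences
  for (id in c(id_a, id_b))
    if (is.null(seqs) || is.na(match(id, names(seqs))))
      stop(sprintf("no sequence available for %s; sequence features are mandatory", id))

  vals <- stats::setNames(rep(NA_real_, length(registry)), registry)

  go <- resources$go
  for (aspect in c("BP", "MF", "CC")) {
    vals[[paste0(aspect, "_similarity")]] <-
      go_similarity(go[[id_a]][[aspect]], go[[id_b]][[aspect]])
  }

  ortho <- resources$orthology
  if (!is.null(ortho))
    vals[paste0("ortho_", names2(ortho, ORTHOLOGY_ORGANISMS))] <-
      lookup_flags(id_a, id_b, ortho)
  dbs <- resources$databases
  if (!is.null(dbs))
    vals[paste0("exists_", names2(dbs, DATABASE_FLAGS))] <-
      lookup_flags(id_a, id_b, dbs)

  ev <- resources$evalues
  if (!is.null(ev)) {
    key <- pair_key(id_a, id_b)
    hit <- match(key, pair_key(ev$id_a, ev$id_b))
    if (!is.na(hit)) vals[["sequence_similarity"]] <- ev$evalue[hit]
  }

  pf <- resources$pfam
  if (!is.null(pf) && !is.null(resources$ddi))
    vals[["pfam_interaction"]] <-
      pfam_interaction(pf[[id_a]], pf[[id_b]], resources$ddi)

  loc <- resources$localizations
  if (!is.null(loc))
    vals[["colocalization"]] <- colocalization(loc[[id_a]], loc[[id_b]])

  if (!is.null(resources$expression)) {
    rho <- expression_correlations(id_a, id_b, resources$expression)
    vals[paste0("expr_spearman_", names(rho))] <- rho
  }

  diffs <- pair_difference(protein_profile(seqs[[id_a]]),
                           protein_profile(seqs[[id_b]]))
  vals[names(diffs)] <- diffs

  list(values = vals, missing = is.na(vals))
}

# use list names when present, else the supplied defaults
names2 <- function(x, default) {
  if (is.null(x)) return(default)
  nm <- names(x)
  if (is.null(nm)) default[seq_along(x)] else nm
}

#' Feature matrix for a set of pairs
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param resources as for [assemble_feature_vector()].
#' @return list with `features` (numeric matrix, pairs x 61) and `missing`
#'   (logical matrix of the same shape).
#' @export
compute_feature_matrix <- function(pairs, resources) {
  registry <- feature_registry(names2(resources$expression,
                                      EXPRESSION_DATASET_IDS))
  n <- nrow(pairs)
  feats <- matrix(NA_real_, n, length(registry),
                  dimnames = list(NULL, registry))
  for (i in seq_len(n)) {
    fv <- assemble_feature_vector(pairs$id_a[i], pairs$id_b[i], resources)
    feats[i, ] <- fv$values
  }
  list(features = feats, missing = is.na(feats))
}

#' Write a feature matrix and its missingness mask to TSV
#'
#' @param fm result of [compute_feature_matrix()].
#' @param pairs the pair data.frame the matrix was computed for.
#' @param path output TSV path; the missingness mask is written alongside
#'   with suffix `.missing.tsv`.
#' @return invisibly, the output path.
#' @export
write_feature_matrix <- function(fm, pairs, path) {
  out <- cbind(pairs[, c("id_a", "id_b")], as.data.frame(fm$features))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  miss <- cbind(pairs[, c("id_a", "id_b")],
                as.data.frame(fm$missing * 1L))
  utils::write.table(miss, paste0(sub("\\.tsv$", "", path), ".missing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
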
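# Synthetic-world generator: proteomes, annotations, interaction tables,
# expression matrices and affinity tables with planted interaction signal,
# so the whole stack is testable without external downloads.

#' Default planted effect sizes
#'
#' Five informative feature channels (GO similarity in the three aspects,
#' the domain-domain interaction flag and co-localization); each value is
#' the probability that a true-interacting pair receives the corresponding
#' planted signal. `expression_rho` is the latent-factor correlation of
#' co-expression profiles for interacting pairs (0 = co-expression carries
#' no signal).
#' @return named list of effect sizes.
#' @export
default_effect_sizes <- function() {
  list(BP_similarity = 0.85, MF_similarity = 0.85, CC_similarity = 0.7,
       pfam_interaction = 0.75, colocalization = 0.85, expression_rho = 0)
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE,
               prob = AA_BACKGROUND_FREQ), collapse = "")
}

sample_unordered_pairs <- function(ids, n, exclude_keys = character(0)) {
  got <- data.frame(id_a = character(0), id_b = character(0))
  seen <- exclude_keys
  guard <- 0
  while (nrow(got) < n) {
    guard <- guard + 1
    if (guard > 1000) stop("infeasible pair count requested")
    m <- (n - nrow(got)) * 2 + 10
    a <- sample(ids, m, replace = TRUE)
    b <- sample(ids, m, replace = TRUE)
    ok <- a != b
    lo <- pmin(a[ok], b[ok]); hi <- pmax(a[ok], b[ok])
    key <- paste(lo, hi, sep = "|")
    new <- !duplicated(key) & !key %in% seen
    got <- rbind(got, data.frame(id_a = lo[new], id_b = hi[new],
                                 stringsAsFactors = FALSE))
    seen <- c(seen, key[new])
  }
  got[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic interaction world with planted signal
#'
#' Builds a random proteome (sequences of length 50-350 drawn with
#' non-uniform residue frequencies), GO/Pfam/localization/expression
#' annotations arranged so that planted-positive pairs have elevated
#' similarity and co-expression according to `effect_sizes`, and a labelled
#' pair table whose observed labels are the true labels flipped with
#' probability `noise`. Bit-reproducible under `seed`; the `manifest`
#' element suffices to recompute every planted label.
#'
#' @param n_proteins proteome size.
#' @param n_positive,n_negative numbers of true-interacting and
#'   non-interacting labelled pairs (together at most `C(n_proteins, 2)`).
#' @param effect_sizes see [default_effect_sizes()].
#' @param noise label-flip probability.
#' @param seed integer RNG seed.
#' @return a `synthetic_world` list: `accessions`, `resources` (the
#'   resource list consumed by [assemble_feature_vector()]), `pairs`
#'   (columns `id_a`, `id_b`, `true_label`, `label`), `effect_sizes`,
#'   `noise`, `seed`, `manifest`.
#' @export
generate_world <- function(n_proteins = 300, n_positive = 200,
                           n_negative = 400,
                           effect_sizes = default_effect_sizes(),
                           noise = 0.05, seed = 1L) {
  if (n_positive + n_negative > choose(n_proteins, 2))
    stop("infeasible: more labelled pairs than distinct pairs")
  withr_seed(seed, {
    acc <- sprintf("P%05d", seq_len(n_proteins))
    sequences <- stats::setNames(
      vapply(sample(50:350, n_proteins, replace = TRUE), random_sequence,
             character(1)), acc)

    go_vocab <- lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(a)
      sprintf("GO:%s%04d", a, seq_len(500)))
    go <- stats::setNames(lapply(acc, function(p)
      lapply(go_vocab, function(v)
        sample(v, stats::rpois(1, 4) + 1))), acc)

    compartments <- c("nucleus", "cytosol", "membrane", "mitochondrion",
                      "ER", "golgi", "lysosome", "secreted", "peroxisome",
                      "cytoskeleton", "endosome", "vesicle")
    loc <- stats::setNames(lapply(acc, function(p)
      sample(compartments, sample(1:2, 1, prob = c(0.7, 0.3)))), acc)

    pfam_vocab <- sprintf("PF%05d", seq_len(40))
    pfam <- stats::setNames(lapply(acc, function(p)
      sample(pfam_vocab, sample(1:3, 1))), acc)

    n_samples <- 12
    expr <- stats::setNames(lapply(EXPRESSION_DATASET_IDS, function(d) {
      m <- matrix(stats::rnorm(n_proteins * n_samples), n_proteins,
                  dimnames = list(acc, paste0("s", seq_len(n_samples))))
      m
    }), EXPRESSION_DATASET_IDS)

    pos <- sample_unordered_pairs(acc, n_positive)
    neg <- sample_unordered_pairs(acc, n_negative,
                                  exclude_keys = paste(pos$id_a, pos$id_b,
                                                       sep = "|"))

    # plant signal into the annotations of true-interacting pairs
    ddi <- data.frame(dom_a = character(0), dom_b = character(0))
    es <- effect_sizes
    for (i in seq_len(nrow(pos))) {
      a <- pos$id_a[i]; b <- pos$id_b[i]
      for (aspect in c("BP", "MF", "CC")) {
        e <- es[[paste0(aspect, "_similarity")]]
        if (!is.null(e) && stats::runif(1) < e) {
          # shared functional module: the same fresh terms join both
          # proteins, so planting survives a protein's other pairings
          module <- sample(go_vocab[[aspect]], stats::rpois(1, 5) + 3)
          go[[a]][[aspect]] <- unique(c(go[[a]][[aspect]], module))
          go[[b]][[aspect]] <- unique(c(go[[b]][[aspect]], module))
        }
      }
      if (!is.null(es$colocalization) && stats::runif(1) < es$colocalization)
        loc[[b]] <- unique(c(loc[[b]], sample(loc[[a]], 1)))
      if (!is.null(es$pfam_interaction) && stats::runif(1) < es$pfam_interaction)
        ddi <- rbind(ddi, data.frame(dom_a = sample(pfam[[a]], 1),
                                     dom_b = sample(pfam[[b]], 1),
                                     stringsAsFactors = FALSE))
      rho <- es$expression_rho
      if (!is.null(rho) && rho > 0) {
        for (d in names(expr)) {
          z <- stats::rnorm(n_samples)
          expr[[d]][b, ] <- rho * expr[[d]][a, ] + sqrt(1 - rho^2) * z
        }
      }
    }
    # a few decoy domain interactions unrelated to the labels
    decoy <- data.frame(dom_a = sample(pfam_vocab, 5),
                        dom_b = sample(pfam_vocab, 5),
                        stringsAsFactors = FALSE)
    ddi <- unique(rbind(ddi, decoy))

    # uninformative auxiliary tables (orthology, databases, E-values)
    rand_table <- function(n) sample_unordered_pairs(acc, n)
    orthology <- stats::setNames(lapply(ORTHOLOGY_ORGANISMS,
                                        function(o) rand_table(30)),
                                 ORTHOLOGY_ORGANISMS)
    databases <- stats::setNames(lapply(DATABASE_FLAGS,
                                        function(d) rand_table(30)),
                                 DATABASE_FLAGS)
    labelled <- rbind(cbind(pos, true_label = 1L),
                      cbind(neg, true_label = 0L))
    evalues <- data.frame(id_a = labelled$id_a, id_b = labelled$id_b,
                          evalue = 10^stats::runif(nrow(labelled), -5, 2),
                          stringsAsFactors = FALSE)

    flip <- stats::runif(nrow(labelled)) < noise
    labelled$label <- ifelse(flip, 1L - labelled$true_label,
                             labelled$true_label)
    rownames(labelled) <- NULL

    resources <- list(sequences = sequences, go = go,
                      orthology = orthology, databases = databases,
                      evalues = evalues, pfam = pfam, ddi = ddi,
                      localizations = loc, expression = expr)
    structure(list(
      accessions = acc, resources = resources, pairs = labelled,
      effect_sizes = effect_sizes, noise = noise, seed = seed,
      manifest = list(seed = seed, n_proteins = n_proteins,
                      n_positive = n_positive, n_negative = n_negative,
                      effect_sizes = effect_sizes, noise = noise,
                      pairs = labelled)),
      class = "synthetic_world")
  })
}

#' Feature matrix for a world's labelled pairs
#' @param world a `synthetic_world`.
#' @return list with `features`, `missing`, `labels` (observed 0/1) and
#'   `true_labels`.
#' @export
world_feature_matrix <- function(world) {
  fm <- compute_feature_matrix(world$pairs, world$resources)
  c(fm, list(labels = world$pairs$label,
             true_labels = world$pairs$true_label))
}

#' Generate a raw binding-affinity table from a world
#'
#' The planted Gibbs energy is a linear combination of the pair's actual
#' feature values (`affinity_rule` coefficients over registry feature
#' names, plus an intercept) plus Gaussian noise. A configurable fraction
#' of records is emitted as Kd at a stated temperature (inverting
#' `dG = RT ln Kd`), the rest directly as dG; decoy rows (value ranges,
#' unsupported units, non-human taxa) are appended to exercise curation.
#'
#' @param world a `synthetic_world`.
#' @param n_records number of genuine records (drawn from the world's
#'   true-positive pairs, with replacement-free sampling).
#' @param sd Gaussian noise standard deviation, kJ/mol.
#' @param seed integer RNG seed.
#' @param kd_fraction fraction of genuine rows reported as Kd.
#' @param affinity_rule named coefficient vector plus `intercept`.
#' @param n_decoys decoy rows per decoy kind.
#' @return list with `table` (raw affinity data.frame), `truth`
#'   (data.frame of pair, planted dG) and `rule`.
#' @export
generate_affinity_table <- function(world, n_records = 120, sd = 1,
                                    seed = 1L, kd_fraction = 0.5,
                                    affinity_rule = c(intercept = -20,
                                                      BP_similarity = -15,
                                                      MF_similarity = -15,
                                                      colocalization = -8,
                                                      pfam_interaction = -8),
                                    n_decoys = 2) {
  pos <- world$pairs[world$pairs$true_label == 1L, , drop = FALSE]
  n_records <- min(n_records, nrow(pos))
  withr_seed(seed + 1L, {
    idx <- sample.int(nrow(pos), n_records)
    sel <- pos[idx, , drop = FALSE]
    fm <- compute_feature_matrix(sel, world$resources)
    coefs <- affinity_rule[setdiff(names(affinity_rule), "intercept")]
    vals <- fm$features[, names(coefs), drop = FALSE]
    vals[is.na(vals)] <- 0
    dg <- unname(affinity_rule[["intercept"]] + vals %*% coefs +
                   stats::rnorm(n_records, 0, sd))[, 1]
    as_kd <- stats::runif(n_records) < kd_fraction
    temp <- 300
    value <- ifelse(as_kd, exp(dg * 1000 / (GAS_CONSTANT_R * temp)),
                    dg)
    tab <- data.frame(
      id_a = sel$id_a, id_b = sel$id_b,
      measure = ifelse(as_kd, "Kd", "dG"),
      value = as.character(value),
      unit = ifelse(as_kd, "M", "kJ/mol"),
      temperature_K = ifelse(as_kd, temp, NA_real_),
      taxon = "9606", stoichiometry = "dimer",
      stringsAsFactors = FALSE)
    decoy_pairs <- sample_unordered_pairs(world$accessions, 3 * n_decoys)
    decoys <- data.frame(
      id_a = decoy_pairs$id_a, id_b = decoy_pairs$id_b,
      measure = rep(c("Kd", "IC50", "Kd"), each = n_decoys),
      value = rep(c("1e-9 - 1e-8", "2e-6", "3e-7"), each = n_decoys),
      unit = rep(c("M", "M", "M"), each = n_decoys),
      temperature_K = NA_real_,
      taxon = rep(c("9606", "9606", "10090"), each = n_decoys),
      stoichiometry = "dimer", stringsAsFactors = FALSE)
    list(table = rbind(tab, decoys),
         truth = data.frame(id_a = sel$id_a, id_b = sel$id_b,
                            delta_g_kj = dg, stringsAsFactors = FALSE),
         rule = list(affinity_rule = affinity_rule, sd = sd,
                     kd_fraction = kd_fraction))
  })
}

#' Generate a taste-receptor catalog for a world
#'
#' @param world a `synthetic_world`.
#' @param classes named integer vector of class sizes, e.g.
#'   `c(bitter = 5, salty = 2)`; the output has `sum(classes)` rows. When
#'   two or more classes are requested, one accession is shared between two
#'   classes (the heterodimer-subunit analogue).
#' @param seed integer RNG seed.
#' @return data.frame with columns `accession`, `taste_class`.
#' @export
generate_tr_catalog <- function(world, classes = c(bitter = 5, salty = 2),
                                seed = 1L) {
  stopifnot(sum(classes) <= length(world$accessions))
  withr_seed(seed + 2L, {
    n_unique <- sum(classes) - if (length(classes) >= 2) 1L else 0L
    ids <- sample(world$accessions, n_unique)
    rows <- list(); used <- 0L
    for (ci in seq_along(classes)) {
      cl <- names(classes)[ci]; n <- classes[[ci]]
      take <- if (ci == 2) {
        # share the last accession of class 1 with class 2
        c(ids[used], ids[used + seq_len(n - 1)])
      } else ids[used + seq_len(n)]
      used <- used + if (ci == 2) n - 1L else n
      rows[[ci]] <- data.frame(accession = take, taste_class = cl,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a world's files to a directory
#'
#' Writes the MITAB-dialect interaction table (the labelled positives),
#' the negative-pair list, FASTA sequences, GO/Pfam/DDI/localization
#' annotation TSVs, per-dataset expression matrices, the E-value table and
#' the ground-truth manifest JSON.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- world$resources
  # FASTA
  writeLines(unlist(lapply(names(res$sequences), function(id)
    c(paste0(">", id), res$sequences[[id]]))),
    file.path(dir, "proteins.fasta"))
  # MITAB-dialect positives; detection methods sampled deterministically
  pos <- world$pairs[world$pairs$label == 1L, , drop = FALSE]
  methods <- withr_seed(world$seed + 3L,
                        sample(c("Y2H", "TAP", "Y2H|TAP", "coIP"),
                               nrow(pos), replace = TRUE,
                               prob = c(0.4, 0.3, 0.1, 0.2)))
  mitab <- data.frame(uidA = paste0("uniprotkb:", pos$id_a),
                      uidB = paste0("uniprotkb:", pos$id_b),
                      Checksum_Interaction = pair_key(pos$id_a, pos$id_b),
                      method = methods,
                      taxid_host = "taxid:9606", sourcedb = "synthetic",
                      stringsAsFactors = FALSE)
  utils::write.table(mitab, file.path(dir, "interactions.mitab.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  neg <- world$pairs[world$pairs$label == 0L, c("id_a", "id_b")]
  utils::write.table(neg, file.path(dir, "negatives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # GO
  go_rows <- do.call(rbind, lapply(names(res$go), function(p)
    do.call(rbind, lapply(c("BP", "MF", "CC"), function(a)
      if (length(res$go[[p]][[a]]))
        data.frame(accession = p, aspect = a, term = res$go[[p]][[a]])))))
  utils::write.table(go_rows, file.path(dir, "go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pfam_rows <- do.call(rbind, lapply(names(res$pfam), function(p)
    data.frame(accession = p, domain = res$pfam[[p]])))
  utils::write.table(pfam_rows, file.path(dir, "pfam.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$ddi, file.path(dir, "ddi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  loc_rows <- do.call(rbind, lapply(names(res$localizations), function(p)
    data.frame(accession = p, compartment = res$localizations[[p]])))
  utils::write.table(loc_rows, file.path(dir, "localization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(res$expression))
    utils::write.table(data.frame(accession = rownames(res$expression[[d]]),
                                  res$expression[[d]], check.names = FALSE),
                       file.path(dir, paste0("expr_", d, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$evalues, file.path(dir, "evalues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(world$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a world directory into a resource list
#'
#' Inverse of [write_world()] for the annotation resources (sequences, GO,
#' Pfam, DDI, localization, expression, E-values).
#'
#' @param dir directory written by [write_world()].
#' @return resource list as consumed by [assemble_feature_vector()].
#' @export
read_world_resources <- function(dir) {
  fasta <- readLines(file.path(dir, "proteins.fasta"))
  hdr <- grepl("^>", fasta)
  ids <- sub("^>", "", fasta[hdr])
  seq_group <- cumsum(hdr)
  seqs <- vapply(split(fasta[!hdr], seq_group[!hdr]), paste, character(1),
                 collapse = "")
  sequences <- stats::setNames(unname(seqs), ids)
  go_rows <- utils::read.delim(file.path(dir, "go.tsv"))
  go <- lapply(split(go_rows, go_rows$accession), function(df)
    lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(a)
      df$term[df$aspect == a]))
  pfam_rows <- utils::read.delim(file.path(dir, "pfam.tsv"))
  pfam <- lapply(split(pfam_rows, pfam_rows$accession), `[[`, "domain")
  ddi <- utils::read.delim(file.path(dir, "ddi.tsv"))
  loc_rows <- utils::read.delim(file.path(dir, "localization.tsv"))
  loc <- lapply(split(loc_rows, loc_rows$accession), `[[`, "compartment")
  expr_files <- list.files(dir, pattern = "^expr_.*\\.tsv$")
  expr <- stats::setNames(lapply(expr_files, function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$accession
    m
  }), sub("^expr_(.*)\\.tsv$", "\\1", expr_files))
  evalues <- utils::read.delim(file.path(dir, "evalues.tsv"))
  list(sequences = sequences, go = go, pfam = pfam, ddi = ddi,
       localizations = loc, expression = expr, evalues = evalues)
}
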
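# Dataset construction: MITAB reading, filter cascade, sampling, splits.

write_mitab_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

mitab_rows <- function(uidA, uidB, method = "Y2H", taxid = "taxid:9606",
                       rigid = NA) {
  data.frame(uidA = uidA, uidB = uidB,
             Checksum_Interaction = ifelse(is.na(rigid), "", rigid),
             method = method, taxid_host = taxid, sourcedb = "fix",
             stringsAsFactors = FALSE)
}

test_that("read_mitab preserves rows, canonicalizes pairs and flags non-UniProt ids", {
  path <- write_mitab_fixture(mitab_rows(
    uidA = c("uniprotkb:Q9BY43", "uniprotkb:notanid"),
    uidB = c("uniprotkb:P59536", "uniprotkb:P12345")))
  rec <- read_mitab(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$id_a[1], "P59536")   # canonical unordered order
  expect_equal(rec$id_b[1], "Q9BY43")
  expect_false(rec$uniprot_valid[2])
  expect_equal(nrow(filter_uniprot_only(rec)), 1)
})

test_that("read_mitab errors on a missing mandatory column, naming it", {
  path <- write_mitab_fixture(data.frame(uidA = "uniprotkb:P12345"))
  expect_error(read_mitab(path), "uidB")
  expect_error(read_mitab(tempfile()), "cannot read")
})

test_that("dedup_by_rigid keeps first per group and is idempotent", {
  rec <- data.frame(id_a = sprintf("P%05d", 1:5), id_b = sprintf("P%05d", 6:10),
                    rigid = c("r1", "r1", "r2", "r3", "r2"))
  d1 <- dedup_by_rigid(rec)
  expect_equal(nrow(d1), 3)           # 5 records, 3 distinct rigids
  expect_equal(d1$rigid, c("r1", "r2", "r3"))
  expect_identical(dedup_by_rigid(d1), d1)
})

test_that("method filter implements the training include and test exclude rules", {
  rec <- data.frame(id_a = "P00001", id_b = "P00002",
                    methods = c("Y2H", "Y2H|TAP", "coIP"))
  expect_equal(nrow(filter_by_methods(rec, c("Y2H", "TAP"), "include")), 2)
  ex <- filter_by_methods(rec, c("Y2H", "TAP"), "exclude")
  expect_equal(ex$methods, "coIP")
  expect_error(filter_by_methods(rec, character(0)), "non-empty")
})

test_that("taxon filter keeps only the requested host", {
  rec <- data.frame(id_a = "P00001", id_b = "P00002",
                    taxon_host = c("9606", "10090", "9606"))
  expect_equal(nrow(filter_by_taxon(rec, 9606)), 2)
  expect_equal(nrow(filter_by_taxon(rec[0, ], 9606)), 0)
})

test_that("independent filters commute on random fixtures", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    ids <- sprintf("P%05d", sample(99999, 2 * n))
    bad <- sample(n, 5)
    ids_a <- ids[1:n]; ids_a[bad] <- paste0("x", ids_a[bad])
    rec <- data.frame(id_a = ids_a, id_b = ids[(n + 1):(2 * n)],
                      methods = sample(c("Y2H", "TAP", "coIP"), n, TRUE),
                      taxon_host = sample(c("9606", "10090"), n, TRUE),
                      rigid = replicate(n, paste(sample(letters, 6), collapse = "")))
    f1 <- filter_by_taxon(filter_uniprot_only(rec), 9606)
    f2 <- filter_uniprot_only(filter_by_taxon(rec, 9606))
    expect_identical(f1, f2)
    g1 <- filter_by_methods(filter_by_taxon(rec, 9606), "Y2H", "include")
    g2 <- filter_by_taxon(filter_by_methods(rec, "Y2H", "include"), 9606)
    expect_identical(g1, g2)
  }
})

test_that("negative sampling hits the exact ratio and is seed-reproducible", {
  pos <- data.frame(id_a = sprintf("P%05d", 1:1678),
                    id_b = sprintf("P%05d", 2001:3678))
  pool <- data.frame(id_a = sprintf("P%05d", 10001:14000),
                     id_b = sprintf("P%05d", 20001:24000))
  neg <- sample_negatives(pos, pool, ratio = 2, seed = 5)
  expect_equal(nrow(neg), 3356)
  expect_equal(nrow(pos) + nrow(neg), 5034)
  expect_identical(neg, sample_negatives(pos, pool, ratio = 2, seed = 5))
  expect_equal(nrow(sample_negatives(pos, pool, ratio = 0, seed = 5)), 0)
  expect_error(sample_negatives(pos, pool[1:10, ], 2, 5), "shortfall")
})

test_that("homology exclusion matches the exhaustive oracle and keeps one-sided similarity", {
  set.seed(11)
  ids <- sprintf("P%05d", 1:60)
  train <- data.frame(id_a = ids[1:20], id_b = ids[21:40])
  test <- data.frame(id_a = ids[41:50], id_b = ids[51:60])
  # plant 3 cross-wise homologous test pairs (a~d, b~c)
  ev <- data.frame(id_a = c(test$id_a[1:3], test$id_b[1:3]),
                   id_b = c(train$id_b[1:3], train$id_a[1:3]),
                   evalue = 1e-30)
  # one-sided similarity only for test pair 4
  ev <- rbind(ev, data.frame(id_a = test$id_a[4], id_b = train$id_a[4],
                             evalue = 1e-30),
              data.frame(id_a = test$id_b[4], id_b = train$id_b[4],
                         evalue = 10))
  # random sub-threshold noise that never pairs up
  ev <- rbind(ev, data.frame(id_a = sample(ids, 20, TRUE),
                             id_b = sample(ids, 20, TRUE), evalue = 5))
  res <- exclude_similar_pairs(test, train, ev, threshold = 0.05)
  expect_equal(nrow(res$removed), 3)
  expect_true(test$id_a[4] %in% res$kept$id_a)  # one-sided pair kept
  oracle <- brute_force_exclusion(test, train, ev, 0.05)
  expect_equal(sort(pair_key(res$removed$id_a, res$removed$id_b)),
               sort(pair_key(test$id_a[oracle], test$id_b[oracle])))
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(test))
})

test_that("train/test split uses the floor convention and leaves no overlap", {
  rec <- data.frame(id_a = sprintf("P%05d", 1:519),
                    id_b = sprintf("P%05d", 601:1119))
  sp <- split_train_test(rec, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 415)
  expect_equal(nrow(sp$test), 104)
  keys <- intersect(pair_key(sp$train$id_a, sp$train$id_b),
                    pair_key(sp$test$id_a, sp$test$id_b))
  expect_length(keys, 0)
  sp2 <- split_train_test(rec, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_equal(nrow(split_train_test(rec[1:10, ], 0.5, 1)$train), 5)
  expect_error(split_train_test(rec[1, , drop = FALSE], 0.5, 1), "at least 2")
})

test_that("build_dataset records stage counts and rejects label conflicts", {
  w <- generate_world(n_proteins = 40, n_positive = 25, n_negative = 50,
                      seed = 9)
  dir <- tempfile(); write_world(w, dir)
  rec <- read_mitab(file.path(dir, "interactions.mitab.tsv"))
  pool <- utils::read.delim(file.path(dir, "negatives.tsv"))
  built <- build_dataset(rec, pool, ratio = 2, seed = 4)
  st <- built$provenance$stages
  expect_true(all(diff(unlist(st[c("input", "uniprot", "dedup", "methods",
                                   "taxon")])) <= 0))
  expect_equal(sum(built$dataset$label == "negative"),
               2 * sum(built$dataset$label == "positive"))
  # conflicting labels must be refused
  clash <- rbind(pool, data.frame(id_a = rec$id_a[1], id_b = rec$id_b[1]))
  expect_error(
    build_dataset(rec[1, , drop = FALSE],
                  clash[nrow(clash), , drop = FALSE], ratio = 1, seed = 1),
    "conflict")
})
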
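# Sequence descriptors and pair-feature assembly.

test_that("amino-acid composition counts residues and rejects invalid ones", {
  expect_equal(unname(aa_composition("AAAA")["A"]), 1)
  expect_equal(unname(aa_composition("ACDE")[c("A", "C", "D", "E")]),
               rep(0.25, 4))
  expect_equal(unname(aa_composition("AAC")[c("A", "C")]), c(2 / 3, 1 / 3))
  expect_equal(sum(aa_composition("MKVLT")), 1)
  expect_error(aa_composition("AXC"), "position 2")
  expect_error(aa_composition(""), "non-empty")
})

test_that("physicochemical descriptors match closed-form oracle values", {
  expect_equal(physchem_profile("FWY")[["aromaticity"]], 1)
  expect_equal(physchem_profile("AG")[["aromaticity"]], 0)
  # Gill-von Hippel coefficients: one Trp + one Tyr
  expect_equal(physchem_profile("WY")[["cys_reduced"]], 6990)
  # Kyte-Doolittle mean of A (1.8) and G (-0.4)
  expect_equal(physchem_profile("AG")[["gravy"]], 0.7)
  # charge sign checks
  expect_lt(physchem_profile("DDDDDD")[["charge_pH7"]], 0)
  expect_gt(physchem_profile("KKKKKK")[["charge_pH7"]], 0)
  # molecular weight: residue masses minus peptide-bond water
  expect_equal(physchem_profile("AG")[["mw"]], 89.0932 + 75.0666 - 18.0153,
               tolerance = 1e-6)
})

test_that("full-alphabet profile agrees with the reference implementation values", {
  # oracle values computed independently with Biopython ProtParam
  p <- physchem_profile("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(p[["instability"]], 84.74, tolerance = 1e-6)
  expect_equal(p[["gravy"]], -0.49, tolerance = 1e-6)
  expect_equal(p[["mw"]], 2395.7134, tolerance = 1e-3)
  expect_equal(p[["aromaticity"]], 0.15, tolerance = 1e-9)
  # secondary-structure classes by direct counting of the documented sets
  expect_equal(p[["helix_frac"]], 6 / 20)
  expect_equal(p[["turn_frac"]], 4 / 20)
  expect_equal(p[["sheet_frac"]], 4 / 20)
})

test_that("instability index is undefined for single residues", {
  expect_true(is.na(physchem_profile("A")[["instability"]]))
})

test_that("pair differences are symmetric, zero on identity, and correct", {
  a <- protein_profile("AAAA"); b <- protein_profile("AACC")
  d <- pair_difference(a, b)
  expect_length(d, 30)
  expect_equal(unname(d["A_pct_dif"]), 0.5)
  expect_equal(pair_difference(a, b), pair_difference(b, a))
  expect_true(all(pair_difference(a, a) == 0))
})

test_that("GO similarity is Jaccard with missing for empty-vs-empty", {
  expect_equal(go_similarity(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(go_similarity(c("g1"), c("g1")), 1)
  expect_equal(go_similarity(c("g1"), c("g2")), 0)
  expect_true(is.na(go_similarity(character(0), character(0))))
})

test_that("pair flags are unordered and zero on empty tables", {
  tabs <- list(A = data.frame(x = "P00001", y = "P00002"),
               B = data.frame(x = character(0), y = character(0)))
  expect_equal(unname(lookup_flags("P00002", "P00001", tabs)), c(1, 0))
  expect_equal(lookup_flags("P00001", "P00002", tabs),
               lookup_flags("P00002", "P00001", tabs))
})

test_that("domain interaction flag agrees with the exhaustive double loop", {
  ddi <- data.frame(a = "PF00001", b = "PF00002")
  expect_equal(pfam_interaction("PF00001", "PF00002", ddi), 1)
  expect_equal(pfam_interaction("PF00003", "PF00004", ddi), 0)
  set.seed(5)
  vocab <- sprintf("PF%05d", 1:30)
  for (rep in 1:10) {
    da <- sample(vocab, 5); db <- sample(vocab, 5)
    tab <- data.frame(a = sample(vocab, 8, TRUE), b = sample(vocab, 8, TRUE))
    keys <- pair_key(tab$a, tab$b)
    oracle <- 0
    for (x in da) for (y in db)
      if (pair_key(x, y) %in% keys) oracle <- 1
    expect_equal(pfam_interaction(da, db, tab), oracle)
  }
})

test_that("colocalization intersects compartments and propagates unknowns", {
  expect_equal(colocalization("nucleus", c("nucleus", "cytosol")), 1)
  expect_equal(colocalization("nucleus", "membrane"), 0)
  expect_true(is.na(colocalization(NULL, "membrane")))
})

test_that("expression correlations are Spearman and monotone-invariant", {
  m <- rbind(P1 = c(1, 2, 3, 4), P2 = c(10, 20, 30, 40),
             P3 = c(4, 3, 2, 1), P4 = c(2, 2, 2, 2))
  mats <- list(D1 = m)
  expect_equal(unname(expression_correlations("P1", "P2", mats)), 1)
  expect_equal(unname(expression_correlations("P1", "P3", mats)), -1)
  expect_true(is.na(expression_correlations("P1", "P4", mats)))  # constant
  expect_true(is.na(expression_correlations("P1", "P9", mats)))  # absent
  # monotone transform of either profile leaves rho unchanged
  m2 <- m; m2["P2", ] <- exp(m2["P2", ])
  expect_equal(expression_correlations("P1", "P2", list(D1 = m2)),
               expression_correlations("P1", "P2", mats))
})

test_that("assembled vectors have 61 slots, explicit missingness and symmetry", {
  w <- generate_world(n_proteins = 30, n_positive = 15, n_negative = 20,
                      seed = 13)
  res <- w$resources
  fv <- assemble_feature_vector(w$pairs$id_a[1], w$pairs$id_b[1], res)
  expect_length(fv$values, 61)
  expect_identical(names(fv$values), as.character(feature_registry()))
  # symmetry in argument order
  fv_rev <- assemble_feature_vector(w$pairs$id_b[1], w$pairs$id_a[1], res)
  expect_equal(fv$values, fv_rev$values)
  # dropping expression data leaves exactly the 17 expression slots missing
  res_noexpr <- res; res_noexpr$expression <- NULL
  fv2 <- assemble_feature_vector(w$pairs$id_a[1], w$pairs$id_b[1], res_noexpr)
  grp <- attr(feature_registry(), "groups")
  expect_true(all(fv2$missing[grp == "expression"]))
  expect_equal(sum(fv2$missing[grp == "expression"]), 17)
  # self-pair: all 30 difference features zero
  fv3 <- assemble_feature_vector(w$pairs$id_a[1], w$pairs$id_a[1], res)
  expect_true(all(fv3$values[grp %in% c("aa_composition", "physchem")] == 0))
  expect_equal(unname(fv3$values["BP_similarity"]), 1)
  # missing sequence is a hard error
  expect_error(assemble_feature_vector("Q99999", w$pairs$id_b[1], res),
               "sequence")
})

test_that("aromaticity equals the sum of F/W/Y composition fractions", {
  set.seed(3)
  for (rep in 1:10) {
    s <- paste(sample(ppievolve:::AA_ALPHABET, 60, TRUE), collapse = "")
    comp <- aa_composition(s)
    expect_equal(physchem_profile(s)[["aromaticity"]],
                 sum(comp[c("F", "W", "Y")]))
  }
})

test_that("cystine extinction exceeds reduced exactly when two cysteines pair", {
  p0 <- physchem_profile("WYA")    # no C
  p1 <- physchem_profile("WYAC")   # one C
  p2 <- physchem_profile("WYACC")  # two C
  expect_equal(p0[["cys_cystines"]], p0[["cys_reduced"]])
  expect_equal(p1[["cys_cystines"]], p1[["cys_reduced"]])
  expect_equal(p2[["cys_cystines"]], p2[["cys_reduced"]] + 125)
})
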
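# Fixed-order registry of the 61 pair features.

# the 17 public expression datasets whose Spearman co-expression features are
# part of the default panel
EXPRESSION_DATASET_IDS <- c(
  "GDS531", "GDS534", "GDS596", "GDS651", "GDS806", "GDS807", "GDS843",
  "GDS987", "GDS1085", "GDS2855", "GDS1402", "GDS181", "GDS1088", "GDS841",
  "GDS3257", "GSE227375", "GSE228702")

ORTHOLOGY_ORGANISMS <- c("M_musculus", "D_melanogaster", "S_cerevisiae",
                         "E_coli")

# only three reference databases are fixed by the panel; the fourth source is
# configurable (default placeholder label "DB4")
DATABASE_FLAGS <- c("MINT", "APID", "BIOGRID", "DB4")

PHYSCHEM_NAMES <- c("mw", "aromaticity", "instability", "helix_frac",
                    "turn_frac", "sheet_frac", "cys_reduced", "cys_cystines",
                    "gravy", "charge_pH7")

#' The fixed 61-name feature registry
#'
#' Returns the ordered names of the 61 pair features: three GO-term
#' similarities (BP/MF/CC), four orthologous-interaction flags, four
#' database-presence flags, the pairwise sequence-similarity E-value, the
#' Pfam domain-domain interaction flag, subcellular co-localization, 17
#' expression Spearman correlations, and 30 absolute physicochemical
#' differences (20 amino-acid percentage differences plus molecular weight,
#' aromaticity, instability index, helix/turn/sheet fractions, extinction
#' coefficients with reduced cysteines and with cystines, GRAVY, and charge
#' at pH 7).
#'
#' @param expression_datasets character vector of expression dataset
#'   identifiers (defaults to the 17-dataset panel). Supplying a different
#'   vector changes the registry length accordingly; the default panel is the
#'   one every exported model expects.
#' @return character vector of feature names with a `groups` attribute
#'   mapping each name to its feature group.
#' @export
#' @examples
#' length(feature_registry())  # 61
feature_registry <- function(expression_datasets = EXPRESSION_DATASET_IDS) {
  go <- c("BP_similarity", "MF_similarity", "CC_similarity")
  ortho <- paste0("ortho_", ORTHOLOGY_ORGANISMS)
  dbs <- paste0("exists_", DATABASE_FLAGS)
  expr <- paste0("expr_spearman_", expression_datasets)
  aa_pct <- paste0(AA_ALPHABET, "_pct_dif")
  phys <- paste0(PHYSCHEM_NAMES, "_dif")
  nms <- c(go, ortho, dbs, "sequence_similarity", "pfam_interaction",
           "colocalization", expr, aa_pct, phys)
  stopifnot(!anyDuplicated(nms))
  groups <- c(rep("go", length(go)), rep("orthology", length(ortho)),
              rep("database", length(dbs)), "sequence_similarity",
              "pfam_interaction", "colocalization",
              rep("expression", length(expr)),
              rep("aa_composition", length(aa_pct)),
              rep("physchem", length(phys)))
  names(groups) <- nms
  structure(nms, groups = groups)
}
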
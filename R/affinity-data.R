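# Binding-affinity curation: Kd/Ki to Gibbs free energy, filtering, and the
# [0, 1] endpoint normalization used by the regression models.

#' Gibbs free energy of binding from a dissociation/inhibition constant
#'
#' `dG = R T ln(k)` with R = 8.314 J mol^-1 K^-1, reported in kJ/mol. The
#' experimental temperature is applied when given, otherwise 300 K.
#'
#' @param k molar constant (Kd or Ki), > 0. Vectorized.
#' @param temperature_K temperature in kelvin; `NA` entries fall back to the
#'   300 K default.
#' @return kJ/mol, strictly increasing in `k`.
#' @export
#' @examples
#' delta_g_from_k(1)       # 0
#' delta_g_from_k(1e-6)    # -34.46 kJ/mol
delta_g_from_k <- function(k, temperature_K = NA_real_) {
  t <- ifelse(is.na(temperature_K), 300, temperature_K)
  if (any(k <= 0, na.rm = TRUE)) stop("Kd/Ki must be > 0")
  if (any(t <= 0)) stop("temperature must be > 0 K")
  GAS_CONSTANT_R * t * log(k) / 1000
}

parse_affinity_value <- function(x) {
  # exact numeric values only; ranges ("1-10", "1~10"), inequalities and
  # other imprecise notations are rejected
  x <- trimws(as.character(x))
  suppressWarnings(v <- as.numeric(x))
  imprecise <- is.na(v) &
    grepl("[0-9]\\s*(-|~|to)\\s*[0-9]|^[<>]", x)
  list(value = v, imprecise = imprecise)
}

UNIT_SCALE <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
                fM = 1e-15, `kJ/mol` = 1)

#' Curate a raw binding-affinity table into Gibbs-energy records
#'
#' Applies, in order: taxonomy filter (human only), stoichiometry filter
#' (dimeric complexes only), measure whitelist (Kd, Ki, dG), unit whitelist,
#' rejection of imprecise values (ranges, inequalities, unparsable strings),
#' Gibbs-energy derivation, and redundancy elimination (first occurrence per
#' unordered pair).
#'
#' @param raw data.frame with columns `id_a`, `id_b`, `measure` (`Kd`, `Ki`
#'   or `dG`), `value`, `unit` (molar prefixes for Kd/Ki, `kJ/mol` for dG),
#'   `temperature_K`, `taxon`, `stoichiometry`.
#' @param taxon retained taxon (default `"9606"`).
#' @param stoichiometry retained stoichiometry label (default `"dimer"`).
#' @return list with `records` (curated data.frame including `delta_g_kj`)
#'   and `rejected` (data.frame of dropped rows with a `reason` code in
#'   `taxon`, `stoichiometry`, `measure`, `unit`, `imprecise`, `duplicate`).
#' @export
curate_affinity <- function(raw, taxon = "9606", stoichiometry = "dimer") {
  reason <- rep(NA_character_, nrow(raw))
  measure <- as.character(raw$measure)
  unit <- as.character(raw$unit)
  reason[is.na(reason) & as.character(raw$taxon) != as.character(taxon)] <- "taxon"
  reason[is.na(reason) &
           as.character(raw$stoichiometry) != stoichiometry] <- "stoichiometry"
  reason[is.na(reason) & !measure %in% c("Kd", "Ki", "dG")] <- "measure"
  valid_unit <- ifelse(measure == "dG", unit == "kJ/mol",
                       unit %in% setdiff(names(UNIT_SCALE), "kJ/mol"))
  reason[is.na(reason) & !valid_unit] <- "unit"
  parsed <- parse_affinity_value(raw$value)
  reason[is.na(reason) & parsed$imprecise] <- "imprecise"
  reason[is.na(reason) & is.na(parsed$value)] <- "unparsable"
  key <- pair_key(as.character(raw$id_a), as.character(raw$id_b))
  ok <- is.na(reason)
  key[!ok] <- paste0("__rejected__", which(!ok))  # never counted as duplicates
  reason[ok & duplicated(key)] <- "duplicate"
  keep <- is.na(reason)

  rec <- raw[keep, , drop = FALSE]
  value <- parsed$value[keep]
  scale <- UNIT_SCALE[unit[keep]]
  temp <- suppressWarnings(as.numeric(rec$temperature_K))
  dg <- ifelse(measure[keep] == "dG", value,
               delta_g_from_k(pmax(value * scale, .Machine$double.xmin),
                              temp))
  rec$id_a <- as.character(rec$id_a); rec$id_b <- as.character(rec$id_b)
  swap <- rec$id_a > rec$id_b
  tmp <- rec$id_a[swap]; rec$id_a[swap] <- rec$id_b[swap]; rec$id_b[swap] <- tmp
  rec$delta_g_kj <- dg
  rownames(rec) <- NULL
  rejected <- raw[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(rejected) <- NULL
  list(records = rec, rejected = rejected)
}

#' Min-max normalize Gibbs energies to the [0, 1] regression endpoint
#'
#' @param values numeric vector of dG values (kJ/mol) with at least two
#'   distinct entries.
#' @return list with `endpoint01` (normalized values) and `scaler` (list
#'   `g_min`, `g_max`), to be reused via [denormalize()] for inversion. The
#'   scaler should be fitted on the training endpoint only.
#' @export
normalize_endpoint <- function(values) {
  g_min <- min(values); g_max <- max(values)
  if (!is.finite(g_min) || g_min == g_max)
    stop("degenerate scale: need at least 2 distinct finite values")
  scaler <- list(g_min = g_min, g_max = g_max)
  list(endpoint01 = (values - g_min) / (g_max - g_min), scaler = scaler)
}

#' Invert the endpoint normalization
#' @param endpoint01 normalized values.
#' @param scaler scaler from [normalize_endpoint()].
#' @return dG in kJ/mol.
#' @export
denormalize <- function(endpoint01, scaler) {
  scaler$g_min + endpoint01 * (scaler$g_max - scaler$g_min)
}
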
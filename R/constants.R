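# Published physicochemical constant tables used by the sequence descriptors.
# All values are from the primary literature: average residue masses and the
# Kyte-Doolittle hydropathy scale (Kyte & Doolittle 1982), the dipeptide
# instability weight table (Guruprasad, Reddy & Pandit 1990), molar extinction
# coefficients (Gill & von Hippel 1989) and the EMBOSS pKa set.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# average (isotope-abundance weighted) residue masses, g/mol, free amino acid
AA_MASS <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885)

WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Dipeptide instability weight values (DIWV); DIWV[a, b] weights dipeptide ab.
DIWV <- local({
  m <- rbind(
  A = c(1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1),
  C = c(1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1),
  D = c(1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1),
  E = c(1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1),
  F = c(1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601),
  G = c(-7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49),
  H = c(1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94),
  I = c(1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1),
  K = c(1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1),
  L = c(1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1),
  M = c(13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68),
  N = c(1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1),
  P = c(20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1),
  Q = c(1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54),
  R = c(1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54),
  S = c(1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1),
  T = c(1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1),
  V = c(1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54),
  W = c(-14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1),
  Y = c(24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34))
  colnames(m) <- AA_ALPHABET
  m
})

# Gill-von Hippel molar extinction coefficients at 280 nm (M^-1 cm^-1)
EPS_TRP <- 5500
EPS_TYR <- 1490
EPS_CYSTINE <- 125

# EMBOSS pKa values for the charge-at-pH calculation
PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Secondary-structure propensity residue classes (fraction-of-sequence
# convention): residues commonly found in helices, turns and sheets.
HELIX_RESIDUES <- c("V", "I", "Y", "F", "W", "L")
TURN_RESIDUES  <- c("N", "P", "G", "S")
SHEET_RESIDUES <- c("E", "M", "A", "L")

AROMATIC_RESIDUES <- c("F", "W", "Y")

# UniProtKB accession pattern (canonical 6- and 10-character forms)
UNIPROT_REGEX <-
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

#' Test whether strings are valid UniProtKB accessions
#'
#' @param x character vector.
#' @return logical vector, `TRUE` where `x` matches the canonical UniProtKB
#'   accession pattern.
#' @export
is_uniprot_accession <- function(x) {
  !is.na(x) & grepl(UNIPROT_REGEX, x)
}

# gas constant, J mol^-1 K^-1
GAS_CONSTANT_R <- 8.314

# Average human-like residue background frequencies used by the synthetic
# sequence generator (non-uniform so composition features carry variance).
AA_BACKGROUND_FREQ <- c(
  A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365,
  G = 0.0657, H = 0.0263, I = 0.0433, K = 0.0572, L = 0.0996,
  M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
  S = 0.0833, T = 0.0535, V = 0.0597, W = 0.0122, Y = 0.0268)
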
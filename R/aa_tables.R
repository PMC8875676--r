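# Amino-acid property tables shared by the geometry, rules and feature modules.

#' @keywords internal
.vs_cache <- new.env(parent = emptyenv())

#' Three-letter to one-letter amino-acid codes (20 standard residues)
#' @keywords internal
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' @keywords internal
AA1 <- stats::setNames(names(AA3), AA3)

#' One-letter codes of the 20 standard amino acids
#' @export
aa_alphabet <- function() unname(AA3)

# Van der Waals radii (Angstrom) used by the accessibility calculation.
# Fixed table; probe radius 1.4 A is the conventional water probe.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

# Theoretical maximum accessible surface area per residue type (A^2),
# Tien et al. 2013 ("theoretical" column). Used to normalize absolute
# SASA into relative SASA; relative SASA < 0.09 is treated as buried.
MAX_SASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
              Q = 225, E = 223, G = 104, H = 224, I = 197,
              L = 201, K = 236, M = 224, F = 240, P = 159,
              S = 155, T = 172, W = 285, Y = 263, V = 174)

# Physicochemical classes used by the structural-event rules. "Hydrophilic"
# means charged or amide-polar; Ser/Thr/Gly/Pro are treated as neutral, so a
# Ser -> Ala substitution triggers no polarity event.
AA_HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
AA_HYDROPHILIC <- c("D", "E", "H", "K", "N", "Q", "R")
AA_CHARGE <- c(D = -1, E = -1, K = +1, R = +1, H = +1)

# Burial threshold on relative SASA (missense3D convention).
BURIED_RSA <- 0.09

#' Formal charge of an amino acid (-1, 0, +1)
#' @param aa one-letter code
#' @keywords internal
aa_charge <- function(aa) {
  ch <- AA_CHARGE[aa]
  ch[is.na(ch)] <- 0
  unname(ch)
}

.check_aa <- function(aa, arg = "aa") {
  bad <- !(aa %in% AA3)
  if (any(bad)) {
    stop(sprintf("unknown amino acid '%s' for %s (one-letter codes of the 20 standard amino acids expected)",
                 paste(unique(aa[bad]), collapse = ","), arg), call. = FALSE)
  }
  invisible(aa)
}

# Grantham (1974) side-chain composition (c), polarity (p) and volume (v)
# properties; the distance matrix is generated from these with the published
# constants (alpha 1.833, beta 0.1018, gamma 0.000399) and scaled so the mean
# over the 190 unordered pairs is 100, then rounded to integers.
GRANTHAM_PROPS <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE
)

#' Grantham distance matrix (20 x 20, one-letter codes)
#'
#' Generated from the published physicochemical properties and formula;
#' symmetric with zero diagonal.
#' @return integer matrix with dimnames of one-letter amino-acid codes
#' @export
grantham_matrix <- function() {
  if (!is.null(.vs_cache$grantham)) return(.vs_cache$grantham)
  pr <- GRANTHAM_PROPS
  n <- nrow(pr)
  raw <- matrix(0, n, n, dimnames = list(pr$aa, pr$aa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    raw[i, j] <- sqrt(1.833 * (pr$c[i] - pr$c[j])^2 +
                      0.1018 * (pr$p[i] - pr$p[j])^2 +
                      0.000399 * (pr$v[i] - pr$v[j])^2)
  }
  rho <- 100 / mean(raw[upper.tri(raw)])
  m <- round(raw * rho)
  m <- m[AA3, AA3]  # canonical alphabetical-by-3-letter order
  storage.mode(m) <- "integer"
  .vs_cache$grantham <- m
  m
}

#' BLOSUM62 substitution matrix restricted to the 20 standard amino acids
#' @return integer matrix
#' @export
blosum62_matrix <- function() {
  if (!is.null(.vs_cache$blosum62)) return(.vs_cache$blosum62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[unname(AA3), unname(AA3)]
  storage.mode(m) <- "integer"
  .vs_cache$blosum62 <- m
  m
}

.aaindex_vector <- function(key) {
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  v <- e$aaindex[[key]]$I
  # seqinr names entries by three-letter code
  nm <- AA3[toupper(names(v))]
  stats::setNames(as.numeric(v), nm)[unname(AA3)]
}

#' Amino-acid volume descriptor (AAindex BIGC670101, residue volume)
#' @return named numeric vector over the 20 one-letter codes
#' @export
aa_volume <- function() {
  if (is.null(.vs_cache$volume)) .vs_cache$volume <- .aaindex_vector("BIGC670101")
  .vs_cache$volume
}

#' Amino-acid hydrophobicity descriptor (AAindex JOND750101)
#' @return named numeric vector over the 20 one-letter codes
#' @export
aa_hydrophobicity <- function() {
  if (is.null(.vs_cache$hydro)) .vs_cache$hydro <- .aaindex_vector("JOND750101")
  .vs_cache$hydro
}

#' Synthetic Sneath-style amino-acid dissimilarity matrix
#'
#' A stand-in for Sneath's (1966) published dissimilarity index, which is not
#' redistributable here. Computed from the bundled volume and hydrophobicity
#' descriptors plus formal-charge and polarity classes, scaled to the 0-100
#' range of the published index. Symmetric, zero diagonal. The feature slot it
#' fills can be redirected to a user-supplied table via the `sneath` argument
#' of [substitution_scores()].
#' @return numeric matrix (synthetic values)
#' @export
sneath_matrix_synthetic <- function() {
  if (!is.null(.vs_cache$sneath)) return(.vs_cache$sneath)
  aa <- unname(AA3)
  vol <- scale(aa_volume()[aa])[, 1]
  hyd <- scale(aa_hydrophobicity()[aa])[, 1]
  chg <- aa_charge(aa)
  pol <- as.numeric(aa %in% AA_HYDROPHILIC)
  d <- outer(vol, vol, "-")^2 + outer(hyd, hyd, "-")^2 +
       outer(chg, chg, "-")^2 + outer(pol, pol, "-")^2
  d <- sqrt(d)
  m <- round(d / max(d) * 100)
  dimnames(m) <- list(aa, aa)
  .vs_cache$sneath <- m
  m
}
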
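# Sequence-derived scores and the 12-feature vector of the classifier.

#' Canonical feature order of the classifier
#'
#' Fixed and versioned: `ddg` (kcal/mol), `ddsvib`, `sasa_ratio` (predicted
#' variant-residue SASA over reference-residue SASA), `pssm_variant`,
#' `pssm_self` (log-odds), `sneath`, `grantham`, `blosum62`, `volume_delta`
#' (BIGC670101 alt - ref), `hydrophobicity_delta` (JOND750101 alt - ref),
#' `total_sasa_delta` (A^2), `rsa_ref` (relative SASA of the reference
#' residue; the declared twelfth feature, which can be dropped to run an
#' 11-feature model).
#'
#' @param include_rsa keep the `rsa_ref` feature (default TRUE)
#' @return character vector of feature names
#' @export
feature_names <- function(include_rsa = TRUE) {
  nm <- c("ddg", "ddsvib", "sasa_ratio", "pssm_variant", "pssm_self",
          "sneath", "grantham", "blosum62", "volume_delta",
          "hydrophobicity_delta", "total_sasa_delta", "rsa_ref")
  if (include_rsa) nm else nm[-12]
}

#' Checksum of a feature schema (train/predict consistency guard)
#'
#' Polynomial rolling hash over the concatenated feature names; stored with
#' trained models and compared at prediction time.
#' @param names character vector of feature names
#' @return character scalar (hex)
#' @export
feature_schema_checksum <- function(names = feature_names()) {
  h <- 17
  for (b in utf8ToInt(paste(names, collapse = "|"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the classic 20-column log-odds section. Row positions are 1-based
#' and must match the query sequence embedded in the file.
#'
#' @param path PSSM file path
#' @param expected_seq optional protein sequence to check the PSSM query
#'   against (consistency error on mismatch)
#' @return object of class `vs_pssm`: `scores` (n x 20 integer matrix, rows
#'   1..n, columns one-letter amino acids), `query` (one-letter string)
#' @export
read_pssm <- function(path, expected_seq = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)
  if (!length(hdr)) stop("PSSM format error: no amino-acid header row in ", path)
  cols <- strsplit(trimws(lines[hdr[1]]), "\\s+")[[1]][1:20]
  if (length(cols) != 20 || !all(cols %in% unname(AA3)))
    stop("PSSM format error: expected 20 amino-acid columns in ", path)
  rows <- list(); query <- character()
  for (ln in lines[-seq_len(hdr[1])]) {
    tk <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tk) < 22) {
      if (!nzchar(trimws(ln))) break else next
    }
    idx <- suppressWarnings(as.integer(tk[1]))
    if (is.na(idx)) break
    vals <- suppressWarnings(as.integer(tk[3:22]))
    if (any(is.na(vals)))
      stop("PSSM format error: non-numeric scores at position ", idx, " in ", path)
    if (idx != length(rows) + 1)
      stop("PSSM format error: positions not consecutive at ", idx, " in ", path)
    rows[[idx]] <- vals
    query <- c(query, tk[2])
  }
  if (!length(rows)) stop("PSSM format error: no score rows in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  m <- m[, unname(AA3), drop = FALSE]
  q <- paste(query, collapse = "")
  if (!is.null(expected_seq) && q != expected_seq)
    stop("PSSM consistency error: query sequence disagrees with the database protein sequence")
  structure(list(scores = m, query = q), class = "vs_pssm")
}

#' @export
print.vs_pssm <- function(x, ...) {
  cat(sprintf("<vs_pssm> %d positions, query %s...\n", nrow(x$scores),
              substr(x$query, 1, 20)))
  invisible(x)
}

#' PSSM log-odds for a position and amino acid
#' @param pssm a `vs_pssm`
#' @param pos 1-based protein position
#' @param aa one-letter amino acid
#' @export
pssm_score <- function(pssm, pos, aa) {
  .check_aa(aa)
  if (pos < 1 || pos > nrow(pssm$scores))
    stop("position ", pos, " outside PSSM range 1..", nrow(pssm$scores))
  pssm$scores[pos, aa]
}

#' Substitution-matrix scores for a residue pair
#'
#' @param ref_aa,alt_aa one-letter amino acids
#' @param sneath optional dissimilarity matrix overriding the bundled
#'   synthetic Sneath-style table (e.g. the published index, if available)
#' @return named numeric vector: `blosum62`, `grantham`, `sneath`
#' @export
substitution_scores <- function(ref_aa, alt_aa, sneath = NULL) {
  .check_aa(c(ref_aa, alt_aa))
  if (is.null(sneath)) sneath <- sneath_matrix_synthetic()
  c(blosum62 = blosum62_matrix()[ref_aa, alt_aa],
    grantham = grantham_matrix()[ref_aa, alt_aa],
    sneath = sneath[ref_aa, alt_aa])
}

#' AAindex descriptor differences for a substitution
#'
#' Differences (alt - ref) of the residue-volume (BIGC670101) and
#' hydrophobicity (JOND750101) descriptors, so a self-substitution maps to
#' zero and reversing the substitution negates both values.
#'
#' @param ref_aa,alt_aa one-letter amino acids
#' @return named numeric vector: `volume_delta`, `hydrophobicity_delta`
#' @export
aaindex_descriptors <- function(ref_aa, alt_aa) {
  .check_aa(c(ref_aa, alt_aa))
  vol <- aa_volume(); hyd <- aa_hydrophobicity()
  c(volume_delta = unname(vol[alt_aa] - vol[ref_aa]),
    hydrophobicity_delta = unname(hyd[alt_aa] - hyd[ref_aa]))
}

#' Assemble the 12-feature vector for one variant
#'
#' The variant-residue SASA is approximated by max-SASA scaling of the
#' reference residue's absolute SASA: `sasa_ratio` therefore reduces to
#' maxSASA(alt)/maxSASA(ref) (defined even for a fully buried reference
#' residue), and `total_sasa_delta` is
#' SASA_ref(pos) * (maxSASA(alt)/maxSASA(ref) - 1).
#'
#' @param pos protein position of the substitution
#' @param ref_aa,alt_aa one-letter amino acids
#' @param ddg stability change (kcal/mol), e.g. from [builtin_ddg()]
#' @param ddsvib vibrational-entropy change, e.g. from [delta_delta_svib()]
#' @param sasa a `vs_sasa` of the reference structure
#' @param pssm a `vs_pssm`
#' @param sneath optional Sneath-style table (see [substitution_scores()])
#' @return named numeric vector in [feature_names()] order
#' @export
assemble_features <- function(pos, ref_aa, alt_aa, ddg, ddsvib, sasa, pssm,
                              sneath = NULL) {
  .check_aa(c(ref_aa, alt_aa))
  missing <- character()
  row <- which(sasa$residue$protein_pos == pos)
  if (!length(row)) missing <- c(missing, sprintf("SASA at position %d", pos))
  if (pos < 1 || pos > nrow(pssm$scores))
    missing <- c(missing, sprintf("PSSM row %d", pos))
  if (!all(is.finite(c(ddg, ddsvib))))
    missing <- c(missing, "finite ddg/ddsvib")
  if (length(missing))
    stop("feature assembly error, missing inputs: ", paste(missing, collapse = "; "))
  abs_sasa <- sasa$residue$sasa[row]
  ratio <- unname(MAX_SASA[alt_aa] / MAX_SASA[ref_aa])
  subs <- substitution_scores(ref_aa, alt_aa, sneath)
  aix <- aaindex_descriptors(ref_aa, alt_aa)
  out <- c(ddg = ddg, ddsvib = ddsvib, sasa_ratio = ratio,
           pssm_variant = unname(pssm_score(pssm, pos, alt_aa)),
           pssm_self = unname(pssm_score(pssm, pos, ref_aa)),
           sneath = unname(subs["sneath"]), grantham = unname(subs["grantham"]),
           blosum62 = unname(subs["blosum62"]),
           volume_delta = unname(aix["volume_delta"]),
           hydrophobicity_delta = unname(aix["hydrophobicity_delta"]),
           total_sasa_delta = abs_sasa * (ratio - 1),
           rsa_ref = unname(abs_sasa / MAX_SASA[ref_aa]))
  stopifnot(identical(names(out), feature_names()), all(is.finite(out)))
  out
}
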
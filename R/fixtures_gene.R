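# Deterministic gene-model, VCF and training-set generators.

#' Synthesize a toy gene model for a protein sequence
#'
#' Chooses a synonymous codon per residue (seeded), lays the coding sequence
#' on GRCh37-style coordinates with a single intron gap in the middle, and
#' derives labeled single-nucleotide variants (known missense / synonymous /
#' nonsense outcomes) for mapping tests. Minus-strand models store descending
#' translation-order coordinates and complemented genomic bases, exactly as a
#' real minus-strand transcript would.
#'
#' @param protein_seq one-letter protein sequence (standard amino acids)
#' @param strand "+" or "-"
#' @param seed integer seed
#' @param chrom chromosome label (default "1")
#' @param start first genomic coordinate of the gene footprint (default 5000)
#' @param intron_gap gap in bp inserted between the two "exons" (default 50)
#' @return list with `gene_model` (a `vs_gene_model`), `protein_seq`, `cds`
#'   (coding sequence in translation order), and `variants` (data.frame:
#'   `chrom`, `pos`, `ref`, `alt`, `expected_status`, `protein_pos`)
#' @export
make_toy_gene <- function(protein_seq, strand = "+", seed = 1,
                          chrom = "1", start = 5000, intron_gap = 50) {
  aa <- strsplit(protein_seq, "")[[1]]
  .check_aa(aa, "protein_seq")
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  codons <- vapply(aa, function(a) {
    syn <- names(gc)[gc == a]
    syn[sample(length(syn), 1)]
  }, character(1))
  n <- length(aa)
  L <- 3L * n
  gap_after <- 3L * (n %/% 2L)  # intron after this CDS base
  gpos_plus <- start + seq_len(L) - 1L + ifelse(seq_len(L) > gap_after, intron_gap, 0L)
  # translation-order CDS index -> genomic coordinate
  coord_of <- if (strand == "+") gpos_plus else rev(gpos_plus)
  map <- data.frame(protein_pos = seq_len(n), aa = aa,
                    g1 = coord_of[3 * seq_len(n) - 2],
                    g2 = coord_of[3 * seq_len(n) - 1],
                    g3 = coord_of[3 * seq_len(n)],
                    codon = unname(codons), stringsAsFactors = FALSE)
  gm <- new_gene_model("TOYGENE", strand, chrom, map)

  # labeled variant sets: scan single-base changes of each codon
  vars <- NULL
  for (i in seq_len(n)) {
    cdn <- strsplit(codons[i], "")[[1]]
    found <- c(missense = FALSE, synonymous = FALSE, nonsense = FALSE)
    for (k in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == cdn[k]) next
      new <- cdn; new[k] <- b
      na <- unname(gc[paste(new, collapse = "")])
      status <- if (na == aa[i]) "synonymous" else if (na == "*") "nonsense" else "missense"
      if (found[status]) next
      found[status] <- TRUE
      gp <- coord_of[3 * (i - 1) + k]
      ref <- if (strand == "+") cdn[k] else .COMPLEMENT(cdn[k])
      alt <- if (strand == "+") b else .COMPLEMENT(b)
      vars <- rbind(vars, data.frame(chrom = chrom, pos = gp, ref = ref,
                                     alt = alt, expected_status = status,
                                     protein_pos = i, stringsAsFactors = FALSE))
    }
  }
  rownames(vars) <- NULL
  list(gene_model = gm, protein_seq = protein_seq,
       cds = paste(codons, collapse = ""), variants = vars)
}

#' Write variants as a minimal plain-text VCF v4.2 file
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#' @param path output path (conventionally `<GENESYMBOL>.vcf`)
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##reference=GRCh37",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     sep = "\t")), con)
  if (nrow(variants)) {
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic PSI-BLAST-style ASCII PSSM for a sequence
#'
#' The self-substitution column gets a high log-odds score, all others small
#' seeded integers — structurally a valid PSSM file for [read_pssm()].
#'
#' @param protein_seq one-letter sequence
#' @param path output path
#' @param seed integer seed
#' @export
write_synthetic_pssm <- function(protein_seq, path, seed = 1) {
  aa <- strsplit(protein_seq, "")[[1]]
  .check_aa(aa)
  set.seed(seed)
  cols <- unname(AA3)
  lines <- c("",
             "Last position-specific scoring matrix computed, weighted, and scaled",
             paste0("            ", paste(sprintf("%3s", cols), collapse = "")))
  for (i in seq_along(aa)) {
    sc <- sample(-3:2, 20, replace = TRUE)
    names(sc) <- cols
    sc[aa[i]] <- sample(4:7, 1)
    lines <- c(lines, paste0(sprintf("%5d %s  ", i, aa[i]),
                             paste(sprintf("%3d", sc), collapse = "")))
  }
  writeLines(c(lines, ""), path)
  invisible(path)
}

#' Simulate a training set of mutations with experimental stability changes
#'
#' Emulates the structure of a curated ddG compilation: each record is one
#' single-residue mutation with an experimental ddG (kcal/mol) and the 12
#' model features. Neutral records draw ddG uniformly inside (-0.45, 0.45),
#' high-impact records draw |ddG| from 0.55 + Exp(mean 1.5) truncated at 12,
#' matching the spread of published compilations. With probability
#' `label_noise` the experimental ddG is redrawn from the opposite class
#' (emulating measurement/curation error), so the stored label — always
#' derived from the stored ddG — disagrees with what the features support.
#' The ddG *feature* is the true value plus Gaussian noise of sd
#' `feature_noise`.
#'
#' @param n number of records (>= 50)
#' @param seed integer seed (same seed gives identical output)
#' @param label_noise probability of class-contradicting experimental ddG
#' @param feature_noise sd (kcal/mol) of the computed-ddG feature error
#' @param class_balance fraction of high-impact records before noise
#' @param path optional CSV output path
#' @return data.frame with columns `protein_id`, `ref_aa`, `pos`, `alt_aa`,
#'   `ddg_exp`, `label`, and the 12 feature columns of [feature_names()]
#' @export
simulate_training_set <- function(n, seed = 1, label_noise = 0.1,
                                  feature_noise = 0.1, class_balance = 0.5,
                                  path = NULL) {
  if (n < 50) stop("n must be >= 50")
  set.seed(seed)
  draw_high <- function(k) {
    s <- sample(c(-1, 1), k, replace = TRUE)
    s * pmin(0.55 + stats::rexp(k, rate = 1 / 1.5), 12)
  }
  draw_neutral <- function(k) stats::runif(k, -0.45, 0.45)
  is_high <- stats::runif(n) < class_balance
  true_ddg <- numeric(n)
  true_ddg[is_high] <- draw_high(sum(is_high))
  true_ddg[!is_high] <- draw_neutral(sum(!is_high))
  # class-contradicting experimental values
  flip <- stats::runif(n) < label_noise
  ddg_exp <- true_ddg
  ddg_exp[flip & is_high] <- draw_neutral(sum(flip & is_high))
  ddg_exp[flip & !is_high] <- draw_high(sum(flip & !is_high))

  aa <- unname(AA3)
  ref_aa <- sample(aa, n, replace = TRUE)
  alt_aa <- vapply(ref_aa, function(r) sample(setdiff(aa, r), 1), character(1))
  z <- ifelse(is_high, 1, -1)
  gm <- grantham_matrix(); bm <- blosum62_matrix(); sm <- sneath_matrix_synthetic()
  vol <- aa_volume(); hyd <- aa_hydrophobicity()
  feats <- data.frame(
    ddg = true_ddg + stats::rnorm(n, 0, feature_noise),
    ddsvib = stats::rnorm(n, 0.2 * z, 0.5),
    sasa_ratio = MAX_SASA[alt_aa] / MAX_SASA[ref_aa],
    pssm_variant = round(stats::rnorm(n, -1 - z, 2)),
    pssm_self = round(stats::rnorm(n, 4, 1.5)),
    sneath = sm[cbind(ref_aa, alt_aa)],
    grantham = gm[cbind(ref_aa, alt_aa)],
    blosum62 = bm[cbind(ref_aa, alt_aa)],
    volume_delta = unname(vol[alt_aa] - vol[ref_aa]),
    hydrophobicity_delta = unname(hyd[alt_aa] - hyd[ref_aa]),
    total_sasa_delta = stats::rnorm(n, 0, 20),
    rsa_ref = stats::runif(n, 0, 1))
  out <- cbind(data.frame(protein_id = sprintf("PROT%02d", sample(1:20, n, replace = TRUE)),
                          ref_aa = ref_aa, pos = sample(1:300, n, replace = TRUE),
                          alt_aa = alt_aa, ddg_exp = round(ddg_exp, 4),
                          label = label_from_ddg(round(ddg_exp, 4)),
                          stringsAsFactors = FALSE),
               round(feats, 4))
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Read a training CSV of mutations with experimental ddG values
#'
#' Schema: `protein_id`, `ref_aa`, `pos`, `alt_aa`, `ddg_exp`, optionally a
#' `label` column and precomputed feature columns. The binary label is always
#' (re)derived from `ddg_exp` via [label_from_ddg()]; a stored label that
#' disagrees is an error.
#'
#' @param path CSV path
#' @return data.frame with a `label` column and any feature columns present
#' @export
read_training_csv <- function(path) {
  if (!file.exists(path)) stop("training CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "ref_aa", "pos", "alt_aa", "ddg_exp")
  if (!all(need %in% names(df)))
    stop("training CSV missing columns: ", paste(setdiff(need, names(df)), collapse = ","))
  lab <- label_from_ddg(df$ddg_exp)
  if ("label" %in% names(df) && !all(df$label == lab))
    stop("stored labels disagree with the ddG labeling rule at rows: ",
         paste(utils::head(which(df$label != lab)), collapse = ","))
  df$label <- lab
  df
}
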
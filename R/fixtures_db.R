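# Generator for a complete per-gene database directory, so end-to-end runs
# need no external downloads.

#' Build a synthetic per-gene database directory
#'
#' Creates `<db_dir>/<gene>/` with all components [annotate_gene()] consumes:
#' a helix-fold structure covering a prefix of the protein (so positions past
#' the coverage exercise the non-processed path), the reference sequence, a
#' codon map from [make_toy_gene()], a synthetic PSSM, an FTMap-style
#' drug-hotspot table, and precomputed hotspot patches from an alanine scan.
#' Deterministic for a fixed seed.
#'
#' @param db_dir database root directory
#' @param gene gene symbol (also names the subdirectory)
#' @param protein_seq one-letter protein sequence; default a seeded 18-mer
#' @param strand "+" or "-"
#' @param seed integer seed
#' @param coverage fraction of the protein covered by the structure
#'   (default 0.75)
#' @param chrom,start genomic placement of the toy gene
#' @return list: `dir`, `gene_model`, `structure`, `variants` (the labeled
#'   variant set of the toy gene)
#' @export
make_gene_db <- function(db_dir, gene, protein_seq = NULL, strand = "+",
                         seed = 1, coverage = 0.75, chrom = "1", start = 5000) {
  set.seed(seed)
  if (is.null(protein_seq))
    protein_seq <- paste(sample(unname(AA3), 18, replace = TRUE), collapse = "")
  dir <- file.path(db_dir, gene)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- nchar(protein_seq)
  ncov <- max(6L, min(L, ceiling(coverage * L)))
  toy <- make_toy_gene(protein_seq, strand = strand, seed = seed,
                       chrom = chrom, start = start)
  toy$gene_model$gene_symbol <- gene

  struct <- make_structure("helix", n_residues = ncov, seed = seed,
                           sequence = substr(protein_seq, 1, ncov),
                           path = file.path(dir, "structure.pdb"))
  seqs <- Biostrings::AAStringSet(stats::setNames(protein_seq, gene))
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequence.fasta"))
  write_codon_map(toy$gene_model, file.path(dir, "codon_map.tsv"))
  write_synthetic_pssm(protein_seq, file.path(dir, "pssm.txt"), seed = seed)

  npos <- sample(seq_len(L), max(3, L %/% 4))
  ftmap <- data.frame(protein_pos = sort(npos),
                      z_score = round(stats::rnorm(length(npos), 1, 0.8), 3),
                      percentile = round(stats::runif(length(npos), 40, 100), 1),
                      n_hits = stats::rpois(length(npos), 4))
  utils::write.csv(ftmap, file.path(dir, "ftmap.csv"), row.names = FALSE)

  scan <- alanine_scan(struct)
  patches <- find_hotspot_patches(scan, struct)
  utils::write.csv(patches, file.path(dir, "hotspots.csv"), row.names = FALSE)

  list(dir = dir, gene_model = toy$gene_model, structure = struct,
       variants = toy$variants)
}
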
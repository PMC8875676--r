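# Gene models, VCF input, and genome-to-protein mapping (GRCh37, 1-based).
#
# A gene model is one transcript's codon map: for every 1-based protein
# position, the three GRCh37 genomic coordinates of its codon in translation
# order, the reference codon (coding-strand bases) and the reference amino
# acid. Minus-strand genes store descending genomic coordinates; the codon
# string is always in translation order (i.e. already reverse-complemented
# relative to the + strand of the assembly).

.COMPLEMENT <- function(x) chartr("ACGT", "TGCA", x)

.translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

#' Construct a gene model
#'
#' @param gene_symbol HGNC-style gene symbol
#' @param strand "+" or "-"
#' @param chrom chromosome label
#' @param map data.frame with columns `protein_pos`, `aa`, `g1`, `g2`, `g3`
#'   (genomic coordinates in translation order), `codon`
#' @return object of class `vs_gene_model`
#' @export
new_gene_model <- function(gene_symbol, strand, chrom, map) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(map))
  need <- c("protein_pos", "aa", "g1", "g2", "g3", "codon")
  if (!all(need %in% names(map)))
    stop("codon map missing columns: ", paste(setdiff(need, names(map)), collapse = ","))
  if (any(nchar(map$codon) != 3)) stop("codons must have length 3")
  map <- map[order(map$protein_pos), , drop = FALSE]
  rownames(map) <- NULL
  structure(list(gene_symbol = gene_symbol, strand = strand,
                 chrom = as.character(chrom), map = map),
            class = "vs_gene_model")
}

#' @export
print.vs_gene_model <- function(x, ...) {
  cat(sprintf("<vs_gene_model> %s (%s strand, chr%s): %d codons, protein %d aa\n",
              x$gene_symbol, x$strand, x$chrom, nrow(x$map), nrow(x$map)))
  invisible(x)
}

#' Write a gene model as a tab-separated codon map file
#'
#' Columns: protein_pos, aa, strand, chrom, g1, g2, g3, codon.
#' @param gm a `vs_gene_model`
#' @param path output TSV path
#' @export
write_codon_map <- function(gm, path) {
  df <- data.frame(protein_pos = gm$map$protein_pos, aa = gm$map$aa,
                   strand = gm$strand, chrom = gm$chrom,
                   g1 = gm$map$g1, g2 = gm$map$g2, g3 = gm$map$g3,
                   codon = gm$map$codon, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon map TSV into a gene model
#' @param path TSV written by [write_codon_map()]
#' @param gene_symbol gene symbol (defaults to the file name stem)
#' @export
read_codon_map <- function(path, gene_symbol = NULL) {
  if (!file.exists(path)) stop("codon map not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(codon = "character", aa = "character",
                                         strand = "character", chrom = "character"))
  if (is.null(gene_symbol))
    gene_symbol <- sub("\\.tsv$", "", basename(path))
  new_gene_model(gene_symbol, unique(df$strand)[1], unique(df$chrom)[1], df)
}

#' Read genomic variants from a plain-text VCF
#'
#' The file must be an uncompressed VCF named `<GENESYMBOL>.vcf`; multi-
#' allelic rows are split into one record per ALT allele. Header lines are
#' preserved as the `meta` attribute for provenance.
#'
#' @param path VCF file path
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   attributes `gene` (from the file name) and `meta`
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  magic <- readBin(path, "raw", n = 2)
  if (length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    stop("compressed VCF detected (gzip magic bytes); an uncompressed plain-text VCF is required: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-row VCF comes back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  out <- data.frame(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    stringsAsFactors = FALSE)
  if (nrow(fix)) {
    pos <- suppressWarnings(as.integer(fix$POS))
    if (any(is.na(pos)))
      stop("malformed VCF row (non-numeric POS) at data line ",
           which(is.na(pos))[1], " of ", path)
    alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
    nall <- lengths(alts)
    out <- data.frame(chrom = rep(fix$CHROM, nall), pos = rep(pos, nall),
                      ref = toupper(rep(fix$REF, nall)),
                      alt = toupper(unlist(alts)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "gene") <- sub("\\.vcf$", "", basename(path))
  attr(out, "meta") <- v@meta
  out
}

#' Map a genomic variant onto the protein
#'
#' Classifies a single-nucleotide variant against a gene model: substitution
#' inside a codon is translated (reverse-complemented for minus-strand genes)
#' and classified missense / synonymous / nonsense; positions outside every
#' codon are `non_coding`; anything that is not an A/C/G/T SNV is
#' `unsupported` (reported but not annotated).
#'
#' @param chrom,pos,ref,alt the variant (GRCh37, 1-based)
#' @param gm a `vs_gene_model`
#' @return one-row data.frame: `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `status`
#' @export
map_variant <- function(chrom, pos, ref, alt, gm) {
  out <- data.frame(gene = gm$gene_symbol, chrom = as.character(chrom),
                    pos = as.integer(pos), ref = ref, alt = alt,
                    protein_pos = NA_integer_, ref_aa = NA_character_,
                    alt_aa = NA_character_, status = NA_character_,
                    stringsAsFactors = FALSE)
  snv <- nchar(ref) == 1 && nchar(alt) == 1 &&
    grepl("^[ACGT]$", ref) && grepl("^[ACGT]$", alt)
  if (!snv) { out$status <- "unsupported"; return(out) }
  if (as.character(chrom) != gm$chrom) { out$status <- "non_coding"; return(out) }
  m <- gm$map
  hit <- which(m$g1 == pos | m$g2 == pos | m$g3 == pos)
  if (!length(hit)) { out$status <- "non_coding"; return(out) }
  row <- m[hit[1], ]
  k <- which(c(row$g1, row$g2, row$g3) == pos)[1]
  codon <- strsplit(row$codon, "")[[1]]
  expected <- if (gm$strand == "+") codon[k] else .COMPLEMENT(codon[k])
  if (expected != ref)
    stop(sprintf("reference mismatch at %s:%d (gene %s): VCF ref '%s' but codon map implies '%s'",
                 chrom, pos, gm$gene_symbol, ref, expected))
  codon[k] <- if (gm$strand == "+") alt else .COMPLEMENT(alt)
  new_codon <- paste(codon, collapse = "")
  ref_aa <- .translate_codon(row$codon)
  alt_aa <- .translate_codon(new_codon)
  out$protein_pos <- row$protein_pos
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out$status <- if (alt_aa == ref_aa) "synonymous"
                else if (alt_aa == "*") "nonsense"
                else "missense"
  out
}

#' Map every record of a VCF data.frame
#' @param variants data.frame from [read_vcf()]
#' @param gm a `vs_gene_model`
#' @return data.frame with one row per input record (see [map_variant()])
#' @export
map_variants <- function(variants, gm) {
  if (!nrow(variants)) {
    return(map_variant("0", 1L, "A", "C", gm)[0, ])
  }
  do.call(rbind, lapply(seq_len(nrow(variants)), function(r) {
    map_variant(variants$chrom[r], variants$pos[r],
                variants$ref[r], variants$alt[r], gm)
  }))
}

#' Quality-check a gene model against the protein reference sequence
#'
#' Verifies that every stored codon translates to the stored amino acid and
#' to the reference sequence at that position, and that genomic coordinates
#' are unique across codons.
#'
#' @param gm a `vs_gene_model`
#' @param protein_seq protein reference sequence (one-letter string)
#' @return list with `ok` (logical) and `failures` (data.frame:
#'   `protein_pos`, `check`, `detail`)
#' @export
validate_codon_map <- function(gm, protein_seq) {
  seq_aa <- strsplit(protein_seq, "")[[1]]
  fails <- data.frame(protein_pos = integer(), check = character(),
                      detail = character(), stringsAsFactors = FALSE)
  add <- function(pos, check, detail) {
    rbind(fails, data.frame(protein_pos = pos, check = check, detail = detail,
                            stringsAsFactors = FALSE))
  }
  m <- gm$map
  for (r in seq_len(nrow(m))) {
    tr <- .translate_codon(m$codon[r])
    pos <- m$protein_pos[r]
    if (is.na(tr) || tr != m$aa[r])
      fails <- add(pos, "codon_translation",
                   sprintf("codon %s translates to %s, stored aa %s", m$codon[r], tr, m$aa[r]))
    if (pos > length(seq_aa) || (!is.na(tr) && tr != seq_aa[pos]))
      fails <- add(pos, "sequence_match",
                   sprintf("translated %s but reference sequence has %s",
                           tr, if (pos <= length(seq_aa)) seq_aa[pos] else "<out of range>"))
  }
  coords <- c(m$g1, m$g2, m$g3)
  dup <- unique(coords[duplicated(coords)])
  for (d in dup)
    fails <- add(m$protein_pos[m$g1 == d | m$g2 == d | m$g3 == d][1],
                 "coordinate_uniqueness", sprintf("genomic coordinate %d used more than once", d))
  if (nrow(m) != length(seq_aa))
    fails <- add(NA_integer_, "length_match",
                 sprintf("codon map has %d positions, sequence has %d", nrow(m), length(seq_aa)))
  list(ok = nrow(fails) == 0, failures = fails)
}

#' Protein position of a genomic coordinate (round-trip helper)
#' @param pos genomic coordinate
#' @param gm a `vs_gene_model`
#' @return protein position or NA when the coordinate is non-coding
#' @export
genomic_to_protein <- function(pos, gm) {
  m <- gm$map
  hit <- which(m$g1 == pos | m$g2 == pos | m$g3 == pos)
  if (!length(hit)) NA_integer_ else m$protein_pos[hit[1]]
}
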
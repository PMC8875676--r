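# Per-gene annotation orchestration and CSV/HTML report output.
#
# The per-gene database directory layout (produced by an auxiliary
# preparation step or by make_gene_db()) is fixed:
#   <dbhome>/<GENE>/structure.pdb   protein structure (author numbering =
#                                   protein reference numbering)
#   <dbhome>/<GENE>/sequence.fasta  protein reference sequence
#   <dbhome>/<GENE>/codon_map.tsv   genome<->protein codon map
#   <dbhome>/<GENE>/pssm.txt        PSI-BLAST ASCII PSSM
#   <dbhome>/<GENE>/ftmap.csv       optional drug-hotspot summary
#                                   (protein_pos, z_score, percentile, n_hits)
#   <dbhome>/<GENE>/hotspots.csv    optional precomputed hotspot patches
#                                   (protein_pos, ref_aa, ddg, patch_id)

.report_columns <- function() {
  c("gene", "chrom", "pos", "ref", "alt", "protein_pos", "ref_aa", "alt_aa",
    "status", feature_names(), "flags", "patch_id",
    "z_score", "percentile", "n_hits", "pred_class", "p_high_impact", "note")
}

.empty_record <- function() {
  cols <- .report_columns()
  out <- as.data.frame(stats::setNames(rep(list(NA), length(cols)), cols))
  out$flags <- ""
  out
}

#' Annotate all variants of one gene VCF against its database directory
#'
#' Runs the full pipeline per variant: genome-to-protein mapping; for covered
#' missense variants the reference-structure context (SASA, secondary
#' structure, disulfides, salt bridges), the stability change, the
#' vibrational-entropy change, the structural-event rules, the 12-feature
#' vector, the classifier prediction, and hotspot/drug-site membership.
#' Non-missense and uncovered variants are reported with their status only —
#' every input ALT allele yields exactly one output record.
#'
#' @param vcf_path plain-text VCF named `<GENESYMBOL>.vcf`
#' @param db_dir per-gene database directory (see layout above)
#' @param model optional `vs_rf_model` for class prediction
#' @param ddg_weights weight vector for [builtin_ddg()]
#' @return data.frame of annotation records (one per ALT allele) with
#'   attribute `gene`
#' @export
annotate_gene <- function(vcf_path, db_dir, model = NULL,
                          ddg_weights = ddg_weights_default()) {
  gene <- sub("\\.vcf$", "", basename(vcf_path))
  req <- c(structure = "structure.pdb", sequence = "sequence.fasta",
           codon_map = "codon_map.tsv", pssm = "pssm.txt")
  paths <- file.path(db_dir, req)
  names(paths) <- names(req)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("database for gene ", gene, " is missing components: ",
         paste(req[missing], collapse = ", "), " (in ", db_dir, ")")

  seq_set <- Biostrings::readAAStringSet(paths["sequence"])
  protein_seq <- as.character(seq_set[[1]])
  gm <- read_codon_map(paths["codon_map"], gene_symbol = gene)
  qc <- validate_codon_map(gm, protein_seq)
  if (!qc$ok)
    stop("codon map QC failed for gene ", gene, ": ",
         nrow(qc$failures), " failure(s), first: ", qc$failures$detail[1])
  struct <- read_pdb(paths["structure"])
  sasa <- shrake_rupley_sasa(struct)
  ss <- suppressWarnings(assign_secondary_structure(struct))
  disulf <- detect_disulfides(struct)
  salt <- detect_salt_bridges(struct)
  pssm <- read_pssm(paths["pssm"], expected_seq = protein_seq)

  hotspot_path <- file.path(db_dir, "hotspots.csv")
  hotspots <- if (file.exists(hotspot_path)) {
    utils::read.csv(hotspot_path, stringsAsFactors = FALSE)
  } else {
    find_hotspot_patches(alanine_scan(struct), struct)
  }
  ftmap_path <- file.path(db_dir, "ftmap.csv")
  ftmap <- if (file.exists(ftmap_path)) {
    read_ftmap(ftmap_path, protein_length = nchar(protein_seq))
  } else NULL

  variants <- read_vcf(vcf_path)
  covered <- covered_positions(struct)
  records <- lapply(seq_len(nrow(variants)), function(r) {
    rec <- .empty_record()
    rec$gene <- gene
    rec$chrom <- variants$chrom[r]; rec$pos <- variants$pos[r]
    rec$ref <- variants$ref[r]; rec$alt <- variants$alt[r]
    mapped <- tryCatch(map_variant(variants$chrom[r], variants$pos[r],
                                   variants$ref[r], variants$alt[r], gm),
                       error = function(e) e)
    if (inherits(mapped, "error")) {
      rec$status <- "non_processed"
      rec$note <- conditionMessage(mapped)
      return(rec)
    }
    rec$protein_pos <- mapped$protein_pos
    rec$ref_aa <- mapped$ref_aa; rec$alt_aa <- mapped$alt_aa
    rec$status <- mapped$status
    if (mapped$status != "missense") return(rec)
    if (!(mapped$protein_pos %in% covered)) {
      rec$status <- "non_processed"
      rec$note <- "position not covered by the protein structure"
      return(rec)
    }
    ann <- tryCatch({
      ddg <- builtin_ddg(struct, mapped$protein_pos, mapped$ref_aa,
                         mapped$alt_aa, sasa, ss, ddg_weights)
      ddsvib <- delta_delta_svib(struct, mapped$protein_pos, mapped$alt_aa)
      fv <- assemble_features(mapped$protein_pos, mapped$ref_aa, mapped$alt_aa,
                              ddg, ddsvib, sasa, pssm)
      rules <- evaluate_rules(struct, sasa, ss, disulf, salt,
                              mapped$protein_pos, mapped$ref_aa, mapped$alt_aa)
      list(fv = fv, rules = rules)
    }, error = function(e) e)
    if (inherits(ann, "error")) {
      rec$status <- "non_processed"
      rec$note <- conditionMessage(ann)
      return(rec)
    }
    rec[, feature_names()] <- as.list(ann$fv)
    rec$flags <- paste(ann$rules$fired, collapse = ";")
    hs <- hotspots[hotspots$protein_pos == mapped$protein_pos, , drop = FALSE]
    if (nrow(hs)) rec$patch_id <- hs$patch_id[1]
    if (!is.null(ftmap)) {
      ft <- ftmap[ftmap$protein_pos == mapped$protein_pos, , drop = FALSE]
      if (nrow(ft)) {
        rec$z_score <- ft$z_score[1]; rec$percentile <- ft$percentile[1]
        rec$n_hits <- ft$n_hits[1]
      }
    }
    if (!is.null(model)) {
      pr <- predict(model, rec)
      rec$pred_class <- pr$class; rec$p_high_impact <- pr$p_high_impact
    }
    rec$status <- "annotated"
    rec
  })
  out <- if (length(records)) do.call(rbind, records) else .empty_record()[0, ]
  rownames(out) <- NULL
  attr(out, "gene") <- gene
  out
}

#' Read an FTMap-style drug-hotspot summary table
#'
#' @param path CSV with columns `protein_pos` (or `position`), `z_score`,
#'   `percentile`, `n_hits`
#' @param protein_length optional length bound for validation
#' @return data.frame
#' @export
read_ftmap <- function(path, protein_length = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("position" %in% names(df) && !("protein_pos" %in% names(df)))
    names(df)[names(df) == "position"] <- "protein_pos"
  need <- c("protein_pos", "z_score", "percentile", "n_hits")
  if (!all(need %in% names(df)))
    stop("drug-hotspot table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ","))
  if (any(df$n_hits < 0)) stop("negative probe-hit counts in ", path)
  if (!is.null(protein_length) && any(df$protein_pos > protein_length))
    stop("drug-hotspot positions exceed protein length in ", path)
  df
}

#' Write CSV and HTML reports for one gene
#'
#' The CSV carries every annotation field in documented column order; the
#' HTML report summarizes each variant with red-flag badges, the
#' genome-protein linkage and drug-binding statistics, and embeds an SVG
#' lolliplot of ddG and ddSvib per position (with the underlying values as
#' JSON). Output is deterministic for fixed input.
#'
#' @param records data.frame from [annotate_gene()]
#' @param out_dir output directory (created if needed)
#' @param gene gene symbol (default: the records' `gene` attribute)
#' @return named character vector with `csv` and `html` paths
#' @export
write_reports <- function(records, out_dir, gene = attr(records, "gene")) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  }
  csv_path <- file.path(out_dir, paste0(gene, ".csv"))
  html_path <- file.path(out_dir, paste0(gene, ".html"))
  df <- records[, .report_columns(), drop = FALSE]
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  writeLines(.render_html(df, gene), html_path)
  c(csv = csv_path, html = html_path)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.lolliplot_svg <- function(df, value_col, title, color) {
  ann <- df[!is.na(df$protein_pos) & !is.na(df[[value_col]]), , drop = FALSE]
  w <- 640; h <- 160; pad <- 36
  if (!nrow(ann)) return(sprintf("<p>No %s data.</p>", title))
  xmax <- max(ann$protein_pos, 10)
  vmax <- max(abs(ann[[value_col]]), 1e-6)
  x <- pad + (w - 2 * pad) * ann$protein_pos / xmax
  y0 <- h / 2
  y <- y0 - (h / 2 - pad / 2) * ann[[value_col]] / vmax
  stems <- sprintf(
    '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s"/><circle cx="%.1f" cy="%.1f" r="4" fill="%s"><title>%s%d%s: %s = %.3f</title></circle>',
    x, y0, x, y, color, x, y, color,
    ann$ref_aa, ann$protein_pos, ann$alt_aa, value_col, ann[[value_col]])
  paste0('<h3>', title, '</h3><svg width="', w, '" height="', h,
         '" role="img"><line x1="', pad, '" y1="', y0, '" x2="', w - pad,
         '" y2="', y0, '" stroke="#999"/>', paste(stems, collapse = ""), "</svg>")
}

.render_html <- function(df, gene) {
  badge <- function(flags) {
    if (is.na(flags) || !nzchar(flags)) return("")
    paste(sprintf('<span class="flag">%s</span>', .html_escape(strsplit(flags, ";")[[1]])),
          collapse = " ")
  }
  fmt <- function(x, digits = 3) ifelse(is.na(x), "", formatC(x, digits = digits, format = "fg"))
  rows <- vapply(seq_len(nrow(df)), function(r) {
    d <- df[r, ]
    sprintf("<tr><td>%s:%s %s&gt;%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s / %s / %s</td></tr>",
            .html_escape(as.character(d$chrom)), fmt(d$pos, 10), d$ref, d$alt,
            ifelse(is.na(d$protein_pos), "",
                   sprintf("%s%d%s", d$ref_aa, d$protein_pos, d$alt_aa)),
            .html_escape(d$status), badge(d$flags),
            fmt(d$ddg), fmt(d$ddsvib),
            ifelse(is.na(d$pred_class), "",
                   sprintf("%s (p=%.2f)", d$pred_class, d$p_high_impact)),
            fmt(d$z_score), fmt(d$percentile), fmt(d$n_hits, 10))
  }, character(1))
  ann <- df[!is.na(df$ddg), , drop = FALSE]
  json <- if (nrow(ann)) {
    paste0("[", paste(sprintf('{"pos":%d,"sub":"%s%d%s","ddg":%.4f,"ddsvib":%.6f}',
                              ann$protein_pos, ann$ref_aa, ann$protein_pos,
                              ann$alt_aa, ann$ddg, ann$ddsvib), collapse = ","), "]")
  } else "[]"
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s variant annotation</title>", .html_escape(gene)),
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:4px 8px;font-size:13px}",
    ".flag{background:#c0392b;color:#fff;border-radius:3px;padding:1px 5px;font-size:11px;margin-right:2px}",
    "</style></head><body>",
    sprintf("<h1>%s</h1>", .html_escape(gene)),
    sprintf("<p>%d variant record(s); %d annotated, %d with red flags.</p>",
            nrow(df), sum(df$status == "annotated", na.rm = TRUE),
            sum(nzchar(df$flags) & !is.na(df$flags))),
    "<table><tr><th>Genomic</th><th>Protein</th><th>Status</th><th>Red flags</th>",
    "<th>ddG (kcal/mol)</th><th>ddSvib</th><th>Prediction</th><th>Drug site z / pct / hits</th></tr>",
    rows, "</table>",
    .lolliplot_svg(df, "ddg", "Stability change (ddG) lolliplot", "#2980b9"),
    .lolliplot_svg(df, "ddsvib", "Vibrational entropy change (ddSvib) lolliplot", "#8e44ad"),
    sprintf("<script>var variantData = %s;</script>", json),
    "</body></html>")
}
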
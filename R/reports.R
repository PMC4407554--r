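#' Write marker design / ePCR reports
#'
#' Writes the fixed-column primer pair TSV, amplicons as BED6, and a full
#' JSON dump. Row order is deterministic (rank, then pair id); re-running on
#' identical input reproduces the files byte-identically.
#'
#' @param results A `marker_design` object, or a list with any of `pairs`
#'   (tibble), `ehtpcr` (`ehtpcr_result`), `gene_a`, `gene_b`, `meta`.
#' @param out_dir Output directory (created if needed).
#' @param page_size Report page size; `primer_pairs_page1.tsv` holds the
#'   top-scoring `min(page_size, n)` pairs.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_reports <- function(results, out_dir, page_size = 60L) {
  if (inherits(results, "marker_design"))
    results <- list(pairs = results$pairs, gene_a = results$gene_a,
                    gene_b = results$gene_b)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  pairs <- results$pairs %||% empty_pairs()
  files <- c()

  tab <- pair_report_table(pairs, results$gene_a %||% "gene_a",
                           results$gene_b %||% "gene_b")
  f <- file.path(out_dir, "primer_pairs.tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["pairs_tsv"] <- f
  f1 <- file.path(out_dir, "primer_pairs_page1.tsv")
  write.table(head(tab, page_size), f1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["pairs_page1_tsv"] <- f1

  amp <- if (!is.null(results$ehtpcr)) results$ehtpcr$amplicons else NULL
  fbed <- file.path(out_dir, "amplicons.bed")
  writeLines(amplicon_bed_lines(amp), fbed)
  files["amplicons_bed"] <- fbed

  dump <- list(pairs = tab,
               ehtpcr = if (!is.null(results$ehtpcr))
                 results$ehtpcr$report else NULL,
               meta = results$meta)
  fjson <- file.path(out_dir, "result.json")
  jsonlite::write_json(dump, fjson, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files["json"] <- fjson
  invisible(files)
}

# fixed-column report table, ordered by (rank, pair_id)
pair_report_table <- function(pairs, gene_a, gene_b) {
  if (nrow(pairs) == 0L) {
    return(data.frame(pair_id = character(0), gene_a = character(0),
                      gene_b = character(0), fw_seq = character(0),
                      rv_seq = character(0), fw_tm = numeric(0),
                      rv_tm = numeric(0), fw_mismatches = integer(0),
                      rv_mismatches = integer(0), product_size_a = integer(0),
                      product_size_b = integer(0),
                      introns_spanned_a = integer(0),
                      introns_spanned_b = integer(0), score = numeric(0),
                      rank = integer(0)))
  }
  o <- order(pairs$rank, pairs$pair_id)
  p <- pairs[o, , drop = FALSE]
  data.frame(
    pair_id = p$pair_id, gene_a = gene_a, gene_b = gene_b,
    fw_seq = p$fw_seq, rv_seq = p$rv_seq,
    fw_tm = round(p$fw_tm, 2), rv_tm = round(p$rv_tm, 2),
    fw_mismatches = p$fw_n_mismatch, rv_mismatches = p$rv_n_mismatch,
    product_size_a = p$product_size_a, product_size_b = p$product_size_b,
    introns_spanned_a = p$introns_spanned_a,
    introns_spanned_b = p$introns_spanned_b,
    score = round(p$score, 3), rank = p$rank)
}

# BED6 lines, one per amplicon: name = pair id, score = total mismatches
amplicon_bed_lines <- function(amp) {
  if (is.null(amp) || nrow(amp) == 0L) return(character(0))
  o <- order(amp$genome_id %||% "", amp$chrom, amp$start, amp$end, amp$pair_id)
  a <- amp[o, , drop = FALSE]
  sprintf("%s\t%d\t%d\t%s\t%d\t%s",
          a$chrom, a$start, a$end, a$pair_id, a$total_mismatches,
          a$orientation)
}
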
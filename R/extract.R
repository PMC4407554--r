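#' Extract a gene's genomic and spliced CDS sequence
#'
#' Cuts the gene span (plus optional flank) out of its chromosome, reorients
#' it onto the coding strand, and splices the CDS. Exon blocks are expressed
#' in local coordinates of the returned genomic string, so all downstream
#' coordinates are strand-agnostic.
#'
#' @param model A [gene_model].
#' @param genome A named `DNAStringSet` containing the model's chromosome.
#' @param flank Non-negative flank (bp) added on both sides; clipped at
#'   chromosome ends. Primers are always exonic, so the flank is contextual
#'   display sequence only.
#' @param cds_only If `TRUE` (default) exon blocks cover CDS intervals only;
#'   otherwise full exons are used (UTR included) and the "CDS" is the
#'   spliced exon sequence.
#' @return A `gene_sequences` list: `gene_id`, `genomic` (coding strand),
#'   `cds`, `blocks` ([exon_blocks], local coordinates), `provenance`,
#'   `window` (chrom, start, end, strand of the extracted genomic window).
#' @export
extract_gene <- function(model, genome, flank = 0L, cds_only = TRUE) {
  stopifnot(inherits(model, "gene_model"))
  if (flank < 0L) stopf("flank must be non-negative")
  seq <- chrom_seq(genome, model$chrom)
  L <- nchar(seq)
  span <- gene_span(model)
  ws <- max(0L, span[["start"]] - as.integer(flank))
  we <- min(L, span[["end"]] + as.integer(flank))
  window <- subseq0(seq, ws, we)
  if (model$strand == "-") window <- revcomp(window)

  ivs <- if (cds_only) model$cds else model$exons
  if (nrow(ivs) == 0L) stopf("gene %s has no CDS intervals", model$gene_id)
  # local coding-strand coordinates of a genomic interval [s, e)
  loc <- local_coords(ivs, ws, we, model$strand)
  seg_len <- loc[, 2] - loc[, 1]
  cum <- cumsum(seg_len)
  blocks <- exon_blocks(
    genomic_start = loc[, 1], genomic_end = loc[, 2],
    cds_start = c(0L, cum[-length(cum)]), cds_end = cum,
    cds_len = cum[length(cum)],
    min_intron = 1L,  # annotation is taken at face value here
    provenance = "annotation"
  )
  cds <- splice_blocks(window, blocks)
  structure(
    list(gene_id = model$gene_id, genomic = window, cds = cds,
         blocks = blocks, provenance = "annotation",
         window = list(chrom = model$chrom, start = ws, end = we,
                       strand = model$strand)),
    class = "gene_sequences"
  )
}

# transcript-ordered genomic intervals -> local coding-strand intervals
local_coords <- function(ivs, ws, we, strand) {
  if (strand == "+") {
    cbind(ivs[, 1] - ws, ivs[, 2] - ws)
  } else {
    cbind(we - ivs[, 2], we - ivs[, 1])
  }
}

#' @export
print.gene_sequences <- function(x, ...) {
  cat(sprintf("<gene_sequences> %s  genomic %d bp, CDS %d bp, %d exon block(s) [%s]\n",
              x$gene_id, nchar(x$genomic), nchar(x$cds), nrow(x$blocks),
              x$provenance))
  invisible(x)
}

#' Exon blocks straight from annotation
#'
#' Arithmetic counterpart of [map_junctions()]: derives the exon block table
#' of a gene from its annotated CDS intervals, in local coordinates of the
#' [extract_gene()] window, without any alignment.
#'
#' @inheritParams extract_gene
#' @param min_intron Minimum intron length accepted (bp).
#' @return An [exon_blocks] table with provenance `"annotation"`.
#' @export
junctions_from_annotation <- function(model, flank = 0L, cds_only = TRUE,
                                      min_intron = 20L) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(model$cds) == 0L && cds_only)
    stopf("gene %s has no CDS intervals", model$gene_id)
  span <- gene_span(model)
  ws <- max(0L, span[["start"]] - as.integer(flank))
  we <- span[["end"]] + as.integer(flank)
  ivs <- if (cds_only) model$cds else model$exons
  loc <- local_coords(ivs, ws, we, model$strand)
  seg_len <- loc[, 2] - loc[, 1]
  cum <- cumsum(seg_len)
  exon_blocks(
    genomic_start = loc[, 1], genomic_end = loc[, 2],
    cds_start = c(0L, cum[-length(cum)]), cds_end = cum,
    cds_len = cum[length(cum)],
    min_intron = min_intron,
    provenance = "annotation"
  )
}
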
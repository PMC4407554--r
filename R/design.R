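#' Build gene sequences from bare genomic + CDS input
#'
#' User-supplied mode: when no annotation is available, the exon-intron
#' structure is recovered by spliced anchoring of the CDS onto the genomic
#' sequence ([map_junctions()]).
#'
#' @param genomic,cds DNA strings (coding strand).
#' @param gene_id Identifier.
#' @param jparams See [junction_params()].
#' @return A `gene_sequences` object with provenance `"spliced_alignment"`.
#' @export
gene_from_sequences <- function(genomic, cds, gene_id = "gene",
                                jparams = junction_params()) {
  genomic <- norm_dna(genomic); cds <- norm_dna(cds)
  blocks <- map_junctions(cds, genomic, jparams)
  structure(
    list(gene_id = gene_id, genomic = genomic, cds = cds, blocks = blocks,
         provenance = "spliced_alignment",
         window = list(chrom = NA_character_, start = 0L,
                       end = nchar(genomic), strand = "+")),
    class = "gene_sequences")
}

#' Design cross-species intron-spanning primer pairs for an ortholog pair
#'
#' Full Primer-Maker workflow: globally align the two CDSs, project both
#' exon structures onto the alignment, extract conserved gapless blocks that
#' avoid junctions, enumerate primer candidates in both orientations from
#' the template species, and combine them into scored, ranked
#' intron-spanning pairs.
#'
#' @param gene_a,gene_b `gene_sequences` objects ([extract_gene()] or
#'   [gene_from_sequences()]).
#' @param params See [primer_params()].
#' @param aparams See [align_params()].
#' @param template Template species (`"a"` default: primer sequences are
#'   taken from species A).
#' @return A `marker_design` object; `tidy()` gives the ranked pair table,
#'   `glance()` a one-row summary, `autoplot()` the pairwise gene structure.
#' @export
design_markers <- function(gene_a, gene_b, params = primer_params(),
                           aparams = align_params(), template = "a") {
  stopifnot(inherits(gene_a, "gene_sequences"),
            inherits(gene_b, "gene_sequences"))
  aln <- global_align_cds(gene_a$cds, gene_b$cds, aparams)
  ps <- build_pair_structure(aln, gene_a$blocks, gene_b$blocks)
  blocks <- conserved_blocks(ps, min_block_len = params$len_range[1],
                             max_mismatches_per_block = params$max_mismatches_per_primer)
  cands <- enumerate_primers(ps, blocks, params, template = template)
  pairs <- pair_primers(cands, ps, params)
  structure(
    list(gene_a = gene_a$gene_id, gene_b = gene_b$gene_id,
         structure = ps, blocks = blocks, candidates = cands, pairs = pairs,
         params = params),
    class = "marker_design")
}

#' @export
print.marker_design <- function(x, ...) {
  cat(sprintf(
    "<marker_design> %s vs %s: %d conserved block(s), %d candidate(s), %d pair(s)\n",
    x$gene_a, x$gene_b, nrow(x$blocks), nrow(x$candidates), nrow(x$pairs)))
  if (nrow(x$pairs) > 0L) {
    best <- x$pairs[x$pairs$rank == 1L, ]
    cat(sprintf("  top pair %s  score %.1f  product %d/%d bp  introns %d/%d\n",
                best$pair_id, best$score, best$product_size_a,
                best$product_size_b, best$introns_spanned_a,
                best$introns_spanned_b))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname design_markers
#' @param x A `marker_design` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.marker_design <- function(x, ...) {
  tibble::as_tibble(x$pairs)
}

#' @rdname design_markers
#' @exportS3Method generics::glance
glance.marker_design <- function(x, ...) {
  st <- x$structure$col_state
  tibble(
    gene_a = x$gene_a, gene_b = x$gene_b,
    alignment_columns = length(st),
    percent_identity = 100 * sum(st == "match") / sum(st %in% c("match", "mismatch")),
    n_junctions_a = length(x$structure$junctions_a),
    n_junctions_b = length(x$structure$junctions_b),
    n_blocks = nrow(x$blocks),
    n_candidates = nrow(x$candidates),
    n_pairs = nrow(x$pairs),
    best_score = if (nrow(x$pairs) > 0L) max(x$pairs$score) else NA_real_)
}
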
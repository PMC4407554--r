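#' Exon block table
#'
#' Ties a spliced CDS to its genomic sequence: each block maps a gapless CDS
#' segment `[cds_start, cds_end)` onto a genomic segment
#' `[genomic_start, genomic_end)` of equal length. Consecutive blocks are
#' separated by introns. Both coordinate systems are 0-based half-open and on
#' the coding strand.
#'
#' @param genomic_start,genomic_end,cds_start,cds_end Integer vectors, one
#'   element per block, in 5'-to-3' order.
#' @param cds_len Total CDS length; the CDS segments must tile
#'   `[0, cds_len)` exactly.
#' @param min_intron Minimum allowed intron length (bp).
#' @param provenance `"annotation"` or `"spliced_alignment"`.
#' @return A tibble of class `exon_blocks` with attribute `provenance`.
#' @export
exon_blocks <- function(genomic_start, genomic_end, cds_start, cds_end,
                        cds_len, min_intron = 20L,
                        provenance = c("annotation", "spliced_alignment")) {
  provenance <- match.arg(provenance)
  b <- tibble(
    genomic_start = as.integer(genomic_start),
    genomic_end = as.integer(genomic_end),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  )
  if (nrow(b) == 0L) stopf("exon_blocks requires at least one block")
  glen <- b$genomic_end - b$genomic_start
  clen <- b$cds_end - b$cds_start
  if (any(glen <= 0L) || any(clen <= 0L)) stopf("empty exon block")
  if (any(glen != clen)) stopf("exon block genomic length != CDS length (indel within block)")
  if (is.unsorted(b$genomic_start, strictly = TRUE) ||
      is.unsorted(b$cds_start, strictly = TRUE))
    stopf("exon blocks must be sorted in both coordinate systems")
  if (b$cds_start[1] != 0L || b$cds_end[nrow(b)] != cds_len ||
      (nrow(b) > 1L && any(b$cds_start[-1] != b$cds_end[-nrow(b)])))
    stopf("CDS segments must tile [0, cds_len) exactly")
  if (nrow(b) > 1L) {
    ilen <- b$genomic_start[-1] - b$genomic_end[-nrow(b)]
    if (any(ilen < min_intron))
      stopf("intron shorter than min_intron (%d bp)", min_intron)
  }
  structure(b, class = c("exon_blocks", class(tibble())),
            provenance = provenance, cds_len = as.integer(cds_len))
}

#' Intron intervals of an exon block table
#'
#' @param blocks An [exon_blocks] table.
#' @return Tibble with `start`, `end`, `length` (genomic, coding strand).
#' @export
introns <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return(tibble(start = integer(0), end = integer(0), length = integer(0)))
  tibble(
    start = blocks$genomic_end[-n],
    end = blocks$genomic_start[-1],
    length = blocks$genomic_start[-1] - blocks$genomic_end[-n]
  )
}

# CDS junction offsets: junction sits between CDS positions j-1 and j
cds_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) integer(0) else blocks$cds_end[-n]
}

# map CDS offsets to genomic offsets (coding strand, same frame as blocks)
cds_to_genomic <- function(blocks, cds_pos) {
  idx <- findInterval(cds_pos, blocks$cds_start)
  if (any(idx < 1L) || any(cds_pos >= blocks$cds_end[idx]))
    stopf("CDS position outside blocks")
  blocks$genomic_start[idx] + (cds_pos - blocks$cds_start[idx])
}

# splice a genomic (coding-strand) sequence according to blocks
splice_blocks <- function(genomic, blocks) {
  paste(substr(rep(genomic, nrow(blocks)),
               blocks$genomic_start + 1L, blocks$genomic_end),
        collapse = "")
}
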
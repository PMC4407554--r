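#' Build the pairwise gene structure
#'
#' Integrates the CDS-to-CDS alignment of two orthologous genes with both
#' species' exon block structures: every CDS junction offset is projected
#' onto an alignment column, and each column is classified as `match`,
#' `mismatch`, `gap_a` or `gap_b`. Junction column `j` means the intron
#' interrupts that species' CDS between columns `j - 1` and `j` (columns are
#' 0-based).
#'
#' @param aln A [global_align_cds()] result.
#' @param blocks_a,blocks_b [exon_blocks] of species A and B (local
#'   coordinates of each species' genomic sequence).
#' @return A `pair_structure` list: `aln`, `col_state` (character vector),
#'   `cds_a`, `cds_b` (per-column 0-based CDS offsets, `NA` at gaps),
#'   `junctions_a`, `junctions_b` (0-based column indices), `blocks_a`,
#'   `blocks_b`.
#' @export
build_pair_structure <- function(aln, blocks_a, blocks_b) {
  stopifnot(inherits(aln, "cds_alignment"))
  a <- chars(aln$aligned_a); b <- chars(aln$aligned_b)
  ga <- a == "-"; gb <- b == "-"
  if (any(ga & gb)) stopf("alignment has a column gapped in both rows")
  col_state <- ifelse(ga, "gap_a", ifelse(gb, "gap_b",
                      ifelse(a == b, "match", "mismatch")))
  cds_a <- ifelse(ga, NA_integer_, cumsum(!ga) - 1L)
  cds_b <- ifelse(gb, NA_integer_, cumsum(!gb) - 1L)
  len_a <- sum(!ga); len_b <- sum(!gb)
  if (attr(blocks_a, "cds_len") != len_a || attr(blocks_b, "cds_len") != len_b)
    stopf("exon blocks CDS length does not match the aligned sequence")
  junctions_a <- junction_columns(cds_junctions(blocks_a), cds_a, len_a)
  junctions_b <- junction_columns(cds_junctions(blocks_b), cds_b, len_b)
  structure(
    list(aln = aln, col_state = col_state, cds_a = cds_a, cds_b = cds_b,
         junctions_a = junctions_a, junctions_b = junctions_b,
         blocks_a = blocks_a, blocks_b = blocks_b),
    class = "pair_structure"
  )
}

# CDS junction offsets -> 0-based alignment columns (column of the base that
# starts the downstream exon)
junction_columns <- function(offsets, cds_map, cds_len) {
  if (length(offsets) == 0L) return(integer(0))
  if (any(offsets <= 0L | offsets >= cds_len))
    stopf("junction CDS offset out of range")
  cols <- match(offsets, cds_map) - 1L
  if (any(is.na(cols))) stopf("junction offset not representable in alignment")
  as.integer(cols)
}

#' @export
print.pair_structure <- function(x, ...) {
  tab <- table(factor(x$col_state, c("match", "mismatch", "gap_a", "gap_b")))
  cat(sprintf(paste0("<pair_structure> %d columns (%d match, %d mismatch, ",
                     "%d gap_a, %d gap_b); junctions A: %d, B: %d\n"),
              length(x$col_state), tab[["match"]], tab[["mismatch"]],
              tab[["gap_a"]], tab[["gap_b"]],
              length(x$junctions_a), length(x$junctions_b)))
  invisible(x)
}

# genomic coordinate (species-local, coding strand) of the base at an
# alignment column, for species "a" or "b"
column_to_genomic <- function(ps, species, cols) {
  map <- if (species == "a") ps$cds_a else ps$cds_b
  blocks <- if (species == "a") ps$blocks_a else ps$blocks_b
  pos <- map[cols + 1L]
  if (any(is.na(pos))) stopf("column maps to a gap in species %s", species)
  cds_to_genomic(blocks, pos)
}

#' Extract conserved gapless blocks
#'
#' Scans the pairwise gene structure for maximal runs of gap-free alignment
#' columns, splits them at every exon-intron junction column of either
#' species (primers may not cross a junction), then greedily partitions each
#' run left-to-right so that no block carries more than
#' `max_mismatches_per_block` mismatch columns. Blocks shorter than
#' `min_block_len` are dropped.
#'
#' @param ps A [build_pair_structure()] result.
#' @param min_block_len Minimum block length in columns (default the minimum
#'   primer length, 18).
#' @param max_mismatches_per_block Mismatch ceiling per block.
#' @return Tibble with `col_start`, `col_end` (0-based half-open columns),
#'   `length`, `n_mismatch`, `mismatch_cols` (list of 0-based columns).
#' @export
conserved_blocks <- function(ps, min_block_len = 18L,
                             max_mismatches_per_block = 3L) {
  stopifnot(inherits(ps, "pair_structure"))
  L <- length(ps$col_state)
  eligible <- ps$col_state %in% c("match", "mismatch")
  # segment breaks *before* these 0-based columns
  breaks <- sort(unique(c(ps$junctions_a, ps$junctions_b)))
  # build maximal eligible runs
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  out <- list()
  is_mm <- ps$col_state == "mismatch"
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    cut <- breaks[breaks > s & breaks < e]
    seg_starts <- c(s, cut)
    seg_ends <- c(cut, e)
    for (k in seq_along(seg_starts)) {
      out[[length(out) + 1L]] <-
        split_by_mismatch(seg_starts[k], seg_ends[k], is_mm,
                          max_mismatches_per_block)
    }
  }
  blocks <- bind_rows(out)
  if (nrow(blocks) == 0L)
    return(tibble(col_start = integer(0), col_end = integer(0),
                  length = integer(0), n_mismatch = integer(0),
                  mismatch_cols = list()))
  blocks <- blocks[blocks$col_end - blocks$col_start >= min_block_len, ,
                   drop = FALSE]
  blocks$length <- blocks$col_end - blocks$col_start
  blocks$mismatch_cols <- lapply(seq_len(nrow(blocks)), function(i) {
    cols <- seq.int(blocks$col_start[i], blocks$col_end[i] - 1L)
    cols[is_mm[cols + 1L]]
  })
  blocks$n_mismatch <- lengths(blocks$mismatch_cols)
  blocks <- blocks[order(blocks$col_start),
                   c("col_start", "col_end", "length", "n_mismatch",
                     "mismatch_cols")]
  tibble::as_tibble(blocks)
}

# Recursive median split of [s, e): while a piece holds more than max_mm
# mismatch columns, remove its median mismatch column and recurse on both
# sides. The cut tree depends only on the mismatch positions, so lowering
# max_mm refines the same partition -- every tighter block is contained in a
# looser one.
split_by_mismatch <- function(s, e, is_mm, max_mm) {
  if (e <= s) return(NULL)
  mm_cols <- seq.int(s, e - 1L)[is_mm[(s + 1L):e]]
  rec <- function(s, e, mm) {
    if (length(mm) <= max_mm) return(list(c(s, e)))
    c0 <- mm[(length(mm) + 1L) %/% 2L]
    c(rec(s, c0, mm[mm < c0]), rec(c0 + 1L, e, mm[mm > c0]))
  }
  m <- do.call(rbind, rec(s, e, mm_cols))
  keep <- m[, 2] > m[, 1]
  tibble(col_start = as.integer(m[keep, 1]), col_end = as.integer(m[keep, 2]))
}
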
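#' Electronic PCR parameters
#'
#' @param max_mismatches Maximum mismatches tolerated per primer-genome hit
#'   (default 5). Matching is ungapped (Hamming distance): primer annealing
#'   across indels essentially never amplifies, and the ungapped contract
#'   stays exhaustively testable.
#' @param max_product_size Largest virtual amplicon reported (bp).
#' @param anchor3 Require this many mismatch-free bases at the hit's 3' end
#'   (0 disables; mapping mismatch count alone over-predicts amplification).
#' @return Named list of parameters.
#' @export
ehtpcr_params <- function(max_mismatches = 5L, max_product_size = 5000L,
                          anchor3 = 0L) {
  stopifnot(max_mismatches >= 0L, max_product_size > 0L, anchor3 >= 0L)
  list(max_mismatches = as.integer(max_mismatches),
       max_product_size = as.integer(max_product_size),
       anchor3 = as.integer(anchor3))
}

#' Reduce primer pairs to a non-redundant primer set
#'
#' @param pairs Pair tibble with `pair_id`, `fw_seq`, `rv_seq`.
#' @return List with `primers` (tibble `uid`, `seq`, `orientation`) and
#'   `back_map` (tibble `pair_id`, `fw_uid`, `rv_uid`) reconstructing every
#'   input pair from the reduced set.
#' @export
dedupe_primers <- function(pairs) {
  if (nrow(pairs) == 0L) stopf("no primer pairs to dedupe")
  seqs <- c(pairs$fw_seq, pairs$rv_seq)
  ori <- rep(c("forward", "reverse"), each = nrow(pairs))
  key <- paste(ori, seqs)
  u <- !duplicated(key)
  primers <- tibble(
    uid = paste0("p", formatC(seq_len(sum(u)), width = 4, flag = "0")),
    seq = seqs[u], orientation = ori[u])
  lut <- primers$uid[match(key, paste(primers$orientation, primers$seq))]
  back_map <- tibble(pair_id = pairs$pair_id,
                     fw_uid = lut[seq_len(nrow(pairs))],
                     rv_uid = lut[nrow(pairs) + seq_len(nrow(pairs))])
  list(primers = primers, back_map = back_map)
}

#' Map a primer onto a genome with bounded mismatches
#'
#' Exhaustive ungapped search: every position on both strands where the
#' Hamming distance between the primer and the genomic window is at most
#' `max_mismatches`. Coordinates are forward-strand and 0-based half-open; a
#' `-` strand hit means the primer matches the reverse complement of the
#' window, with its 3' end at the window start.
#'
#' @param primer Primer sequence (>= 15 nt, no N), 5'-to-3'.
#' @param genome Named `DNAStringSet`.
#' @param max_mismatches Mismatch tolerance.
#' @return Tibble: `chrom`, `start`, `end`, `strand`, `mismatch_count`,
#'   `mismatch_offsets` (list of 0-based primer offsets, 5'-to-3').
#' @export
find_sites <- function(primer, genome, max_mismatches = 5L) {
  primer <- norm_dna(primer)
  if (nchar(primer) < 15L) stopf("primer shorter than 15 nt")
  if (grepl("[^ACGT]", primer)) stopf("primer contains ambiguous bases")
  if (length(genome) == 0L) stopf("empty genome")
  pat <- Biostrings::DNAString(primer)
  rcp <- Biostrings::reverseComplement(pat)
  out <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else rcp
      m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m) - 1L
      wins <- as.character(Biostrings::extractAt(
        subject, IRanges::IRanges(starts + 1L, width = nchar(primer))))
      offs <- lapply(wins, function(wseq) {
        hit5to3 <- if (strand == "+") wseq else revcomp(wseq)
        which(chars(hit5to3) != chars(primer)) - 1L
      })
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom, start = starts, end = starts + nchar(primer),
        strand = strand,
        mismatch_count = lengths(offs),
        mismatch_offsets = offs)
    }
  }
  if (length(out) == 0L)
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), mismatch_count = integer(0),
                  mismatch_offsets = list()))
  h <- bind_rows(out)
  h[order(h$chrom, h$start, h$strand), , drop = FALSE]
}

#' Enumerate virtual amplicons from primer hit sets
#'
#' Combines forward and reverse primer hits from one genome: a product forms
#' when the forward primer sits on `+` upstream of the reverse primer on `-`
#' (or the strand-mirrored configuration, reported in forward-strand
#' coordinates), on the same chromosome, with a size between the summed
#' primer lengths and `max_product_size`.
#'
#' @param fw_hits,rv_hits Hit tibbles from [find_sites()] for the pair's
#'   forward and reverse primer.
#' @param params See [ehtpcr_params()].
#' @return Tibble sorted by (`chrom`, `start`): `chrom`, `start`, `end`,
#'   `size`, `orientation` (`"+"` if the forward primer is on `+`),
#'   `fw_start`, `rv_start`, `total_mismatches`.
#' @export
enumerate_amplicons <- function(fw_hits, rv_hits, params = ehtpcr_params()) {
  combine <- function(left, right, ori) {
    # left primer on +, right primer on -, right downstream
    if (nrow(left) == 0L || nrow(right) == 0L) return(NULL)
    out <- list()
    for (chrom in intersect(unique(left$chrom), unique(right$chrom))) {
      l <- left[left$chrom == chrom, , drop = FALSE]
      r <- right[right$chrom == chrom, , drop = FALSE]
      g <- expand.grid(i = seq_len(nrow(l)), j = seq_len(nrow(r)))
      size <- r$end[g$j] - l$start[g$i]
      ok <- size >= (l$end[g$i] - l$start[g$i]) + (r$end[g$j] - r$start[g$j]) &
        size <= params$max_product_size
      if (!any(ok)) next
      g <- g[ok, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        chrom = chrom,
        start = l$start[g$i], end = r$end[g$j],
        size = r$end[g$j] - l$start[g$i],
        orientation = ori,
        fw_start = if (ori == "+") l$start[g$i] else r$start[g$j],
        rv_start = if (ori == "+") r$start[g$j] else l$start[g$i],
        total_mismatches = l$mismatch_count[g$i] + r$mismatch_count[g$j])
    }
    bind_rows(out)
  }
  amp <- bind_rows(
    combine(fw_hits[fw_hits$strand == "+", , drop = FALSE],
            rv_hits[rv_hits$strand == "-", , drop = FALSE], "+"),
    combine(rv_hits[rv_hits$strand == "+", , drop = FALSE],
            fw_hits[fw_hits$strand == "-", , drop = FALSE], "-"))
  if (nrow(amp) == 0L)
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  size = integer(0), orientation = character(0),
                  fw_start = integer(0), rv_start = integer(0),
                  total_mismatches = integer(0)))
  amp[order(amp$chrom, amp$start, amp$end), , drop = FALSE]
}

# apply the 3'-anchor rule to a hit table
filter_anchor3 <- function(hits, primer_len, anchor3) {
  if (anchor3 == 0L || nrow(hits) == 0L) return(hits)
  ok <- vapply(hits$mismatch_offsets, function(o) {
    !any(o >= primer_len - anchor3)
  }, logical(1))
  hits[ok, , drop = FALSE]
}

#' Run electronic high-throughput PCR
#'
#' Three-step workflow: the primer pool is reduced to a non-redundant set,
#' each unique primer is mapped onto every selected genome with bounded
#' mismatches, and forward/reverse hit combinations are assembled into
#' virtual amplicons. Each (pair, genome) is then classified: `specific`
#' (exactly one genomic locus), `non_specific` (two or more loci) or
#' `no_amplification`.
#'
#' @param pairs Pair tibble (needs `pair_id`, `fw_seq`, `rv_seq`).
#' @param genomes Named list of `DNAStringSet` genomes.
#' @param params See [ehtpcr_params()].
#' @param dedupe Reduce the primer pool first (result is identical either
#'   way; deduplication only avoids re-mapping shared sequences).
#' @return An `ehtpcr_result` list: `report` (tibble `pair_id`, `genome_id`,
#'   `status`, `locus_count`), `amplicons` (tibble with `pair_id` and locus
#'   coordinates), `params`.
#' @export
run_ehtpcr <- function(pairs, genomes, params = ehtpcr_params(),
                       dedupe = TRUE) {
  if (nrow(pairs) == 0L) stopf("no primer pairs supplied")
  if (length(genomes) == 0L || is.null(names(genomes)))
    stopf("genomes must be a non-empty named list")
  if (dedupe) {
    dd <- dedupe_primers(pairs)
    primers <- dd$primers; back <- dd$back_map
  } else {
    primers <- tibble(
      uid = paste0("p", seq_len(2L * nrow(pairs))),
      seq = c(pairs$fw_seq, pairs$rv_seq),
      orientation = rep(c("forward", "reverse"), each = nrow(pairs)))
    back <- tibble(pair_id = pairs$pair_id,
                   fw_uid = primers$uid[seq_len(nrow(pairs))],
                   rv_uid = primers$uid[nrow(pairs) + seq_len(nrow(pairs))])
  }
  report <- list(); amplicons <- list()
  for (gid in names(genomes)) {
    hits <- lapply(seq_len(nrow(primers)), function(i) {
      h <- find_sites(primers$seq[i], genomes[[gid]], params$max_mismatches)
      filter_anchor3(h, nchar(primers$seq[i]), params$anchor3)
    })
    names(hits) <- primers$uid
    for (p in seq_len(nrow(back))) {
      amp <- enumerate_amplicons(hits[[back$fw_uid[p]]],
                                 hits[[back$rv_uid[p]]], params)
      loci <- unique(amp[, c("chrom", "start", "end")])
      n <- nrow(loci)
      report[[length(report) + 1L]] <- tibble(
        pair_id = back$pair_id[p], genome_id = gid,
        status = if (n == 0L) "no_amplification"
                 else if (n == 1L) "specific" else "non_specific",
        locus_count = n)
      if (n > 0L) {
        amp$pair_id <- back$pair_id[p]
        amp$genome_id <- gid
        amplicons[[length(amplicons) + 1L]] <- amp
      }
    }
  }
  amplicons <- bind_rows(amplicons)
  if (nrow(amplicons) > 0L)
    amplicons <- amplicons[order(amplicons$genome_id, amplicons$chrom,
                                 amplicons$start, amplicons$pair_id), ,
                           drop = FALSE]
  structure(list(report = bind_rows(report), amplicons = amplicons,
                 params = params),
            class = "ehtpcr_result")
}

#' @export
print.ehtpcr_result <- function(x, ...) {
  tab <- table(x$report$status)
  cat(sprintf("<ehtpcr_result> %d pair-genome combinations (%s)\n",
              nrow(x$report),
              paste(names(tab), as.integer(tab), sep = ": ", collapse = ", ")))
  invisible(x)
}
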
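#' Parameters for CDS-to-genomic junction mapping
#'
#' @param anchor_k Seed k-mer length for exact anchors.
#' @param refine_window Junction boundaries may slide by up to this many bp
#'   to land on canonical splice dinucleotides.
#' @param min_coverage Minimum fraction of CDS covered by chained anchors.
#' @param min_intron Genomic gaps shorter than this are alignment noise, not
#'   introns.
#' @param max_kmer_hits Seed k-mers occurring more often than this in the
#'   genomic sequence are skipped (repeat guard).
#' @return A named list of parameters.
#' @export
junction_params <- function(anchor_k = 16L, refine_window = 10L,
                            min_coverage = 0.95, min_intron = 20L,
                            max_kmer_hits = 100L) {
  list(anchor_k = as.integer(anchor_k), refine_window = as.integer(refine_window),
       min_coverage = min_coverage, min_intron = as.integer(min_intron),
       max_kmer_hits = as.integer(max_kmer_hits))
}

#' Locate exon-intron junctions by spliced anchoring
#'
#' Aligns a CDS to the genomic sequence of its own locus to recover the exon
#' block structure: maximal exact anchor matches (k-mer seeded) are chained
#' colinearly by dynamic programming to maximise matched CDS coverage, and
#' each resulting junction is then slid within `refine_window` bp to prefer
#' canonical `GT..AG` (then `GC..AG`) intron boundaries.
#'
#' The CDS and genomic sequence are expected to come from the same gene
#' (near-identical in exons); this is a spliced placement, not a general
#' cross-species aligner.
#'
#' @param cds Spliced CDS (character, coding strand).
#' @param genomic Genomic sequence containing the locus (coding strand).
#' @param params See [junction_params()].
#' @return An [exon_blocks] table with provenance `"spliced_alignment"`.
#' @export
map_junctions <- function(cds, genomic, params = junction_params()) {
  cds <- norm_dna(cds); genomic <- norm_dna(genomic)
  n <- nchar(cds); m <- nchar(genomic)
  k <- params$anchor_k
  if (n < 20L) stopf("CDS too short to anchor (%d bp)", n)
  if (m < n) stopf("genomic sequence shorter than CDS")

  anchors <- find_anchors(cds, genomic, k, params$max_kmer_hits)
  if (nrow(anchors) == 0L)
    stopf("CDS could not be located in the genomic sequence (no anchors)")

  chain <- chain_anchors(anchors, n)
  covered <- sum(chain$cds_end - chain$cds_start)
  if (covered / n < params$min_coverage)
    stopf("CDS coverage %.3f below min_coverage %.3f; CDS not locatable",
          covered / n, params$min_coverage)

  blocks <- tidy_chain(chain, n, m, params$min_intron)
  blocks <- refine_junctions(blocks, cds, genomic, params$refine_window,
                             params$min_intron)
  exon_blocks(blocks$g_start, blocks$g_end, blocks$c_start, blocks$c_end,
              cds_len = n, min_intron = params$min_intron,
              provenance = "spliced_alignment")
}

# maximal exact match blocks between cds and genomic, seeded by shared k-mers
find_anchors <- function(cds, genomic, k, max_kmer_hits) {
  n <- nchar(cds); m <- nchar(genomic)
  ck <- substring(cds, 1:(n - k + 1L), k:n)
  gk <- substring(genomic, 1:(m - k + 1L), k:m)
  idx <- split(seq_along(gk), gk)           # genomic positions per k-mer
  idx <- idx[lengths(idx) <= max_kmer_hits]
  hits <- idx[ck]                            # list parallel to cds positions
  lens <- lengths(hits)
  if (sum(lens) == 0L)
    return(tibble(cds_start = integer(0), cds_end = integer(0),
                  g_start = integer(0)))
  ci <- rep.int(seq_along(ck), lens) - 1L    # 0-based cds seed starts
  gi <- unlist(hits, use.names = FALSE) - 1L # 0-based genomic seed starts
  diag <- gi - ci
  # merge runs of consecutive seeds on the same diagonal into maximal blocks
  o <- order(diag, ci)
  ci <- ci[o]; diag <- diag[o]
  new_run <- c(TRUE, diff(ci) != 1L | diff(diag) != 0L)
  run <- cumsum(new_run)
  cs <- tapply(ci, run, min)
  ce <- tapply(ci, run, max) + k
  dg <- diag[new_run]
  tibble(cds_start = as.integer(cs), cds_end = as.integer(ce),
         g_start = as.integer(cs + dg))
}

# colinear chain maximising covered CDS length; ties -> leftmost genomic
chain_anchors <- function(a, cds_len) {
  a <- a[order(a$cds_start, a$g_start), , drop = FALSE]
  B <- nrow(a)
  len <- a$cds_end - a$cds_start
  diag <- a$g_start - a$cds_start
  best <- len            # best coverage of a chain ending at block i
  prev <- rep(NA_integer_, B)
  if (B > 1L) {
    for (j in 2:B) {
      for (i in 1:(j - 1L)) {
        if (diag[i] > diag[j]) next                 # introns only add genomic
        if (a$cds_start[i] >= a$cds_start[j]) next
        if (a$cds_end[i] >= a$cds_end[j]) next
        if (diag[i] == diag[j] || a$g_start[j] >= a$g_start[i] + len[i]) {
          gain <- a$cds_end[j] - max(a$cds_start[j], a$cds_end[i])
          cand <- best[i] + gain
          if (cand > best[j] ||
              (cand == best[j] && !is.na(prev[j]) && a$g_start[i] < a$g_start[prev[j]])) {
            best[j] <- cand
            prev[j] <- i
          }
        }
      }
    }
  }
  top <- which(best == max(best))
  j <- top[which.min(a$g_start[top])]
  path <- j
  while (!is.na(prev[j])) { j <- prev[j]; path <- c(j, path) }
  a[path, , drop = FALSE]
}

# resolve cds overlaps, absorb zero-length-gap mismatch runs, extend ends,
# and merge sub-min_intron genomic gaps; returns g_start/g_end/c_start/c_end
tidy_chain <- function(chain, n, m, min_intron) {
  cs <- chain$cds_start; ce <- chain$cds_end; gs <- chain$g_start
  ge <- gs + (ce - cs)
  B <- length(cs)
  # trim later block when consecutive blocks overlap in CDS
  if (B > 1L) {
    for (j in 2:B) {
      ov <- ce[j - 1L] - cs[j]
      if (ov > 0L) { cs[j] <- cs[j] + ov; gs[j] <- gs[j] + ov }
    }
  }
  # extend first/last block to the CDS ends (unanchored mismatch tails)
  ext <- min(cs[1], gs[1])
  cs[1] <- cs[1] - ext; gs[1] <- gs[1] - ext
  ext <- min(n - ce[B], m - ge[B])
  ce[B] <- ce[B] + ext; ge[B] <- ge[B] + ext
  if (cs[1] > 0L || ce[B] < n)
    stopf("CDS ends could not be placed within the genomic sequence")
  # interior gaps: equal cds/genomic gap = mismatch run (absorb into left
  # block); genomic-only gap >= min_intron = intron; a small genomic excess
  # is alignment noise we cannot represent -> absorb what we can or fail
  keep <- rep(TRUE, B)
  if (B > 1L) {
    for (j in 2:B) {
      dc <- cs[j] - ce[j - 1L]
      dgap <- gs[j] - ge[j - 1L]
      if (dc < 0L || dgap < dc) stopf("inconsistent anchor chain")
      if (dgap == dc) {                     # no intron: merge across mismatches
        cs[j] <- ce[j - 1L]; gs[j] <- ge[j - 1L]
        keep[j - 1L] <- FALSE
        cs[j] <- min(cs[j], cs[j - 1L]); gs[j] <- min(gs[j], gs[j - 1L])
      } else {
        if (dc > 0L) {                      # give unanchored cds bases to the left
          ce[j - 1L] <- ce[j - 1L] + dc; ge[j - 1L] <- ge[j - 1L] + dc
        }
        if (gs[j] - ge[j - 1L] < min_intron)
          stopf("genomic gap of %d bp is below min_intron and not mergeable",
                gs[j] - ge[j - 1L])
      }
    }
  }
  list(g_start = gs[keep], g_end = ge[keep],
       c_start = cs[keep], c_end = ce[keep])
}

# slide each junction within +/- window to prefer GT..AG then GC..AG introns
refine_junctions <- function(b, cds, genomic, window, min_intron) {
  B <- length(b$g_start)
  if (B < 2L) return(b)
  for (j in 1:(B - 1L)) {
    ge <- b$g_end[j]; gs2 <- b$g_start[j + 1L]; ce <- b$c_end[j]
    shifts <- setdiff(seq.int(-window, window), 0L)
    shifts <- shifts[order(abs(shifts), shifts)]
    cand <- c(0L, shifts)
    pick <- 0L; pick_rank <- intron_rank(genomic, ge, gs2)
    for (s in cand) {
      ne <- ge + s; ns2 <- gs2 + s; nc <- ce + s
      if (nc <= b$c_start[j] || nc >= b$c_end[j + 1L]) next
      if (ne <= b$g_start[j] || ns2 >= b$g_end[j + 1L]) next
      if (ns2 - ne < min_intron) next
      if (s != 0L && !shift_valid(cds, genomic, ce, ge, gs2, s)) next
      r <- intron_rank(genomic, ne, ns2)
      if (r < pick_rank) { pick <- s; pick_rank <- r }
      if (pick_rank == 1L) break
    }
    if (pick != 0L) {
      b$g_end[j] <- ge + pick
      b$c_end[j] <- ce + pick
      b$g_start[j + 1L] <- gs2 + pick
      b$c_start[j + 1L] <- ce + pick
    }
  }
  b
}

# 1 = GT..AG, 2 = GC..AG, 3 = other
intron_rank <- function(genomic, istart, iend) {
  d5 <- subseq0(genomic, istart, istart + 2L)
  d3 <- subseq0(genomic, iend - 2L, iend)
  if (d3 != "AG") return(3L)
  if (d5 == "GT") 1L else if (d5 == "GC") 2L else 3L
}

# sliding the junction by s must keep exon bases identical to the CDS
shift_valid <- function(cds, genomic, ce, ge, gs2, s) {
  if (s > 0L) {
    subseq0(cds, ce, ce + s) == subseq0(genomic, ge, ge + s)
  } else {
    subseq0(cds, ce + s, ce) == subseq0(genomic, gs2 + s, gs2)
  }
}
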
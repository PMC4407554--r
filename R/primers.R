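#' Primer design parameters
#'
#' Defaults follow common PCR practice for genotyping markers; the
#' cross-species mismatch ceiling is 3 per primer, and mismatches in the
#' 3'-terminal window or at adjacent positions are rejected outright because
#' they compromise extension.
#'
#' @param len_range Primer length range (nt).
#' @param tm_range Acceptable melting temperature range (degrees C),
#'   evaluated on the template species' allele.
#' @param tm_opt Optimal Tm used in scoring.
#' @param max_pair_tm_diff Maximum |Tm(fw) - Tm(rv)| (template species).
#' @param gc_range GC content range (percent).
#' @param max_mismatches_per_primer Cross-species mismatch ceiling per primer.
#' @param forbid_3prime_mismatch_window No cross-species mismatch may fall
#'   within this many nt of the primer 3' end (0 disables).
#' @param forbid_consecutive_mismatches Reject primers with two mismatches at
#'   adjacent positions.
#' @param at_rich_3prime_rule Flag primers whose last 5 nt contain no G/C.
#' @param at_rich_hard_filter Turn the AT-rich 3' flag into a hard filter.
#' @param product_size_range Allowed genomic product size per species (bp).
#' @param min_introns_spanned Minimum introns between the primers in each
#'   species.
#' @param preferred_size Product size (bp) with zero length penalty.
#' @param w_mm,w_mm3,w_tm,w_dtm,w_len Score penalty weights (see
#'   [score_pairs()]).
#' @return A named list of parameters.
#' @export
primer_params <- function(len_range = c(18L, 24L),
                          tm_range = c(55, 62),
                          tm_opt = 58,
                          max_pair_tm_diff = 3,
                          gc_range = c(35, 65),
                          max_mismatches_per_primer = 3L,
                          forbid_3prime_mismatch_window = 5L,
                          forbid_consecutive_mismatches = TRUE,
                          at_rich_3prime_rule = TRUE,
                          at_rich_hard_filter = FALSE,
                          product_size_range = c(300L, 2000L),
                          min_introns_spanned = 1L,
                          preferred_size = 800,
                          w_mm = 3, w_mm3 = 8, w_tm = 1, w_dtm = 2, w_len = 1) {
  p <- list(len_range = as.integer(len_range), tm_range = tm_range,
            tm_opt = tm_opt, max_pair_tm_diff = max_pair_tm_diff,
            gc_range = gc_range,
            max_mismatches_per_primer = as.integer(max_mismatches_per_primer),
            forbid_3prime_mismatch_window = as.integer(forbid_3prime_mismatch_window),
            forbid_consecutive_mismatches = forbid_consecutive_mismatches,
            at_rich_3prime_rule = at_rich_3prime_rule,
            at_rich_hard_filter = at_rich_hard_filter,
            product_size_range = as.integer(product_size_range),
            min_introns_spanned = as.integer(min_introns_spanned),
            preferred_size = preferred_size,
            w_mm = w_mm, w_mm3 = w_mm3, w_tm = w_tm, w_dtm = w_dtm,
            w_len = w_len)
  for (r in c("len_range", "tm_range", "gc_range", "product_size_range"))
    if (length(p[[r]]) != 2L || p[[r]][1] > p[[r]][2])
      stopf("%s must be an ordered range", r)
  p
}

#' Enumerate primer candidates inside conserved blocks
#'
#' Every window of every allowed length inside every conserved block is
#' considered in both orientations. The primer sequence is taken from the
#' template species; Tm is computed against each species' own allele (the
#' primer anneals to each genome separately). Reverse candidates are reported
#' 5'-to-3' on the antisense strand, so their 3' end sits at the window
#' start.
#'
#' @param ps A [build_pair_structure()] result.
#' @param blocks A [conserved_blocks()] table.
#' @param params See [primer_params()].
#' @param template Which species supplies the primer sequence (`"a"` or
#'   `"b"`).
#' @return Tibble of candidates in deterministic (block, offset, length,
#'   orientation) order.
#' @export
enumerate_primers <- function(ps, blocks, params = primer_params(),
                              template = c("a", "b")) {
  stopifnot(inherits(ps, "pair_structure"))
  template <- match.arg(template)
  empty <- tibble(
    id = character(0), orientation = character(0),
    col_start = integer(0), col_end = integer(0), length = integer(0),
    seq = character(0), tm_a = numeric(0), tm_b = numeric(0),
    gc = numeric(0), n_mismatch = integer(0), mm_3prime = integer(0),
    has_3prime_mismatch = logical(0), has_consecutive_mismatch = logical(0),
    at_rich_3prime = logical(0),
    gen_a_start = integer(0), gen_a_end = integer(0),
    gen_b_start = integer(0), gen_b_end = integer(0))
  if (nrow(blocks) == 0L) return(structure(empty, template = template))

  L <- length(ps$col_state)
  is_mm <- ps$col_state == "mismatch"
  pref_mm <- c(0L, cumsum(is_mm))
  adj <- is_mm & c(is_mm[-1], FALSE)          # adj[i]: cols i-1 and i mismatch
  pref_adj <- c(0L, cumsum(adj))
  row_t <- if (template == "a") ps$aln$aligned_a else ps$aln$aligned_b
  ch_t <- chars(row_t)
  is_gc <- ch_t %in% c("G", "C")
  pref_gc <- c(0L, cumsum(is_gc))
  is_bad <- !(chars(ps$aln$aligned_a) %in% c("A", "C", "G", "T", "-")) |
            !(chars(ps$aln$aligned_b) %in% c("A", "C", "G", "T", "-"))
  pref_bad <- c(0L, cumsum(is_bad))
  cnt <- function(pref, s, e) pref[e + 1L] - pref[s + 1L]  # 0-based [s, e)

  # all windows
  wins <- list()
  for (bi in seq_len(nrow(blocks))) {
    for (len in params$len_range[1]:params$len_range[2]) {
      ns <- blocks$col_end[bi] - blocks$col_start[bi] - len
      if (ns < 0L) next
      s <- blocks$col_start[bi] + 0:ns
      wins[[length(wins) + 1L]] <- tibble(block = bi, col_start = s,
                                          col_end = s + len, length = len)
    }
  }
  if (length(wins) == 0L) return(structure(empty, template = template))
  w <- bind_rows(wins)
  w <- w[order(w$block, w$col_start, w$length), , drop = FALSE]

  s <- w$col_start; e <- w$col_end
  w$n_mismatch <- cnt(pref_mm, s, e)
  w$has_consecutive_mismatch <- cnt(pref_adj, s, e - 1L) > 0L
  has_n <- cnt(pref_bad, s, e) > 0L
  w3 <- 5L  # 3'-terminal window for flags/AT-rule
  mm_head <- cnt(pref_mm, s, pmin(e, s + w3))
  mm_tail <- cnt(pref_mm, pmax(s, e - w3), e)
  gc_head <- cnt(pref_gc, s, pmin(e, s + w3))
  gc_tail <- cnt(pref_gc, pmax(s, e - w3), e)
  fw_win <- params$forbid_3prime_mismatch_window
  mm_fw3 <- cnt(pref_mm, pmax(s, e - fw_win), e)   # forward 3' = window end
  mm_rv3 <- cnt(pref_mm, s, pmin(e, s + fw_win))   # reverse 3' = window start
  tmpl_seq <- substr(rep(row_t, nrow(w)), s + 1L, e)
  seq_a <- substr(rep(ps$aln$aligned_a, nrow(w)), s + 1L, e)
  seq_b <- substr(rep(ps$aln$aligned_b, nrow(w)), s + 1L, e)
  w$gc <- cnt(pref_gc, s, e) / w$length * 100

  keep0 <- !has_n &
    w$n_mismatch <= params$max_mismatches_per_primer &
    w$gc >= params$gc_range[1] & w$gc <= params$gc_range[2]
  if (params$forbid_consecutive_mismatches)
    keep0 <- keep0 & !w$has_consecutive_mismatch
  if (!any(keep0)) return(structure(empty, template = template))

  # Tm per species on the kept windows only
  tm_a <- tm_b <- rep(NA_real_, nrow(w))
  tm_a[keep0] <- melting_temp(seq_a[keep0])
  tm_b[keep0] <- melting_temp(seq_b[keep0])
  tm_t <- if (template == "a") tm_a else tm_b
  keep0 <- keep0 & !is.na(tm_t) &
    tm_t >= params$tm_range[1] & tm_t <= params$tm_range[2]

  # genomic coordinates of window ends per species
  ca <- ps$cds_a; cb <- ps$cds_b
  make_orient <- function(ori) {
    fwd <- ori == "forward"
    keep <- keep0
    if (fw_win > 0L)
      keep <- keep & (if (fwd) mm_fw3 else mm_rv3) == 0L
    at_rich <- (if (fwd) gc_tail else gc_head) < 1L
    if (params$at_rich_hard_filter && params$at_rich_3prime_rule)
      keep <- keep & !at_rich
    if (!any(keep)) return(NULL)
    k <- which(keep)
    tibble(
      id = sprintf("%s%d_%d", if (fwd) "F" else "R", s[k], w$length[k]),
      orientation = ori,
      col_start = s[k], col_end = e[k], length = w$length[k],
      seq = if (fwd) tmpl_seq[k] else revcomp(tmpl_seq[k]),
      tm_a = tm_a[k], tm_b = tm_b[k], gc = w$gc[k],
      n_mismatch = w$n_mismatch[k],
      mm_3prime = if (fwd) mm_tail[k] else mm_head[k],
      has_3prime_mismatch = (if (fwd) mm_tail[k] else mm_head[k]) > 0L,
      has_consecutive_mismatch = w$has_consecutive_mismatch[k],
      at_rich_3prime = at_rich[k] & params$at_rich_3prime_rule,
      gen_a_start = cds_to_genomic(ps$blocks_a, ca[s[k] + 1L]),
      gen_a_end = cds_to_genomic(ps$blocks_a, ca[e[k]]) + 1L,
      gen_b_start = cds_to_genomic(ps$blocks_b, cb[s[k] + 1L]),
      gen_b_end = cds_to_genomic(ps$blocks_b, cb[e[k]]) + 1L
    )
  }
  out <- bind_rows(make_orient("forward"), make_orient("reverse"))
  if (nrow(out) == 0L) return(structure(empty, template = template))
  out <- out[order(out$col_start, out$length,
                   match(out$orientation, c("forward", "reverse"))), ,
             drop = FALSE]
  structure(tibble::as_tibble(out), template = template)
}

#' Combine candidates into intron-spanning primer pairs
#'
#' All forward x reverse combinations with the forward primer strictly
#' upstream of the reverse primer, at least `min_introns_spanned` introns
#' between them in *each* species, per-species genomic product sizes within
#' range, and a template-species Tm difference within `max_pair_tm_diff`.
#' Pairs are scored and ranked (see [score_pairs()]).
#'
#' @param cands Candidate tibble from [enumerate_primers()].
#' @param ps The [build_pair_structure()] result the candidates came from.
#' @param params See [primer_params()].
#' @return Tibble of primer pairs, ranked by score.
#' @export
pair_primers <- function(cands, ps, params = primer_params()) {
  template <- attr(cands, "template") %||% "a"
  fw <- cands[cands$orientation == "forward", , drop = FALSE]
  rv <- cands[cands$orientation == "reverse", , drop = FALSE]
  empty <- empty_pairs()
  if (nrow(fw) == 0L || nrow(rv) == 0L)
    return(structure(empty, params = params, template = template))
  rv <- rv[order(rv$col_start), , drop = FALSE]

  ja <- sort(ps$junctions_a); jb <- sort(ps$junctions_b)
  n_upto <- function(j, x) findInterval(x, j)   # junction columns <= x

  tm_fw <- if (template == "a") fw$tm_a else fw$tm_b
  tm_rv <- if (template == "a") rv$tm_a else rv$tm_b

  res <- vector("list", nrow(fw))
  for (i in seq_len(nrow(fw))) {
    first <- findInterval(fw$col_end[i] - 1L, rv$col_start) + 1L
    if (first > nrow(rv)) next
    j <- first:nrow(rv)
    size_a <- rv$gen_a_end[j] - fw$gen_a_start[i]
    size_b <- rv$gen_b_end[j] - fw$gen_b_start[i]
    spn_a <- n_upto(ja, rv$col_start[j]) - n_upto(ja, fw$col_end[i] - 1L)
    spn_b <- n_upto(jb, rv$col_start[j]) - n_upto(jb, fw$col_end[i] - 1L)
    ok <- spn_a >= params$min_introns_spanned &
      spn_b >= params$min_introns_spanned &
      size_a >= params$product_size_range[1] &
      size_a <= params$product_size_range[2] &
      size_b >= params$product_size_range[1] &
      size_b <= params$product_size_range[2] &
      abs(tm_fw[i] - tm_rv[j]) <= params$max_pair_tm_diff
    if (!any(ok)) next
    jj <- j[ok]
    res[[i]] <- tibble(
      fw_row = i, rv_row = jj,
      product_size_a = size_a[ok], product_size_b = size_b[ok],
      introns_spanned_a = spn_a[ok], introns_spanned_b = spn_b[ok])
  }
  res <- bind_rows(res)
  if (nrow(res) == 0L)
    return(structure(empty, params = params, template = template))

  grab <- function(d, rows, prefix) {
    cols <- c("id", "seq", "col_start", "col_end", "length", "tm_a", "tm_b",
              "gc", "n_mismatch", "mm_3prime", "has_3prime_mismatch",
              "has_consecutive_mismatch", "at_rich_3prime",
              "gen_a_start", "gen_b_start")
    out <- d[rows, cols]
    names(out) <- paste0(prefix, "_", cols)
    out
  }
  pairs <- bind_cols(grab(fw, res$fw_row, "fw"), grab(rv, res$rv_row, "rv"),
                     res[, c("product_size_a", "product_size_b",
                             "introns_spanned_a", "introns_spanned_b")])
  pairs$pair_id <- paste0(pairs$fw_id, "|", pairs$rv_id)
  pairs$fw_tm <- if (template == "a") pairs$fw_tm_a else pairs$fw_tm_b
  pairs$rv_tm <- if (template == "a") pairs$rv_tm_a else pairs$rv_tm_b
  pairs <- score_pairs(tibble::as_tibble(pairs), params)
  structure(pairs, params = params, template = template)
}

empty_pairs <- function() {
  tibble(pair_id = character(0), fw_id = character(0), rv_id = character(0),
         fw_seq = character(0), rv_seq = character(0),
         fw_tm = numeric(0), rv_tm = numeric(0),
         fw_n_mismatch = integer(0), rv_n_mismatch = integer(0),
         product_size_a = integer(0), product_size_b = integer(0),
         introns_spanned_a = integer(0), introns_spanned_b = integer(0),
         score = numeric(0), rank = integer(0))
}

#' Score and rank primer pairs
#'
#' `score = 100 - (w_mm * total_mismatches + w_mm3 * mismatches_within_5nt_of_a_3'_end
#' + w_tm * (|tm_fw - tm_opt| + |tm_rv - tm_opt|) + w_dtm * |tm_fw - tm_rv|
#' + w_len * |mean(product sizes) - preferred_size| / 100)`. Higher is
#' better; a mismatch-free pair with both primers at the optimal Tm and the
#' preferred product size scores exactly 100. Ties are broken by fewer total
#' mismatches, then smaller |product_size_a - product_size_b|, then leftmost
#' forward primer.
#'
#' @param pairs Pair tibble from [pair_primers()].
#' @param params See [primer_params()].
#' @return The tibble with `score` and `rank` columns, sorted by rank.
#' @export
score_pairs <- function(pairs, params = primer_params()) {
  if (nrow(pairs) == 0L) { pairs$score <- numeric(0); pairs$rank <- integer(0); return(pairs) }
  mm_total <- pairs$fw_n_mismatch + pairs$rv_n_mismatch
  mm3 <- pairs$fw_mm_3prime + pairs$rv_mm_3prime
  mean_size <- (pairs$product_size_a + pairs$product_size_b) / 2
  pairs$score <- 100 -
    (params$w_mm * mm_total +
     params$w_mm3 * mm3 +
     params$w_tm * (abs(pairs$fw_tm - params$tm_opt) +
                    abs(pairs$rv_tm - params$tm_opt)) +
     params$w_dtm * abs(pairs$fw_tm - pairs$rv_tm) +
     params$w_len * abs(mean_size - params$preferred_size) / 100)
  o <- order(-pairs$score, mm_total,
             abs(pairs$product_size_a - pairs$product_size_b),
             pairs$fw_col_start)
  pairs <- pairs[o, , drop = FALSE]
  pairs$rank <- seq_len(nrow(pairs))
  pairs
}

#' Narrow a set of designed pairs (search-within-result)
#'
#' A pure filter over an existing pair table: any subset of stricter
#' [primer_params()] settings plus an explicit pair-id selection. It never
#' adds pairs, criteria looser than the originals are warned about and
#' ignored, and ranks are recomputed within the survivors (scores are kept).
#'
#' @param pairs Pair tibble from [pair_primers()].
#' @param criteria Named list with any of `max_mismatches_per_primer`,
#'   `tm_range`, `max_pair_tm_diff`, `product_size_range`,
#'   `min_introns_spanned`, `forbid_3prime_mismatch`, `forbid_at_rich_3prime`,
#'   `forbid_consecutive_mismatches`.
#' @param pair_ids Optional explicit pair-id whitelist.
#' @return Filtered, re-ranked tibble.
#' @export
refine_pairs <- function(pairs, criteria = list(), pair_ids = NULL) {
  orig <- attr(pairs, "params") %||% primer_params()
  template <- attr(pairs, "template") %||% "a"
  keep <- rep(TRUE, nrow(pairs))
  chk <- function(name, looser) {
    if (looser) { warnf("criterion '%s' is looser than the original; ignored", name); TRUE }
    else FALSE
  }
  if (!is.null(criteria$max_mismatches_per_primer)) {
    v <- criteria$max_mismatches_per_primer
    if (!chk("max_mismatches_per_primer", v > orig$max_mismatches_per_primer))
      keep <- keep & pairs$fw_n_mismatch <= v & pairs$rv_n_mismatch <= v
  }
  if (!is.null(criteria$tm_range)) {
    v <- criteria$tm_range
    if (!chk("tm_range", v[1] < orig$tm_range[1] || v[2] > orig$tm_range[2]))
      keep <- keep & pairs$fw_tm >= v[1] & pairs$fw_tm <= v[2] &
        pairs$rv_tm >= v[1] & pairs$rv_tm <= v[2]
  }
  if (!is.null(criteria$max_pair_tm_diff)) {
    v <- criteria$max_pair_tm_diff
    if (!chk("max_pair_tm_diff", v > orig$max_pair_tm_diff))
      keep <- keep & abs(pairs$fw_tm - pairs$rv_tm) <= v
  }
  if (!is.null(criteria$product_size_range)) {
    v <- criteria$product_size_range
    if (!chk("product_size_range",
             v[1] < orig$product_size_range[1] || v[2] > orig$product_size_range[2]))
      keep <- keep & pairs$product_size_a >= v[1] & pairs$product_size_a <= v[2] &
        pairs$product_size_b >= v[1] & pairs$product_size_b <= v[2]
  }
  if (!is.null(criteria$min_introns_spanned)) {
    v <- criteria$min_introns_spanned
    if (!chk("min_introns_spanned", v < orig$min_introns_spanned))
      keep <- keep & pairs$introns_spanned_a >= v & pairs$introns_spanned_b >= v
  }
  if (isTRUE(criteria$forbid_3prime_mismatch))
    keep <- keep & !pairs$fw_has_3prime_mismatch & !pairs$rv_has_3prime_mismatch
  if (isTRUE(criteria$forbid_at_rich_3prime))
    keep <- keep & !pairs$fw_at_rich_3prime & !pairs$rv_at_rich_3prime
  if (isTRUE(criteria$forbid_consecutive_mismatches))
    keep <- keep & !pairs$fw_has_consecutive_mismatch &
      !pairs$rv_has_consecutive_mismatch
  if (!is.null(pair_ids)) keep <- keep & pairs$pair_id %in% pair_ids
  out <- pairs[keep, , drop = FALSE]
  o <- order(out$rank)
  out <- out[o, , drop = FALSE]
  if (nrow(out) > 0L) out$rank <- seq_len(nrow(out))
  structure(out, params = orig, template = template)
}

#' First report page
#'
#' The report viewer shows the top-scoring `min(page_size, n)` pairs on its
#' first page (default page size 60).
#'
#' @param pairs Ranked pair tibble.
#' @param page_size Page size.
#' @return The leading rows of `pairs` by rank.
#' @export
first_page <- function(pairs, page_size = 60L) {
  pairs[order(pairs$rank), , drop = FALSE][seq_len(min(page_size, nrow(pairs))), ,
                                           drop = FALSE]
}
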
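# identical 30-column single-block structure used by several tests
identical_block_ps <- function(len = 30, seed = 51) {
  withr::with_seed(seed, {
    s <- random_dna(len)
    aln <- global_align_cds(s, s)
    build_pair_structure(
      aln, exon_blocks(0L, len, 0L, len, cds_len = len),
      exon_blocks(0L, len, 0L, len, cds_len = len))
  })
}

test_that("blocks shorter than the minimum primer length yield no candidates", {
  ps <- identical_block_ps(30)
  blocks <- conserved_blocks(ps, min_block_len = 18L)
  p <- primer_params(tm_range = c(0, 100), gc_range = c(0, 100))
  short <- blocks
  short$col_end <- short$col_start + 17L
  expect_equal(nrow(enumerate_primers(ps, short, p)), 0L)
})

test_that("candidate enumeration equals a brute-force window count", {
  ps <- identical_block_ps(30)
  blocks <- conserved_blocks(ps, min_block_len = 18L)
  # disable Tm/GC filtering so the count is purely combinatorial
  p <- primer_params(tm_range = c(0, 100), gc_range = c(0, 100))
  cands <- enumerate_primers(ps, blocks, p)
  brute <- 0L
  for (len in 18:24) for (s in 0:(30 - len)) brute <- brute + 2L  # both orientations
  expect_equal(nrow(cands), brute)
  expect_equal(sum(cands$orientation == "forward"),
               sum(cands$orientation == "reverse"))
  # identical alleles: no mismatches anywhere
  expect_true(all(cands$n_mismatch == 0L))
  # Tm/GC filters only ever shrink this set
  cands2 <- enumerate_primers(ps, blocks, primer_params(tm_range = c(55, 62)))
  expect_true(all(cands2$id %in% cands$id))
})

test_that("a 3'-terminal mismatch excludes the affected orientation", {
  withr::with_seed(52, {
    s <- random_dna(30)
    ch <- strsplit(s, "")[[1]]
    ch[30] <- setdiff(c("A", "C", "G", "T"), ch[30])[1]  # mismatch at col 29
    aln <- structure(list(aligned_a = s, aligned_b = paste(ch, collapse = ""),
                          score = 0, params = align_params()),
                     class = "cds_alignment")
    ps <- build_pair_structure(
      aln, exon_blocks(0L, 30L, 0L, 30L, cds_len = 30L),
      exon_blocks(0L, 30L, 0L, 30L, cds_len = 30L))
    blocks <- conserved_blocks(ps, min_block_len = 18L)
    p <- primer_params(tm_range = c(0, 100), gc_range = c(0, 100))
    cands <- enumerate_primers(ps, blocks, p)
    # windows ending at column 30 would put the mismatch at the forward 3' end
    fw_at_end <- cands[cands$orientation == "forward" & cands$col_end == 30L, ]
    expect_equal(nrow(fw_at_end), 0L)
    # reverse primers ending at column 30 have the mismatch at their 5' end: fine
    rv_at_end <- cands[cands$orientation == "reverse" & cands$col_end == 30L, ]
    expect_gt(nrow(rv_at_end), 0L)
    expect_true(all(rv_at_end$n_mismatch == 1L))
  })
})

test_that("product size difference equals the intron length difference", {
  fx <- two_exon_fixture(intron_a = 500, intron_b = 300)
  gp <- gene_pair_from_fixture(fx)
  des <- design_markers(gp$a, gp$b,
                        primer_params(tm_range = c(40, 80), gc_range = c(0, 100),
                                      product_size_range = c(100L, 3000L)))
  expect_gt(nrow(des$pairs), 0L)
  expect_true(all(des$pairs$product_size_a - des$pairs$product_size_b == 200L))
  expect_true(all(des$pairs$introns_spanned_a == 1L))
  expect_true(all(des$pairs$introns_spanned_b == 1L))
})

test_that("pairs within a single exon are never produced", {
  # single-exon gene vs itself: nothing can span an intron
  withr::with_seed(53, {
    s <- random_dna(600)
    g <- gene_from_sequences(s, s, "single")
    des <- design_markers(g, g, primer_params(tm_range = c(40, 80),
                                              gc_range = c(0, 100),
                                              product_size_range = c(50L, 3000L)))
    expect_equal(nrow(des$pairs), 0L)
  })
})

test_that("per-species product size bounds reject pairs on either side", {
  fx <- two_exon_fixture(intron_a = 500, intron_b = 300)
  gp <- gene_pair_from_fixture(fx)
  loose <- primer_params(tm_range = c(40, 80), gc_range = c(0, 100),
                         product_size_range = c(100L, 3000L))
  des <- design_markers(gp$a, gp$b, loose)
  sizes_b <- des$pairs$product_size_b
  # a window that excludes every species-B size must kill all pairs even
  # though species-A sizes (200 bp larger) could pass
  tight <- primer_params(tm_range = c(40, 80), gc_range = c(0, 100),
                         product_size_range = c(max(sizes_b) + 1L, 3000L))
  des2 <- design_markers(gp$a, gp$b, tight)
  expect_true(all(des2$pairs$product_size_b >= max(sizes_b) + 1L))
  expect_lt(nrow(des2$pairs), nrow(des$pairs))
})

test_that("the score formula behaves as documented", {
  p <- primer_params()
  base <- tibble::tibble(
    pair_id = "x", fw_col_start = 0L,
    fw_n_mismatch = 0L, rv_n_mismatch = 0L,
    fw_mm_3prime = 0L, rv_mm_3prime = 0L,
    fw_tm = p$tm_opt, rv_tm = p$tm_opt,
    product_size_a = 800L, product_size_b = 800L)
  expect_equal(score_pairs(base, p)$score, 100)
  # one mismatch inside the 3' window costs w_mm + w_mm3 = 11
  mm3 <- base
  mm3$fw_n_mismatch <- 1L
  mm3$fw_mm_3prime <- 1L
  expect_equal(score_pairs(mm3, p)$score, 100 - (p$w_mm + p$w_mm3))
  expect_equal(p$w_mm + p$w_mm3, 11)
  # Tm deviation and product-size deviation are linear
  tmoff <- base
  tmoff$fw_tm <- p$tm_opt + 2
  expect_equal(score_pairs(tmoff, p)$score,
               100 - p$w_tm * 2 - p$w_dtm * 2)
  szoff <- base
  szoff$product_size_a <- 1000L
  expect_equal(score_pairs(szoff, p)$score, 100 - p$w_len * 100 / 100)
})

test_that("scores are symmetric in the species labels for symmetric input", {
  fx <- two_exon_fixture(intron_a = 400, intron_b = 400)
  gp <- gene_pair_from_fixture(fx)
  p <- primer_params(tm_range = c(40, 80), gc_range = c(0, 100),
                     product_size_range = c(100L, 3000L))
  d_ab <- design_markers(gp$a, gp$b, p)
  d_ba <- design_markers(gp$b, gp$a, p)
  expect_equal(d_ab$pairs$score, d_ba$pairs$score)
  expect_equal(d_ab$pairs$pair_id, d_ba$pairs$pair_id)
})

test_that("every emitted pair satisfies all primer parameter bounds", {
  sim <- simulate_ortholog_pair(sim_params(seed = 55, n_exons = 4,
                                           intron_len = c(80, 600),
                                           genome_padding = 500))
  p <- primer_params()
  des <- design_markers(sim$a$gene, sim$b$gene, p)
  pr <- des$pairs
  expect_gt(nrow(pr), 0L)
  expect_true(all(nchar(pr$fw_seq) >= p$len_range[1] &
                  nchar(pr$fw_seq) <= p$len_range[2]))
  expect_true(all(pr$fw_n_mismatch <= p$max_mismatches_per_primer))
  expect_true(all(pr$rv_n_mismatch <= p$max_mismatches_per_primer))
  expect_true(all(!pr$fw_has_3prime_mismatch & !pr$rv_has_3prime_mismatch))
  expect_true(all(abs(pr$fw_tm - pr$rv_tm) <= p$max_pair_tm_diff + 1e-9))
  expect_true(all(pr$product_size_a >= p$product_size_range[1] &
                  pr$product_size_a <= p$product_size_range[2]))
  expect_true(all(pr$introns_spanned_a >= 1L & pr$introns_spanned_b >= 1L))
  expect_true(all(pr$fw_tm >= p$tm_range[1] & pr$fw_tm <= p$tm_range[2]))
  # no primer window contains a gap or junction column of either species
  st <- des$structure
  gapj <- sort(unique(c(which(st$col_state %in% c("gap_a", "gap_b")) - 1L)))
  juncs <- sort(unique(c(st$junctions_a, st$junctions_b)))
  for (i in seq_len(min(nrow(pr), 200))) {
    for (pre in c("fw", "rv")) {
      cs <- pr[[paste0(pre, "_col_start")]][i]
      ce <- pr[[paste0(pre, "_col_end")]][i]
      expect_false(any(gapj >= cs & gapj < ce))
      expect_false(any(juncs > cs & juncs < ce))
    }
  }
})

test_that("refine_pairs is a pure, commutative, never-adding filter", {
  sim <- simulate_ortholog_pair(sim_params(seed = 56, n_exons = 3,
                                           intron_len = c(80, 500),
                                           genome_padding = 400))
  des <- design_markers(sim$a$gene, sim$b$gene)
  pairs <- des$pairs
  expect_gt(nrow(pairs), 1L)
  # identical criteria -> identity (modulo recomputed ranks)
  same <- refine_pairs(pairs, list())
  expect_equal(same$pair_id, pairs$pair_id[order(pairs$rank)])
  # stricter mismatch criterion keeps only mismatch-free pairs
  mmfree <- refine_pairs(pairs, list(max_mismatches_per_primer = 0L))
  expect_true(all(mmfree$fw_n_mismatch == 0L & mmfree$rv_n_mismatch == 0L))
  expect_true(all(mmfree$pair_id %in% pairs$pair_id))
  # commutativity of two filters
  x <- list(max_mismatches_per_primer = 1L)
  y <- list(tm_range = c(56, 61))
  xy <- refine_pairs(refine_pairs(pairs, x), y)
  yx <- refine_pairs(refine_pairs(pairs, y), x)
  expect_equal(xy$pair_id, yx$pair_id)
  # looser criteria warn and are ignored
  expect_warning(loose <- refine_pairs(pairs, list(max_mismatches_per_primer = 10L)),
                 "looser")
  expect_equal(nrow(loose), nrow(pairs))
})

test_that("the first report page holds the top-scoring min(60, n) pairs", {
  sim <- simulate_ortholog_pair(sim_params(seed = 57, n_exons = 4,
                                           intron_len = c(80, 600),
                                           genome_padding = 400))
  des <- design_markers(sim$a$gene, sim$b$gene)
  pairs <- des$pairs
  pg <- first_page(pairs)
  expect_equal(nrow(pg), min(60L, nrow(pairs)))
  expect_equal(pg$rank, seq_len(nrow(pg)))
  expect_true(all(pg$score >= max(pairs$score[!pairs$pair_id %in% pg$pair_id],
                                  -Inf)))
  expect_equal(nrow(first_page(pairs[pairs$rank <= 10, ])), 10L)
})
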
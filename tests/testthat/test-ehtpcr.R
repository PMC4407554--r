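make_pairs_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    pair_id = vapply(rows, `[[`, character(1), 1),
    fw_seq = vapply(rows, `[[`, character(1), 2),
    rv_seq = vapply(rows, `[[`, character(1), 3))
}

test_that("dedupe_primers removes shared sequences losslessly", {
  p <- make_pairs_tbl(list("p1", "ACGTACGTACGTACGTAC", "TTGGCCAATTGGCCAATT"),
                      list("p2", "ACGTACGTACGTACGTAC", "AATTCCGGAATTCCGGAA"))
  dd <- dedupe_primers(p)
  expect_equal(nrow(dd$primers), 3L)
  expect_equal(dd$back_map$pair_id, c("p1", "p2"))
  expect_equal(dd$back_map$fw_uid[1], dd$back_map$fw_uid[2])
  # all distinct -> identity
  p2 <- make_pairs_tbl(list("p1", "ACGTACGTACGTACGTAC", "TTGGCCAATTGGCCAATT"),
                       list("p2", "CCGGTTAACCGGTTAACC", "AATTCCGGAATTCCGGAA"))
  expect_equal(nrow(dedupe_primers(p2)$primers), 4L)
})

test_that("find_sites recovers a planted exact match and its mirror", {
  withr::with_seed(61, {
    chrom <- random_dna(50000)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    primer <- substr(chrom, 1001, 1020)   # 0-based start 1000
    h <- find_sites(primer, genome, max_mismatches = 0L)
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, 1000L)
    expect_equal(h$strand, "+")
    expect_equal(h$mismatch_count, 0L)
    # reverse complement of a substring -> one minus-strand hit, mirrored coords
    h2 <- find_sites(rc(substr(chrom, 2001, 2020)), genome, 0L)
    expect_equal(nrow(h2), 1L)
    expect_equal(h2$start, 2000L)
    expect_equal(h2$strand, "-")
  })
})

test_that("find_sites equals the brute-force Hamming scanner", {
  withr::with_seed(62, {
    chrom <- random_dna(20000)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    for (i in 1:10) {
      L <- sample(18:24, 1)
      primer <- if (i %% 2 == 0) random_dna(L) else {
        # plant a degenerate copy so non-trivial hits exist
        pos <- sample(19000, 1)
        s <- substr(chrom, pos, pos + L - 1)
        ch <- strsplit(s, "")[[1]]
        k <- sample(0:4, 1)
        for (j in sample(L, k)) ch[j] <- sample(setdiff(c("A","C","G","T"), ch[j]), 1)
        paste(ch, collapse = "")
      }
      for (mm in c(0L, 2L, 4L)) {
        got <- find_sites(primer, genome, mm)
        exp <- oracle_hamming_scan(primer, "chr1", chrom, mm)
        if (is.null(exp)) exp <- data.frame(chrom = character(0),
                                            start = integer(0),
                                            strand = character(0))
        got_key <- sort(paste(got$chrom, got$start, got$strand))
        exp_key <- sort(paste(exp$chrom, exp$start, exp$strand))
        expect_equal(got_key, exp_key, info = sprintf("i=%d mm=%d", i, mm))
      }
    }
  })
})

test_that("mismatch offsets are reported 5'-to-3' on the primer", {
  withr::with_seed(63, {
    chrom <- random_dna(4000)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    target <- substr(chrom, 501, 520)
    ch <- strsplit(target, "")[[1]]
    ch[3] <- setdiff(c("A", "C", "G", "T"), ch[3])[1]
    primer <- paste(ch, collapse = "")
    h <- find_sites(primer, genome, 1L)
    plus <- h[h$start == 500L & h$strand == "+", ]
    expect_equal(plus$mismatch_offsets[[1]], 2L)  # 0-based offset
    # the same mismatch seen through the minus strand flips to L-1-offset
    hrc <- find_sites(rc(primer), genome, 1L)
    minus <- hrc[hrc$start == 500L & hrc$strand == "-", ]
    expect_equal(minus$mismatch_offsets[[1]], 17L)
  })
})

test_that("amplicon coordinate arithmetic matches the worked example", {
  fw <- tibble::tibble(chrom = "c", start = 100L, end = 120L, strand = "+",
                       mismatch_count = 0L, mismatch_offsets = list(integer(0)))
  rv <- tibble::tibble(chrom = "c", start = 580L, end = 600L, strand = "-",
                       mismatch_count = 0L, mismatch_offsets = list(integer(0)))
  amp <- enumerate_amplicons(fw, rv, ehtpcr_params())
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 100L)
  expect_equal(amp$end, 600L)
  expect_equal(amp$size, 500L)
  # reverse hit upstream of the forward hit -> nothing
  rv_up <- rv; rv_up$start <- 80L; rv_up$end <- 100L
  expect_equal(nrow(enumerate_amplicons(fw, rv_up, ehtpcr_params())), 0L)
})

test_that("amplicon enumeration equals the all-combination oracle", {
  withr::with_seed(64, {
    for (case in 1:50) {
      n_fw <- sample(1:4, 1); n_rv <- sample(1:4, 1)
      mk <- function(n) {
        starts <- sort(sample(0:3000, n))
        tibble::tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                       start = starts, end = starts + 20L,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       mismatch_count = 0L,
                       mismatch_offsets = replicate(n, integer(0),
                                                    simplify = FALSE))
      }
      fw <- mk(n_fw); rv <- mk(n_rv)
      prm <- ehtpcr_params(max_product_size = sample(c(500L, 2000L, 5000L), 1))
      got <- enumerate_amplicons(fw, rv, prm)
      exp <- oracle_amplicons(fw, rv, prm$max_product_size)
      got_key <- sort(unique(paste(got$chrom, got$start, got$end)))
      exp_key <- sort(paste(exp$chrom, exp$start, exp$end))
      expect_equal(got_key, exp_key, info = paste("case", case))
    }
  })
})

# shared end-to-end fixture for the specificity tests
ehtpcr_fixture <- function() {
  sim <- simulate_ortholog_pair(sim_params(seed = 65, n_exons = 3,
                                           intron_len = c(100, 400),
                                           genome_padding = 2000))
  des <- design_markers(sim$a$gene, sim$b$gene)
  list(sim = sim, pairs = first_page(des$pairs, 15L))
}

test_that("unique targets are specific; paralogs and deletions change status", {
  fx <- ehtpcr_fixture()
  genomes <- list(A = fx$sim$a$genome, B = fx$sim$b$genome)
  # classification logic is exercised at a tolerance where chance hits of
  # short primers are essentially impossible; high-tolerance over-prediction
  # is a property of the mapping step, not of the classifier
  prm <- ehtpcr_params(max_mismatches = 2L)
  res <- run_ehtpcr(fx$pairs, genomes, prm)
  expect_true(all(res$report$status == "specific"))
  expect_true(all(res$report$locus_count == 1L))
  expect_true(all(res$amplicons$size <= prm$max_product_size))
  # specific loci come with their coordinates
  expect_true(all(fx$pairs$pair_id %in% res$amplicons$pair_id))

  # planted identical paralog: every pair becomes non-specific with >= 2 loci
  pg <- plant_paralog(fx$sim$a$genome, fx$sim$a$model, identity = 1, seed = 8)
  res2 <- run_ehtpcr(fx$pairs, list(A = pg$genome), prm)
  expect_true(all(res2$report$status == "non_specific"))
  expect_true(all(res2$report$locus_count >= 2L))

  # deleting the locus kills amplification
  chrom <- as.character(fx$sim$a$genome[[1]])
  span <- c(2000, nchar(chrom) - 2000)
  gutted <- Biostrings::DNAStringSet(
    c(chrA = paste0(substr(chrom, 1, span[1]),
                    substr(chrom, span[2], nchar(chrom)))))
  res3 <- run_ehtpcr(fx$pairs, list(A = gutted), prm)
  expect_true(all(res3$report$status == "no_amplification"))
})

test_that("the specificity report is identical with and without dedupe", {
  fx <- ehtpcr_fixture()
  genomes <- list(A = fx$sim$a$genome, B = fx$sim$b$genome)
  r1 <- run_ehtpcr(fx$pairs, genomes, dedupe = TRUE)
  r2 <- run_ehtpcr(fx$pairs, genomes, dedupe = FALSE)
  expect_equal(r1$report, r2$report)
  expect_equal(r1$amplicons[, c("pair_id", "genome_id", "chrom", "start", "end")],
               r2$amplicons[, c("pair_id", "genome_id", "chrom", "start", "end")])
})

test_that("amplicons are invariant under genome reverse-complement", {
  fx <- ehtpcr_fixture()
  genome <- fx$sim$a$genome
  L <- length(genome[[1]])
  mirrored <- Biostrings::reverseComplement(genome)
  names(mirrored) <- names(genome)
  r1 <- run_ehtpcr(fx$pairs, list(A = genome))
  r2 <- run_ehtpcr(fx$pairs, list(A = mirrored))
  expect_equal(r1$report, r2$report)
  # coordinate transform x -> L - x maps one amplicon set onto the other
  k1 <- sort(paste(r1$amplicons$pair_id, r1$amplicons$chrom,
                   r1$amplicons$start, r1$amplicons$end))
  k2 <- sort(paste(r2$amplicons$pair_id, r2$amplicons$chrom,
                   L - r2$amplicons$end, L - r2$amplicons$start))
  expect_equal(k1, k2)
})

test_that("raising tolerances never removes hits or amplicons", {
  withr::with_seed(66, {
    chrom <- random_dna(20000)
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    primer <- substr(chrom, 5001, 5020)
    prev <- -1L
    for (mm in 0:5) {
      n <- nrow(find_sites(primer, genome, mm))
      expect_gte(n, prev)
      prev <- n
    }
  })
  fx <- ehtpcr_fixture()
  sizes <- c(2000L, 5000L)
  n <- vapply(sizes, function(sz) {
    nrow(run_ehtpcr(fx$pairs, list(A = fx$sim$a$genome),
                    ehtpcr_params(max_product_size = sz))$amplicons)
  }, integer(1))
  expect_true(n[2] >= n[1])
})

test_that("primer preconditions are enforced", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGTACGTACGTACGT"))
  expect_error(find_sites("ACGTACGTACGT", genome), "shorter")
  expect_error(find_sites("ACGTNACGTACGTACGTN", genome), "ambiguous")
})
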
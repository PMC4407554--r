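# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they test.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# --- nearest-neighbor Tm, coded via dinucleotide counting ------------------
# Same published unified parameter table, different code path: tabulate the
# 16 dinucleotide counts and take an inner product.
oracle_tm <- function(seq, primer_conc = 250e-9, na_conc = 0.05) {
  dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
          CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
          GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
          TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
          CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
          GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
          TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  counts <- table(factor(paste0(ch[-L], ch[-1]), levels = names(dh)))
  H <- sum(counts * dh)
  S <- sum(counts * ds)
  for (term in c(ch[1], ch[L])) {
    if (term %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (L - 1) * log(na_conc)
  H * 1000 / (S + 1.987 * log(primer_conc / 4)) - 273.15
}

# --- exhaustive Hamming scan over both strands -----------------------------
oracle_hamming_scan <- function(primer, chrom_name, chrom, max_mm) {
  p <- strsplit(primer, "")[[1]]
  L <- length(p)
  g <- strsplit(chrom, "")[[1]]
  G <- length(g)
  scan_one <- function(pat) {
    mm <- integer(G - L + 1)
    for (k in seq_len(L)) mm <- mm + (g[k:(G - L + k)] != pat[k])
    which(mm <= max_mm)
  }
  plus <- scan_one(p)
  minus <- scan_one(strsplit(rc(primer), "")[[1]])
  rbind(
    if (length(plus)) data.frame(chrom = chrom_name, start = plus - 1L,
                                 strand = "+"),
    if (length(minus)) data.frame(chrom = chrom_name, start = minus - 1L,
                                  strand = "-"))
}

# --- all-combination amplicon filter ---------------------------------------
oracle_amplicons <- function(fw_hits, rv_hits, max_size) {
  res <- list()
  add <- function(l, r) {
    for (i in seq_len(nrow(l))) for (j in seq_len(nrow(r))) {
      if (l$chrom[i] != r$chrom[j]) next
      size <- r$end[j] - l$start[i]
      if (size < (l$end[i] - l$start[i]) + (r$end[j] - r$start[j])) next
      if (size > max_size) next
      res[[length(res) + 1L]] <<- data.frame(chrom = l$chrom[i],
                                             start = l$start[i],
                                             end = r$end[j])
    }
  }
  add(fw_hits[fw_hits$strand == "+", , drop = FALSE],
      rv_hits[rv_hits$strand == "-", , drop = FALSE])
  add(rv_hits[rv_hits$strand == "+", , drop = FALSE],
      fw_hits[fw_hits$strand == "-", , drop = FALSE])
  if (length(res) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  out <- unique(do.call(rbind, res))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# --- affine-gap global alignment score via Biostrings ----------------------
# gap of length L costs gapOpening + L * gapExtension = 12 + 2(L-1) here
oracle_affine_score <- function(a, b, match = 2, mismatch = -3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 10, gapExtension = 2,
                                scoreOnly = TRUE)
}

# --- fixture: two-exon ortholog pair with fully identical exons ------------
# Exons are shared; intron lengths differ between the species.
two_exon_fixture <- function(exon1 = 240, exon2 = 240, intron_a = 500,
                             intron_b = 300, seed = 42) {
  withr::with_seed(seed, {
    e1 <- random_dna(exon1)
    e2 <- random_dna(exon2)
    ia <- paste0("GT", random_dna(intron_a - 4), "AG")
    ib <- paste0("GT", random_dna(intron_b - 4), "AG")
    cds <- paste0(e1, e2)
    list(cds = cds,
         genomic_a = paste0(e1, ia, e2),
         genomic_b = paste0(e1, ib, e2),
         exon1 = exon1, intron_a = intron_a, intron_b = intron_b)
  })
}

gene_pair_from_fixture <- function(fx) {
  list(a = gene_from_sequences(fx$genomic_a, fx$cds, "gA"),
       b = gene_from_sequences(fx$genomic_b, fx$cds, "gB"))
}
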
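#' Simulation parameters for ortholog gene pairs
#'
#' The simulator emulates the premise of cross-species genic marker design:
#' coding exons diverge slowly (default identity 0.97), introns diverge fast
#' (default identity 0.60) and accumulate short indels, and splice
#' dinucleotides stay canonical `GT..AG`.
#'
#' @param seed Integer seed; every run is fully reproducible from it.
#' @param n_exons Range (or single value) for the exon count.
#' @param exon_len,intron_len Length ranges in bp.
#' @param exon_identity,intron_identity Expected per-site identity between
#'   the two descendant species in each region class.
#' @param indel_rate_intron Per-bp indel rate inside introns (geometric
#'   lengths, mean 3 bp, never touching the splice dinucleotides).
#' @param genome_padding Random background sequence added on each side of
#'   the gene (bp).
#' @param paralog_identity Identity used by [plant_paralog()] by default.
#' @return Named list of parameters.
#' @export
sim_params <- function(seed = 1L, n_exons = c(2L, 10L),
                       exon_len = c(60L, 400L), intron_len = c(80L, 2000L),
                       exon_identity = 0.97, intron_identity = 0.60,
                       indel_rate_intron = 0.02, genome_padding = 3000L,
                       paralog_identity = 0.85) {
  if (length(n_exons) == 1L) n_exons <- c(n_exons, n_exons)
  if (length(exon_len) == 1L) exon_len <- c(exon_len, exon_len)
  if (length(intron_len) == 1L) intron_len <- c(intron_len, intron_len)
  stopifnot(exon_identity > 0, exon_identity <= 1,
            intron_identity > 0, intron_identity <= 1,
            all(n_exons >= 1L), all(exon_len > 0L), all(intron_len >= 24L),
            genome_padding >= 0L)
  list(seed = as.integer(seed), n_exons = as.integer(n_exons),
       exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
       exon_identity = exon_identity, intron_identity = intron_identity,
       indel_rate_intron = indel_rate_intron,
       genome_padding = as.integer(genome_padding),
       paralog_identity = paralog_identity)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# sample from a vector even when it has length 1
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# Per-lineage substitution probability p such that two independently mutated
# descendants differ at a site with probability d: with substitutions uniform
# over the 3 alternative bases, d = 2p(1-p) + (2/3)p^2, i.e.
# d = 2p - (4/3)p^2.
per_lineage_p <- function(d) {
  if (d <= 0) return(0)
  a <- 4 / 3
  (1 - sqrt(1 - a * d)) / a
}

# substitute each base with probability p, uniformly over the 3 alternatives
mutate_seq <- function(seq, p, protect = integer(0)) {
  ch <- chars(seq)
  hit <- which(runif(length(ch)) < p)
  hit <- setdiff(hit, protect)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), positions = hit)
}

# intron descendant: substitutions plus short indels, splice sites protected
mutate_intron <- function(seq, psub, indel_rate) {
  L <- nchar(seq)
  protect <- c(1:2, (L - 1L):L)
  m <- mutate_seq(seq, psub, protect)
  ch <- chars(m$seq)
  interior <- 3:(L - 2L)
  sites <- interior[runif(length(interior)) < indel_rate]
  for (i in rev(sites)) {            # right-to-left keeps indices valid
    len <- rgeom(1L, 1 / 3) + 1L
    if (runif(1) < 0.5) {
      ch <- append(ch, chars(rand_dna(len)), after = i)
    } else {
      last <- min(i + len - 1L, L - 2L)
      if (last >= i && i > 2L) ch <- ch[-(i:last)]
    }
    L <- length(ch)
  }
  out <- paste(ch, collapse = "")
  # splice dinucleotides must have survived
  substr(out, 1, 2) <- "GT"
  substr(out, nchar(out) - 1L, nchar(out)) <- "AG"
  out
}

#' Simulate an orthologous gene pair embedded in two genomes
#'
#' Generates an ancestral multi-exon gene (canonical `GT..AG` introns) and
#' derives two descendant species by independent per-site substitution --
#' slow in exons, fast in introns -- plus intron indels, so the realised
#' between-species identity matches the requested class identities. Each
#' descendant gene is embedded in random background sequence with a
#' consistent annotation.
#'
#' @param params See [sim_params()]; `params$seed` drives a single local RNG
#'   stream (the global RNG state is untouched).
#' @return List with elements `a` and `b` (each: `genome` `DNAStringSet`,
#'   `model` [gene_model], `gene` [extract_gene()] result) and `truth`
#'   (ancestor structure, per-species junctions and mutated exon positions).
#' @export
simulate_ortholog_pair <- function(params = sim_params()) {
  withr::with_seed(params$seed, {
    n_ex <- resample(params$n_exons[1]:params$n_exons[2], 1L)
    exon_lens <- resample(params$exon_len[1]:params$exon_len[2], n_ex)
    # keep CDS length a multiple of 3 (complete coding frame)
    rem <- sum(exon_lens) %% 3L
    exon_lens[n_ex] <- exon_lens[n_ex] - rem
    intron_lens <- if (n_ex > 1L)
      resample(params$intron_len[1]:params$intron_len[2], n_ex - 1L)
    else integer(0)
    exons <- vapply(exon_lens, rand_dna, character(1))
    intr <- vapply(intron_lens, function(L)
      paste0("GT", rand_dna(L - 4L), "AG"), character(1))

    # identities are realised *between the two descendants*; divergence is
    # split evenly over the two lineages
    p_exon <- per_lineage_p(1 - params$exon_identity)
    p_intr <- per_lineage_p(1 - params$intron_identity)
    make_species <- function() {
      ex <- lapply(exons, mutate_seq, p = p_exon)
      it <- vapply(intr, mutate_intron, character(1),
                   psub = p_intr,
                   indel_rate = params$indel_rate_intron / 2,
                   USE.NAMES = FALSE)
      ex_seq <- vapply(ex, `[[`, character(1), "seq")
      gene <- ex_seq[1]
      if (n_ex > 1L) for (k in 2:n_ex) gene <- paste0(gene, it[k - 1L], ex_seq[k])
      list(exons = ex_seq, introns = it, gene = gene,
           mutated = lapply(ex, `[[`, "positions"))
    }
    sa <- make_species()
    sb <- make_species()

    embed <- function(sp, chrom) {
      pad5 <- rand_dna(params$genome_padding)
      pad3 <- rand_dna(params$genome_padding)
      genome <- Biostrings::DNAStringSet(paste0(pad5, sp$gene, pad3))
      names(genome) <- chrom
      offset <- params$genome_padding
      lens <- nchar(sp$exons)
      ilens <- nchar(sp$introns)
      starts <- offset + c(0L, cumsum(lens[-length(lens)] + ilens))
      exm <- cbind(start = as.integer(starts),
                   end = as.integer(starts + lens))
      model <- gene_model(sprintf("gene_%s", chrom), chrom, "+", exm, exm)
      list(genome = genome, model = model,
           gene = extract_gene(model, genome))
    }
    ga <- embed(sa, "chrA")
    gb <- embed(sb, "chrB")
    list(
      a = ga, b = gb,
      truth = list(
        n_exons = n_ex, exon_lens = exon_lens, intron_lens = intron_lens,
        ancestor_exons = exons, ancestor_introns = intr,
        blocks_a = ga$gene$blocks, blocks_b = gb$gene$blocks,
        mutated_a = sa$mutated, mutated_b = sb$mutated,
        params = params))
  })
}

#' Plant a paralog copy into a genome
#'
#' Inserts a mutated copy of a gene's genomic span at a random position
#' downstream of the gene (so the gene's own annotation stays valid). With
#' `identity = 1` the copy is exact and every exact-match primer on the gene
#' gains a second locus.
#'
#' @param genome Named `DNAStringSet`.
#' @param model The [gene_model] of the gene to copy.
#' @param identity Per-site identity of the copy to the original.
#' @param seed Integer seed (local RNG stream).
#' @param margin Minimum distance (bp) between the gene and the insertion.
#' @return List: `genome` (modified), `insertion` (0-based position),
#'   `copy_len`.
#' @export
plant_paralog <- function(genome, model, identity = 1, seed = 1L,
                          margin = 200L) {
  withr::with_seed(as.integer(seed), {
    seq <- chrom_seq(genome, model$chrom)
    span <- gene_span(model)
    src <- subseq0(seq, span[["start"]], span[["end"]])
    lo <- span[["end"]] + margin
    hi <- nchar(seq)
    if (lo >= hi) stopf("genome too small to insert a paralog downstream")
    pos <- resample(lo:hi, 1L)
    copy <- if (identity < 1) mutate_seq(src, 1 - identity)$seq else src
    newseq <- paste0(subseq0(seq, 0L, pos), copy, subseq0(seq, pos, nchar(seq)))
    out <- genome
    out[[model$chrom]] <- Biostrings::DNAString(newseq)
    list(genome = out, insertion = pos, copy_len = nchar(copy))
  })
}
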
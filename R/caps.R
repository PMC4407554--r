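#' Load a restriction enzyme table
#'
#' The package ships a small editable TSV of common 6-cutters
#' (`name`, IUPAC `site`, `cut_offset` = bases of the site left of the
#' top-strand cut). It is a self-contained working set, not a complete
#' commercial catalogue.
#'
#' @param path TSV path; defaults to the bundled table.
#' @return Tibble with `name`, `site`, `cut_offset`, `palindromic`.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "intronspan")) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "site", "cut_offset") %in% names(e)))
    stopf("enzyme table needs columns name, site, cut_offset")
  e$site <- toupper(e$site)
  bad <- grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                      collapse = "")), e$site)
  if (any(bad)) stopf("unknown IUPAC code in enzyme site: %s",
                      paste(e$name[bad], collapse = ", "))
  if (any(nchar(e$site) < 4L)) stopf("recognition sites must be >= 4 nt")
  e$palindromic <- vapply(e$site, function(s) {
    s == as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, logical(1), USE.NAMES = FALSE)
  e <- e[order(e$name), , drop = FALSE]
  tibble::as_tibble(e)
}

# 0-based cut positions of one enzyme on a linear sequence; both strands,
# palindromic sites counted once (top strand only)
cut_positions <- function(seq, site, cut_offset, palindromic = NULL) {
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(site)
  if (is.null(palindromic))
    palindromic <- site ==
      as.character(Biostrings::reverseComplement(pat))
  top <- BiocGenerics::start(Biostrings::matchPattern(pat, subject,
                                                      fixed = FALSE)) - 1L
  cuts <- top + cut_offset
  if (!palindromic) {
    rc <- Biostrings::reverseComplement(pat)
    bot <- BiocGenerics::start(Biostrings::matchPattern(rc, subject,
                                                        fixed = FALSE)) - 1L
    cuts <- c(cuts, bot + (nchar(site) - cut_offset))
  }
  sort(unique(cuts[cuts > 0L & cuts < nchar(seq)]))
}

#' Predict the restriction digestion pattern of a linear sequence
#'
#' Cuts at every match of the IUPAC recognition site on either strand;
#' fragment lengths are reported 5'-to-3' and always sum to the sequence
#' length.
#'
#' @param seq DNA string.
#' @param enzyme One row of [load_enzymes()] (or a list with `site`,
#'   `cut_offset`).
#' @return Integer vector of fragment lengths.
#' @export
digest_pattern <- function(seq, enzyme) {
  seq <- norm_dna(seq)
  cuts <- cut_positions(seq, enzyme$site, enzyme$cut_offset,
                        enzyme$palindromic %||% NULL)
  as.integer(diff(c(0L, cuts, nchar(seq))))
}

#' Call SNPs between two alleles of one amplicon
#'
#' Globally aligns the two sequences (same engine as the ortholog CDS
#' alignment) and reports substitution columns; indel columns are excluded
#' from the SNP list but recorded separately.
#'
#' @param seq_a,seq_b Amplicon sequences of the two genotypes.
#' @param params See [align_params()].
#' @param flank Bases of alignment context stored around each SNP.
#' @return Tibble of SNPs (`column` = 0-based alignment column, `pos_a`,
#'   `pos_b` = 0-based positions in each input, `allele_a`, `allele_b`,
#'   `flank_a`, `flank_b`) with an `indels` attribute (tibble `col_start`,
#'   `col_end`, `gap_in`) and an `alignment` attribute.
#' @export
call_snps <- function(seq_a, seq_b, params = align_params(), flank = 10L) {
  aln <- global_align_cds(seq_a, seq_b, params)
  a <- chars(aln$aligned_a); b <- chars(aln$aligned_b)
  ga <- a == "-"; gb <- b == "-"
  pos_a <- cumsum(!ga) - 1L; pos_b <- cumsum(!gb) - 1L
  snp_cols <- which(!ga & !gb & a != b) - 1L
  gap <- ga | gb
  r <- rle(gap)
  ends <- cumsum(r$lengths); starts <- c(0L, ends[-length(ends)])
  ind <- tibble(col_start = starts[r$values], col_end = ends[r$values])
  ind$gap_in <- vapply(ind$col_start, function(s)
    if (ga[s + 1L]) "a" else "b", character(1))
  L <- length(a)
  ctx <- function(row, col) {
    lo <- max(0L, col - flank); hi <- min(L, col + flank + 1L)
    paste(row[(lo + 1L):hi], collapse = "")
  }
  snps <- tibble(
    column = snp_cols,
    pos_a = pos_a[snp_cols + 1L], pos_b = pos_b[snp_cols + 1L],
    allele_a = a[snp_cols + 1L], allele_b = b[snp_cols + 1L],
    flank_a = vapply(snp_cols, function(c0) ctx(a, c0), character(1)),
    flank_b = vapply(snp_cols, function(c0) ctx(b, c0), character(1)))
  structure(snps, indels = ind, alignment = aln)
}

#' Screen restriction enzymes for CAPS candidates
#'
#' Digests both alleles with every enzyme and reports the enzymes whose
#' fragment-length patterns differ (a cleaved amplified polymorphic sequence
#' marker). Each candidate is annotated with the called SNPs that overlap a
#' differential recognition site.
#'
#' @param seq_a,seq_b Parental amplicon sequences.
#' @param enzymes Enzyme tibble from [load_enzymes()].
#' @param params Alignment parameters for SNP calling.
#' @return Tibble: `enzyme`, `site`, `diagnostic`, `n_fragments_a/b`,
#'   `fragments_a`, `fragments_b` (list columns), `snp_positions` (list of
#'   0-based alignment columns of overlapping SNPs or indels).
#' @export
find_caps <- function(seq_a, seq_b, enzymes = load_enzymes(),
                      params = align_params()) {
  if (nrow(enzymes) == 0L) stopf("empty enzyme table")
  seq_a <- norm_dna(seq_a); seq_b <- norm_dna(seq_b)
  snps <- call_snps(seq_a, seq_b, params)
  indels <- attr(snps, "indels")
  aln <- attr(snps, "alignment")
  a <- chars(aln$aligned_a); b <- chars(aln$aligned_b)
  # alignment column of each 0-based sequence position
  col_of_a <- which(a != "-") - 1L
  col_of_b <- which(b != "-") - 1L

  out <- list()
  for (i in seq_len(nrow(enzymes))) {
    enz <- enzymes[i, ]
    fa <- digest_pattern(seq_a, enz)
    fb <- digest_pattern(seq_b, enz)
    if (identical(sort(fa), sort(fb))) next
    # differential site matches, projected to alignment columns
    ma <- site_match_cols(seq_a, enz, col_of_a)
    mb <- site_match_cols(seq_b, enz, col_of_b)
    diff_sites <- c(setdiff_intervals(ma, mb), setdiff_intervals(mb, ma))
    snp_hits <- integer(0)
    for (iv in diff_sites) {
      snp_hits <- c(snp_hits,
                    snps$column[snps$column >= iv[1] & snps$column < iv[2]])
      if (nrow(indels) > 0L)
        snp_hits <- c(snp_hits,
                      indels$col_start[indels$col_start < iv[2] &
                                       indels$col_end > iv[1]])
    }
    out[[length(out) + 1L]] <- tibble(
      enzyme = enz$name, site = enz$site, diagnostic = TRUE,
      n_fragments_a = length(fa), n_fragments_b = length(fb),
      fragments_a = list(fa), fragments_b = list(fb),
      snp_positions = list(sort(unique(snp_hits))))
  }
  res <- if (length(out) == 0L) {
    tibble(enzyme = character(0), site = character(0), diagnostic = logical(0),
           n_fragments_a = integer(0), n_fragments_b = integer(0),
           fragments_a = list(), fragments_b = list(), snp_positions = list())
  } else bind_rows(out)
  structure(res, snps = snps)
}

# alignment-column intervals of all matches of an enzyme site (either strand)
# in one sequence
site_match_cols <- function(seq, enz, col_of) {
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enz$site)
  starts <- BiocGenerics::start(Biostrings::matchPattern(pat, subject,
                                                         fixed = FALSE)) - 1L
  if (!enz$palindromic) {
    rc <- Biostrings::reverseComplement(pat)
    starts <- c(starts,
                BiocGenerics::start(Biostrings::matchPattern(rc, subject,
                                                             fixed = FALSE)) - 1L)
  }
  starts <- sort(unique(starts))
  lapply(starts, function(s)
    c(col_of[s + 1L], col_of[s + nchar(enz$site)] + 1L))
}

# intervals in x with no identical counterpart in y
setdiff_intervals <- function(x, y) {
  keyy <- vapply(y, paste, character(1), collapse = ",")
  x[!vapply(x, paste, character(1), collapse = ",") %in% keyy]
}
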
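#' Construct an annotated gene model
#'
#' A `gene_model` holds one transcript's exon and CDS intervals on a
#' chromosome. Intervals are 0-based half-open and listed in transcript
#' (5'-to-3') order, i.e. ascending genomic coordinates on `+` and descending
#' on `-`.
#'
#' @param gene_id Gene/transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix of exon `[start, end)` intervals.
#' @param cds Two-column integer matrix of CDS intervals; every CDS interval
#'   must be contained in some exon.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds) {
  if (!is_string(gene_id) || !nzchar(gene_id)) stopf("gene_id must be a non-empty string")
  if (!strand %in% c("+", "-")) stopf("unknown strand '%s' for gene %s", strand, gene_id)
  exons <- as_interval_matrix(exons, "exons", gene_id)
  cds <- as_interval_matrix(cds, "cds", gene_id)
  if (nrow(exons) == 0L) stopf("gene %s has no exons", gene_id)
  check_transcript_order(exons, strand, "exons", gene_id)
  if (nrow(cds) > 0L) {
    check_transcript_order(cds, strand, "cds", gene_id)
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(inside))
      stopf("gene %s: CDS interval outside every exon", gene_id)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds),
    class = "gene_model"
  )
}

as_interval_matrix <- function(x, what, gene_id) {
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(is.na(x))) stopf("gene %s: NA in %s intervals", gene_id, what)
  if (any(x[, 2] <= x[, 1])) stopf("gene %s: empty/reversed %s interval", gene_id, what)
  x
}

check_transcript_order <- function(x, strand, what, gene_id) {
  if (nrow(x) < 2L) return(invisible())
  s <- x[, 1]
  e <- x[, 2]
  ok <- if (strand == "+") all(s[-1] >= e[-length(e)]) else all(e[-1] <= s[-length(s)])
  if (!ok) stopf("gene %s: %s intervals overlap or are out of transcript order", gene_id, what)
  invisible()
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%s  %d exon(s), %d CDS interval(s)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

# genomic span [start, end) covered by the gene's exons
gene_span <- function(model) {
  c(start = min(model$exons[, 1]), end = max(model$exons[, 2]))
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features linked by `ID`/`Parent` and
#' returns one [gene_model] per mRNA. GFF3 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `DNAStringSet`; when given, features on unknown
#'   chromosomes or extending past a chromosome end are errors.
#' @return A named list of `gene_model` objects (names = mRNA ids).
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("gene", "mRNA", "exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  parent <- md$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))

  mrna_idx <- which(type == "mRNA")
  if (length(mrna_idx) == 0L) stopf("no mRNA features in %s", path)
  models <- list()
  for (i in mrna_idx) {
    mid <- as.character(md$ID[i])
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    strand <- as.character(BiocGenerics::strand(gr[i]))
    if (!strand %in% c("+", "-"))
      stopf("mRNA %s has unknown strand '%s'", mid, strand)
    child <- which(parent1 == mid)
    ex <- child[type[child] == "exon"]
    cd <- child[type[child] == "CDS"]
    if (length(cd) == 0L) stopf("mRNA %s has no CDS features", mid)
    if (length(ex) == 0L) ex <- cd  # CDS-only annotation
    exm <- feature_matrix(gr[ex], strand)
    cdm <- feature_matrix(gr[cd], strand)
    # children must lie inside the mRNA span
    ms <- GenomicRanges::start(gr[i]) - 1L
    me <- GenomicRanges::end(gr[i])
    if (min(exm[, 1], cdm[, 1]) < ms || max(exm[, 2], cdm[, 2]) > me)
      stopf("mRNA %s: child feature outside parent span", mid)
    if (!is.null(genome)) {
      if (!chrom %in% names(genome))
        stopf("mRNA %s references unknown chromosome '%s'", mid, chrom)
      L <- length(genome[[chrom]])
      if (max(exm[, 2], cdm[, 2]) > L)
        stopf("mRNA %s: feature extends past end of chromosome %s", mid, chrom)
    }
    models[[mid]] <- gene_model(mid, chrom, strand, exm, cdm)
  }
  models
}

# GRanges features -> 0-based half-open matrix in transcript order
feature_matrix <- function(gr, strand) {
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  o <- if (strand == "+") order(s) else order(-s)
  cbind(start = s[o], end = e[o])
}
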
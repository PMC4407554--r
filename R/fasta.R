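#' Read a DNA FASTA file
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet].
#' Sequences are uppercased and `U` is converted to `T`. Characters outside
#' `A/C/G/T/N` are an error in strict mode and are converted to `N` otherwise.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default), duplicate record ids and non-ACGTN
#'   characters are errors; otherwise duplicates are kept and stray IUPAC or
#'   junk characters become `N`.
#' @return A named `DNAStringSet`; names are the first whitespace-delimited
#'   token of each header, the remainder of the header is kept in
#'   `mcols(x)$description`.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stopf("empty FASTA file: %s", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stopf("FASTA record with empty id in %s", path)
  if (anyDuplicated(ids)) {
    if (strict) stopf("duplicate FASTA ids: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- norm_dna(as.character(raw))
  if (any(nchar(seqs) == 0L)) stopf("FASTA record with empty sequence in %s", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (strict) {
      offending <- unique(unlist(lapply(seqs[bad], bad_dna_chars)))
      stopf("illegal characters in FASTA (%s); use strict = FALSE to convert to N",
            paste(offending, collapse = ", "))
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `DNAStringSet` or a named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stopf("all records must be named to write FASTA")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# fetch one chromosome as a plain character string
chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stopf("chromosome '%s' not present in genome", chrom)
  as.character(genome[[chrom]])
}
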
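# All coordinates inside the package are 0-based half-open intervals; the
# 1-based inclusive convention appears only in GFF3 input and human-readable
# report columns.

# substring under the 0-based half-open convention
subseq0 <- function(x, start, end) substr(x, start + 1L, end)

# vectorised reverse complement of plain character DNA (ACGTN)
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# normalise raw sequence text: uppercase, U -> T
norm_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# check alphabet; returns offending characters
bad_dna_chars <- function(x, alphabet = c("A", "C", "G", "T", "N")) {
  setdiff(unique(chars(x)), alphabet)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))
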
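# Unified nearest-neighbor parameters for DNA duplex formation
# (SantaLucia 1998 unified set). dH in kcal/mol, dS in cal/(mol K).
.nn_dh <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# duplex initiation per terminal base
.init_dh <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.init_ds <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

.gas_const <- 1.987  # cal / (mol K)

#' Primer melting temperature (nearest-neighbor model)
#'
#' Two-state nearest-neighbor thermodynamics with the unified parameter set
#' and an entropic monovalent-salt correction
#' (`dS + 0.368 * (N - 1) * ln[Na+]`, N = primer length). The primer is
#' assumed to be in excess over template (Tm uses `CT/4`).
#'
#' @param seq Character vector of primer sequences, 8-50 nt, `A/C/G/T` only.
#' @param primer_conc Total strand concentration in mol/L (default 250 nM).
#' @param na_conc Monovalent cation concentration in mol/L (default 50 mM).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temp <- function(seq, primer_conc = 250e-9, na_conc = 0.05) {
  seq <- norm_dna(seq)
  n <- nchar(seq)
  if (any(n < 8L | n > 50L))
    stopf("primer length out of range [8, 50]")
  if (any(grepl("[^ACGT]", seq)))
    stopf("ambiguous base in primer; Tm requires A/C/G/T only")
  vapply(seq, function(s) {
    L <- nchar(s)
    nn <- substring(s, 1:(L - 1L), 2:L)
    b1 <- substr(s, 1L, 1L); bL <- substr(s, L, L)
    dh <- sum(.nn_dh[nn]) + .init_dh[[b1]] + .init_dh[[bL]]
    ds <- sum(.nn_ds[nn]) + .init_ds[[b1]] + .init_ds[[bL]]
    ds <- ds + 0.368 * (L - 1L) * log(na_conc)
    dh * 1000 / (ds + .gas_const * log(primer_conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# GC fraction of a primer, in percent
gc_percent <- function(seq) {
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) 100 * sum(ch %in% c("G", "C")) / length(ch),
         numeric(1))
}
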
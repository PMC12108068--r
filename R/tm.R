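#' Nearest-neighbor melting temperature of fully specified oligos
#'
#' Two-state nearest-neighbor model with the unified Watson-Crick parameter
#' set (SantaLucia & Hicks 2004): duplex enthalpy/entropy accumulated over
#' dinucleotide stacks plus initiation and terminal A/T penalties, a
#' monovalent-salt entropy correction of 0.368 (N-1) ln[Na+], and
#'
#'   Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15
#'
#' for non-self-complementary duplexes at total strand concentration `CT`.
#' Defaults (50 mM Na+, 250 pM oligo) reflect hybridization-capture pools
#' where each probe is present at picomolar concentration. Tm is strand
#' symmetric: `melting_temperature(s) == melting_temperature(revcomp(s))`.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T only; `N` or other
#'   ambiguity codes are an error — probes must be fully specified).
#' @param na_mM Monovalent cation concentration in mM.
#' @param oligo_conc_M Total oligo concentration CT in mol/L.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(seq, na_mM = 50, oligo_conc_M = 250e-12) {
  if (length(seq) == 0) return(numeric(0))
  if (any(grepl("[^ACGT]", seq))) {
    stop("melting_temperature requires fully specified ACGT sequences")
  }
  if (any(nchar(seq) < 2)) stop("sequences must have length >= 2")
  out <- numeric(length(seq))
  lens <- nchar(seq)
  for (L in unique(lens)) {
    i <- which(lens == L)
    s <- seq[i]
    term_at <- (substr(s, 1L, 1L) %in% c("A", "T")) +
      (substr(s, L, L) %in% c("A", "T"))
    dH <- 0.2 + 2.2 * term_at
    dS <- -5.7 + 6.9 * term_at
    for (k in seq_len(L - 1L)) {
      din <- substr(s, k, k + 1L)
      dH <- dH + unname(.NN_DH[din])
      dS <- dS + unname(.NN_DS[din])
    }
    dS <- dS + 0.368 * (L - 1L) * log(na_mM / 1000)
    out[i] <- 1000 * dH / (dS + 1.987 * log(oligo_conc_M / 4)) - 273.15
  }
  out
}

# unified NN parameters, kcal/mol (dH) and cal/(mol K) (dS);
# keys cover all 16 dinucleotides via reverse-complement equivalence
.NN_DH <- c(AA = -7.6, TT = -7.6, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -21.3, TT = -21.3, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of DNA (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
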
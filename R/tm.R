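# Unified nearest-neighbor thermodynamic parameters (dH kcal/mol, dS cal/mol/K)
# for DNA/DNA duplexes; 5'->3' dinucleotide stacks.
NN_DH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
  GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
  TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4, CT = -21.0,
  GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
  TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9
)
# duplex initiation terms per terminal base pair
NN_INIT_DH <- c(AT = 2.3, GC = 0.1)
NN_INIT_DS <- c(AT = 4.1, GC = -2.8)

#' Nearest-neighbor primer melting temperature
#'
#' Computes the duplex melting temperature of a primer against its perfect
#' complement using the unified nearest-neighbor thermodynamic parameter set,
#' with entropic salt correction \eqn{\Delta S + 0.368 (N-1) \ln[\mathrm{Na}^+]}
#' and \eqn{T_m = 1000\,\Delta H / (\Delta S + R \ln C_T) - 273.15}.
#'
#' @param seq primer sequence (A/C/G/T only, length >= 8).
#' @param na_molar monovalent cation concentration in mol/L (default 0.05,
#'   i.e. 50 mM).
#' @param primer_molar primer strand concentration in mol/L (default 2.5e-7,
#'   i.e. 250 nM; template assumed negligible).
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("CGTTCAAAAGCGTGTCCTGTG")
melting_temperature <- function(seq, na_molar = 0.05, primer_molar = 250e-9) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 8L) stop("melting_temperature: primer shorter than 8 bases")
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("melting_temperature: ambiguity codes not allowed in primer: ", seq)
  }
  stacks <- paste0(chars[-length(chars)], chars[-1])
  dH <- sum(NN_DH[stacks])
  dS <- sum(NN_DS[stacks])
  term <- function(b) if (b %in% c("A", "T")) "AT" else "GC"
  dH <- dH + NN_INIT_DH[[term(chars[1])]] + NN_INIT_DH[[term(chars[length(chars)])]]
  dS <- dS + NN_INIT_DS[[term(chars[1])]] + NN_INIT_DS[[term(chars[length(chars)])]]
  dS <- dS + 0.368 * (length(chars) - 1L) * log(na_molar)
  R <- 1.987 # cal/mol/K
  tm_k <- 1000 * dH / (dS + R * log(primer_molar))
  tm_k - 273.15
}

#' GC fraction of a sequence
#'
#' @param seq character string over A/C/G/T.
#' @return Fraction of G or C bases, in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}
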
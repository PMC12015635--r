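# IUPAC nucleotide ambiguity codes -> the set of concrete bases each denotes.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# base-pair complement over the full IUPAC alphabet
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' IUPAC code for a set of bases
#'
#' Returns the single-letter ambiguity code denoting exactly the given set of
#' concrete bases (e.g. `c("A","G")` -> `"R"`). Used to encode heterozygous
#' positions in consensus flank sequences.
#'
#' @param bases character vector of bases from `A`, `C`, `G`, `T`.
#' @return A single IUPAC character.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("iupac_code: bases must be A/C/G/T, got: ", paste(bases, collapse = ","))
  }
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  stop("iupac_code: no code for base set ", paste(bases, collapse = ","))
}

#' Reverse complement of an IUPAC sequence
#'
#' @param seq single character string over the IUPAC alphabet.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(IUPAC_COMPLEMENT)
  if (any(bad)) stop("revcomp: non-IUPAC symbol(s): ", paste(unique(chars[bad]), collapse = ","))
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# Translate an IUPAC pattern into a PCRE character-class regex that matches
# concrete A/C/G/T subjects only: ambiguity is honoured on the pattern side,
# while N or ambiguity codes in the subject never match (an uncertain base
# cannot certify a recognition site).
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) stop("invalid IUPAC symbol(s) in pattern: ", paste(unique(chars[bad]), collapse = ","))
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All start positions (1-based) where the IUPAC pattern matches the subject,
# including overlapping occurrences.
iupac_match_positions <- function(subject, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, toupper(subject), perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# TRUE when the recognition sequence is its own IUPAC-aware reverse complement
is_palindromic <- function(recognition) {
  identical(toupper(recognition), revcomp(recognition))
}

#' Format a SNP identifier
#'
#' Identifiers follow the `<contig>_<pos>_<ref>_<alt>` convention used in
#' candidate tables and marker reports (e.g. `1_14411896_T_C`).
#'
#' @param contig contig/scaffold name.
#' @param pos 1-based position.
#' @param ref,alt alleles.
#' @return character vector of IDs.
#' @export
snp_id <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = "_")
}
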
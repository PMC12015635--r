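#' Construct a genotype matrix object
#'
#' The central container of the pipeline: per-site metadata plus a dosage
#' matrix coding each diploid call by its count of the \emph{reference}
#' allele (2 = reference homozygote, 1 = heterozygote, 0 = alternate
#' homozygote, `NA` = missing) and an optional per-call read-depth matrix.
#' Internally all coordinates are 1-based (VCF convention at every surface).
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated for multi-allelic records).
#' @param dosage integer matrix, sites x samples, values in `{0,1,2,NA}`.
#' @param samples character vector of sample names (column order).
#' @param depth optional numeric matrix of per-call read depths (`NA` =
#'   depth unknown).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosage, samples, depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(sites)) stop("genotype_matrix: sites/dosage row mismatch")
  if (ncol(dosage) != length(samples)) stop("genotype_matrix: samples/dosage column mismatch")
  if (!all(dosage %in% c(0L, 1L, 2L, NA))) stop("genotype_matrix: dosage values must be 0/1/2/NA")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(dosage))) stop("genotype_matrix: depth dimensions differ from dosage")
  }
  if (any(sites$pos < 1)) stop("genotype_matrix: positions must be 1-based (>= 1)")
  sites$snp_id <- snp_id(sites$contig, sites$pos,
                         sites$ref, sub(",.*", "", sites$alt))
  rownames(dosage) <- sites$snp_id
  colnames(dosage) <- samples
  if (!is.null(depth)) dimnames(depth) <- dimnames(dosage)
  structure(list(sites = sites, dosage = dosage, depth = depth,
                 samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%s depth)\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$depth)) "no" else "with"))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return Integer site count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix by site index
#' @param gm a `genotype_matrix`.
#' @param idx integer or logical index over sites.
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE],
                  gm$dosage[idx, , drop = FALSE],
                  gm$samples,
                  if (is.null(gm$depth)) NULL else gm$depth[idx, , drop = FALSE])
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named character vector of uppercase sequences; names are the
#'   first whitespace token of each header, full headers kept in the
#'   `headers` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("read_fasta: no records in ", path)
  headers <- names(set)
  nms <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nms)) stop("read_fasta: duplicate contig names in ", path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("read_fasta: empty record in ", path)
  names(seqs) <- nms
  attr(seqs, "headers") <- headers
  seqs
}

#' Write a genome to FASTA (60-column wrap)
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unlist(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# dosage (count of REF allele) from a vector of GT strings such as
# "0/1", "1|0", "./."; ploidy other than 2 is an error.
gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("gt_to_dosage: non-diploid genotype '", paste(p, collapse = "/"), "'")
    if (any(p == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(p))
    if (any(is.na(a))) stop("gt_to_dosage: malformed genotype")
    sum(a == 0L)
  }, integer(1))
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads every record (multi-allelic records and indels are preserved here and
#' rejected later by [basic_filter()]); requires a GT FORMAT field, uses DP
#' when present. For records that are not biallelic SNPs the dosage is coded
#' against allele 0 vs any alternate.
#'
#' @param path VCF file (plain or gzipped).
#' @param genome optional genome from [read_fasta()]; when supplied, each
#'   record's REF is cross-checked against the genome sequence.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("read_vcf: no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("read_vcf: no records in ", path)
  fmt <- v@gt[, "FORMAT", drop = TRUE]
  if (!all(grepl("GT", fmt))) stop("read_vcf: GT FORMAT field required in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  dosage <- apply(gt, 2L, function(col) {
    col[is.na(col)] <- "./."
    gt_to_dosage(col)
  })
  dosage <- matrix(as.integer(dosage), nrow = nrow(fix),
                   dimnames = list(NULL, samples))
  depth <- NULL
  if (any(grepl("DP", fmt))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- matrix(as.numeric(dp), nrow = nrow(fix),
                    dimnames = list(NULL, samples))
  }
  sites <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    for (i in seq_len(nrow(sites))) {
      ctg <- sites$contig[i]
      if (!ctg %in% names(genome)) {
        stop("read_vcf: contig '", ctg, "' absent from genome")
      }
      span <- nchar(sites$ref[i])
      obs <- substr(genome[[ctg]], sites$pos[i], sites$pos[i] + span - 1L)
      if (!identical(obs, toupper(sites$ref[i]))) {
        stop("read_vcf: REF mismatch at ", ctg, ":", sites$pos[i],
             " (VCF ", sites$ref[i], ", genome ", obs, ")")
      }
    }
  }
  genotype_matrix(sites, dosage, samples, depth)
}

#' Write a candidate table as TSV
#'
#' Rows carry `snp_id` in the `<contig>_<pos>_<ref>_<alt>` format; column and
#' row order are stable so outputs are byte-reproducible.
#'
#' @param records data.frame of candidates (may be empty; header still written).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_candidate_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = NA,
                    check.names = FALSE)
}
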
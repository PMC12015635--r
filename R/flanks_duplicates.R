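#' Extract per-sample consensus flanks around a SNP
#'
#' Builds the reference flank (`radius` bp each side of the SNP, clipped at
#' contig edges with a record of the clipping) and one consensus sequence
#' per sample: homozygous-alternate substitutions are applied, heterozygous
#' substitutions become the two-base IUPAC code, untyped positions become
#' `N`. Heterozygous or untyped indels are masked as an `N`-run over the
#' REF span (one sequence per sample, and primers can never sit on an
#' uncertain position); homozygous-alternate indels are applied literally.
#'
#' @param genome named character vector of contigs.
#' @param gm a `genotype_matrix` covering the flank's variant sites (use the
#'   full pre-filter matrix so every known polymorphism is encoded).
#' @param site_index row index of the focal SNP in `gm$sites`.
#' @param radius flank radius in bp (default 1000).
#' @return An object of class `flank_set`.
#' @export
extract_flanks <- function(genome, gm, site_index, radius = 1000L) {
  site <- gm$sites[site_index, ]
  if (!site$contig %in% names(genome)) stop("extract_flanks: contig not in genome")
  ctg <- genome[[site$contig]]
  if (nchar(site$ref) != 1L) stop("extract_flanks: focal site must be a SNP")
  start <- site$pos - radius
  end <- site$pos + radius
  clipped <- start < 1L || end > nchar(ctg)
  if (clipped) warning("extract_flanks: flank clipped at contig edge for ", site$snp_id)
  start <- max(1L, start); end <- min(nchar(ctg), end)
  ref_flank <- substr(ctg, start, end)
  snp_offset <- site$pos - start # 0-based index of the SNP in the flank

  # variant records overlapping the flank
  span_end <- gm$sites$pos + nchar(gm$sites$ref) - 1L
  idx <- which(gm$sites$contig == site$contig &
                 gm$sites$pos <= end & span_end >= start)
  vars <- gm$sites[idx, , drop = FALSE]
  vd <- gm$dosage[idx, , drop = FALSE]
  all_ref <- apply(vd, 1L, function(r) all(!is.na(r) & r == 2L))

  variants <- data.frame(pos = vars$pos, ref = vars$ref,
                         alt = vars$alt,
                         offset = vars$pos - start,
                         ref_len = nchar(vars$ref),
                         all_ref_typed = all_ref,
                         stringsAsFactors = FALSE)

  samples <- gm$samples
  sample_flanks <- stats::setNames(character(length(samples)), samples)
  ord <- order(variants$pos, decreasing = TRUE) # right-to-left keeps offsets valid
  for (s in seq_along(samples)) {
    chars <- strsplit(ref_flank, "", fixed = TRUE)[[1]]
    out <- paste(chars, collapse = "")
    for (v in ord) {
      d <- vd[v, s]
      o <- variants$offset[v] + 1L # 1-based within flank
      rl <- variants$ref_len[v]
      alt1 <- sub(",.*", "", variants$alt[v])
      multi <- grepl(",", variants$alt[v], fixed = TRUE)
      is_sub <- rl == 1L && nchar(alt1) == 1L && !multi
      lo <- max(1L, o); hi <- min(nchar(out), o + rl - 1L)
      if (is_sub) {
        if (is.na(d)) {
          substr(out, o, o) <- "N"
        } else if (d == 1L) {
          substr(out, o, o) <- iupac_code(c(variants$ref[v], alt1))
        } else if (d == 0L) {
          substr(out, o, o) <- alt1
        }
      } else {
        if (!is.na(d) && d == 0L && !multi) {
          out <- paste0(substr(out, 1L, lo - 1L), alt1,
                        substr(out, hi + 1L, nchar(out)))
        } else if (is.na(d) || d != 2L) {
          substr(out, lo, hi) <- paste(rep("N", hi - lo + 1L), collapse = "")
        }
      }
    }
    sample_flanks[s] <- out
  }

  structure(list(site = as.list(site), radius = radius,
                 reference_flank = ref_flank, sample_flanks = sample_flanks,
                 snp_offset = snp_offset, flank_start = start,
                 clipped = clipped, variants = variants),
            class = "flank_set")
}

#' Conserved-position map of a flank
#'
#' A flank position is conserved (eligible for primer placement) when it is
#' a concrete A/C/G/T in the reference and is not covered by the REF span
#' of any variant record at which some sample is non-reference or untyped.
#'
#' @param flank a `flank_set`.
#' @return Logical vector along the reference flank.
#' @export
flank_conserved <- function(flank) {
  chars <- strsplit(flank$reference_flank, "", fixed = TRUE)[[1]]
  conserved <- chars %in% c("A", "C", "G", "T")
  v <- flank$variants
  for (i in seq_len(nrow(v))) {
    if (isTRUE(v$all_ref_typed[i])) next
    lo <- max(1L, v$offset[i] + 1L)
    hi <- min(length(conserved), v$offset[i] + v$ref_len[i])
    if (hi >= lo) conserved[lo:hi] <- FALSE
  }
  conserved
}

#' Export a flank set as FASTA
#'
#' One file per candidate SNP: the reference flank plus every sample flank,
#' headers carrying the SNP ID and sample name.
#'
#' @param flank a `flank_set`.
#' @param path output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_flank_fasta <- function(flank, path) {
  seqs <- c(stats::setNames(flank$reference_flank,
                            paste0(flank$site$snp_id, "|reference")),
            stats::setNames(flank$sample_flanks,
                            paste0(flank$site$snp_id, "|", names(flank$sample_flanks))))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1, nchar(s), 60), pmin(nchar(s), seq(60, nchar(s) + 59, 60))), con)
  }
  invisible(path)
}

# seed-and-extend search of `query` against one contig sequence (one strand)
scan_contig <- function(query, contig_seq, k, scoring) {
  qlen <- nchar(query)
  starts <- seq_len(qlen - k + 1L)
  kmers <- substring(query, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  if (!any(keep)) return(NULL)
  kmers <- kmers[keep]; koff <- starts[keep]
  uniq <- !duplicated(kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[uniq]))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(contig_seq))
  cand <- integer(0)
  uo <- koff[uniq]
  for (i in seq_along(hits)) {
    st <- BiocGenerics::start(hits[[i]])
    if (length(st)) cand <- c(cand, st - uo[i] + 1L)
  }
  if (!length(cand)) return(NULL)
  cand <- sort(unique(pmax(1L, cand)))
  # cluster candidate starts within half a query of each other
  grp <- cumsum(c(TRUE, diff(cand) > qlen %/% 2L))
  out <- NULL
  pad <- 12L
  for (g in unique(grp)) {
    cs <- cand[grp == g]
    lo <- max(1L, min(cs) - pad)
    hi <- min(nchar(contig_seq), max(cs) + qlen - 1L + pad)
    target <- substr(contig_seq, lo, hi)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(target),
      type = "global-local", substitutionMatrix = scoring$mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- Biostrings::nmatch(aln) / alen
    sub_rng <- aln@subject@range
    out <- rbind(out, data.frame(
      start = lo + BiocGenerics::start(sub_rng) - 1L,
      end = lo + BiocGenerics::end(sub_rng) - 1L,
      identity = ident, stringsAsFactors = FALSE))
  }
  out
}

#' Screen a candidate flank for duplicated regions
#'
#' Seed-and-extend local search (exact k-mer seeds, gapped extension with
#' megablast-like scoring: match +1, mismatch -2, gap open 2.5, gap extend
#' 0.5) of windows centred on the SNP against both strands of every
#' supplied genome. Identity is matches over alignment columns including
#' gaps. The query is taken from the reference flank, so the hit at the
#' marker's own locus (the self-hit, identity 1) is always reported.
#'
#' @param flank a `flank_set`.
#' @param genomes named list of genomes (each a named character vector of
#'   contigs); must include the marker's own reference.
#' @param window_small,window_large odd window widths in bp (default 41 and
#'   201, i.e. 20 and 100 bp each side of the SNP).
#' @param identity_min minimum identity for a hit to count as qualifying.
#' @param k_small,k_large seed k-mer sizes for the two windows.
#' @return data.frame of hits: `query_id`, `window`, `genome`, `contig`,
#'   `start`, `end`, `strand`, `identity`, `overlaps_snp`, `qualifying`.
#' @export
duplicate_scan <- function(flank, genomes, window_small = 41L,
                           window_large = 201L, identity_min = 0.90,
                           k_small = 11L, k_large = 16L) {
  if (is.null(names(genomes))) names(genomes) <- paste0("genome_", seq_along(genomes))
  scoring <- list(
    mat = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                   baseOnly = TRUE),
    gap_open = 2.5, gap_extend = 0.5)
  snp_idx <- flank$snp_offset + 1L
  flen <- nchar(flank$reference_flank)
  out <- NULL
  for (w in c(window_small, window_large)) {
    if (w %% 2L == 0L) stop("duplicate_scan: window widths must be odd")
    half <- (w - 1L) %/% 2L
    if (snp_idx - half < 1L || snp_idx + half > flen) {
      stop("duplicate_scan: window of ", w, " bp exceeds the flank")
    }
    query <- substr(flank$reference_flank, snp_idx - half, snp_idx + half)
    k <- if (w <= 100L) k_small else k_large
    for (gname in names(genomes)) {
      gen <- genomes[[gname]]
      for (ctg in names(gen)) {
        for (strand in c("+", "-")) {
          q <- if (strand == "+") query else revcomp(query)
          hits <- scan_contig(q, gen[[ctg]], k, scoring)
          if (is.null(hits)) next
          out <- rbind(out, data.frame(
            query_id = flank$site$snp_id, window = w, genome = gname,
            contig = ctg, start = hits$start, end = hits$end,
            strand = strand, identity = hits$identity,
            overlaps_snp = TRUE, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), window = integer(0),
                      genome = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      overlaps_snp = logical(0), stringsAsFactors = FALSE)
  } else {
    # dedupe hits of one window covering the same locus on both strands or
    # from overlapping seed clusters: keep the best identity
    key <- paste(out$window, out$genome, out$contig,
                 round(out$start / 20))
    out <- out[order(key, -out$identity), , drop = FALSE]
    out <- out[!duplicated(paste(out$window, out$genome, out$contig,
                                 round(out$start / 20))), , drop = FALSE]
    rownames(out) <- NULL
  }
  out$qualifying <- out$identity >= identity_min & out$overlaps_snp
  out
}

#' Verdict of the duplicate screen
#'
#' Fails when, within any single genome, more than one hit qualifies
#' (identity at or above the threshold and overlapping the SNP) for the
#' same scan window — the self-hit counts as the first occurrence, so any
#' qualifying second hit means the locus lies in a duplicated region.
#'
#' @param hits data.frame from [duplicate_scan()].
#' @return `list(pass, reason)`.
#' @export
duplicate_verdict <- function(hits) {
  q <- hits[hits$qualifying, , drop = FALSE]
  if (nrow(q) == 0L) {
    return(list(pass = FALSE, reason = "no self-hit found"))
  }
  tab <- stats::aggregate(qualifying ~ genome + window, data = q, FUN = length)
  if (any(tab$qualifying > 1L)) {
    g <- tab$genome[which.max(tab$qualifying)]
    return(list(pass = FALSE,
                reason = paste0("duplicated region: ", max(tab$qualifying),
                                " qualifying hits in genome '", g, "'")))
  }
  list(pass = TRUE, reason = "unique")
}
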
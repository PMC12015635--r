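#' Load a restriction-enzyme catalog
#'
#' Reads a REBASE-like TSV with columns `name`, `recognition` (IUPAC),
#' `cut_top`, `cut_bottom` (cut offsets in bp from the 5' end of the
#' recognition sequence on the top strand; offsets may exceed the
#' recognition length for offset cutters such as MnlI) and optionally
#' `source`. The packaged catalog covers the enzymes used by the bundled
#' Arabidopsis lyrata marker panel plus common six-base cutters, with
#' recognition sites and offsets transcribed from the public REBASE
#' listings.
#'
#' @param path catalog TSV; defaults to the packaged catalog.
#' @return data.frame of class `enzyme_catalog` with an added `palindromic`
#'   column.
#' @export
load_enzyme_catalog <- function(path = system.file("extdata", "restriction_enzymes.tsv",
                                                   package = "capsforge")) {
  cat <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_top", "cut_bottom")
  if (!all(need %in% names(cat))) stop("load_enzyme_catalog: missing columns")
  if (nrow(cat) == 0L) {
    warning("load_enzyme_catalog: empty catalog")
    cat$palindromic <- logical(0)
    class(cat) <- c("enzyme_catalog", "data.frame")
    return(cat)
  }
  cat$recognition <- toupper(cat$recognition)
  for (i in seq_len(nrow(cat))) {
    chars <- strsplit(cat$recognition[i], "", fixed = TRUE)[[1]]
    if (length(chars) == 0L || !all(chars %in% names(IUPAC_SETS))) {
      stop("load_enzyme_catalog: malformed recognition for enzyme '",
           cat$name[i], "': ", cat$recognition[i])
    }
  }
  cat$palindromic <- vapply(cat$recognition, is_palindromic, logical(1),
                            USE.NAMES = FALSE)
  class(cat) <- c("enzyme_catalog", "data.frame")
  cat
}

#' Find recognition-site matches in a sequence
#'
#' IUPAC degeneracy is honoured on the pattern side only; `N` or ambiguity
#' codes in the subject never match (an uncertain base cannot certify a
#' site). Reverse-strand matches of non-palindromic sites are reported as
#' the forward-coordinate start of the matched span.
#'
#' @param sequence subject sequence.
#' @param enzyme one catalog row (list or single-row data.frame).
#' @param both_strands scan the reverse strand too (default TRUE; palindromic
#'   sites are only reported once).
#' @return data.frame with `pos` (1-based start) and `strand` (`"+"`/`"-"`).
#' @export
match_recognition <- function(sequence, enzyme, both_strands = TRUE) {
  rec <- toupper(enzyme$recognition)
  fwd <- iupac_match_positions(sequence, rec)
  out <- data.frame(pos = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands && !is_palindromic(rec)) {
    rev <- iupac_match_positions(sequence, revcomp(rec))
    out <- rbind(out, data.frame(pos = rev, strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

# Offset of the sense-strand cut from the start of a matched recognition
# span, by match strand. For a minus-strand match the amplicon sense strand
# is cut at the enzyme's bottom-strand position.
cut_offset_for_strand <- function(enzyme, strand) {
  L <- nchar(enzyme$recognition)
  if (strand == "+") enzyme$cut_top else L - enzyme$cut_bottom
}

# both allele versions of the reference flank sequence
flank_allele_versions <- function(flank) {
  seq_ref <- flank$reference_flank
  seq_alt <- seq_ref
  substr(seq_alt, flank$snp_offset + 1L, flank$snp_offset + 1L) <- flank$site$alt
  list(ref = seq_ref, alt = seq_alt)
}

# matches of `enzyme` overlapping 1-based index `idx` in `seq`
overlapping_matches <- function(seq, enzyme, idx) {
  m <- match_recognition(seq, enzyme, both_strands = TRUE)
  L <- nchar(enzyme$recognition)
  m[m$pos <= idx & idx <= m$pos + L - 1L, , drop = FALSE]
}

#' Discover allele-specific restriction sites at a SNP
#'
#' For each catalog enzyme, both allele versions of the reference flank are
#' scanned in the window reaching one recognition length either side of the
#' SNP. A candidate is emitted iff exactly one allele version carries at
#' least one recognition match overlapping the SNP while the other carries
#' none — the CAPS condition: the SNP creates or destroys the site.
#'
#' @param flank a `flank_set` (see [extract_flanks()]).
#' @param catalog an `enzyme_catalog`.
#' @return data.frame of candidates: `snp_id`, `enzyme`, `digest_allele`,
#'   `match_offset` (SNP-relative, 0 = site starts at the SNP), `strand`.
#' @export
allele_specific_sites <- function(flank, catalog) {
  versions <- flank_allele_versions(flank)
  snp_idx <- flank$snp_offset + 1L
  out <- NULL
  for (i in seq_len(nrow(catalog))) {
    enz <- as.list(catalog[i, ])
    L <- nchar(enz$recognition)
    lo <- max(1L, snp_idx - (L - 1L))
    hi <- min(nchar(versions$ref), snp_idx + (L - 1L))
    win_ref <- substr(versions$ref, lo, hi)
    win_alt <- substr(versions$alt, lo, hi)
    idx <- snp_idx - lo + 1L
    m_ref <- overlapping_matches(win_ref, enz, idx)
    m_alt <- overlapping_matches(win_alt, enz, idx)
    hit <- NULL
    if (nrow(m_ref) >= 1L && nrow(m_alt) == 0L) {
      hit <- list(allele = flank$site$ref, m = m_ref[1, ])
    } else if (nrow(m_alt) >= 1L && nrow(m_ref) == 0L) {
      hit <- list(allele = flank$site$alt, m = m_alt[1, ])
    }
    if (!is.null(hit)) {
      out <- rbind(out, data.frame(
        snp_id = flank$site$snp_id, enzyme = enz$name,
        digest_allele = hit$allele,
        match_offset = hit$m$pos + lo - 1L - snp_idx,
        strand = hit$m$strand, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(snp_id = character(0), enzyme = character(0),
                      digest_allele = character(0),
                      match_offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

# constitutive matches (present for both alleles, same pos and strand)
constitutive_matches <- function(flank, enzyme, lo, hi) {
  versions <- flank_allele_versions(flank)
  m_ref <- match_recognition(substr(versions$ref, lo, hi), enzyme)
  m_alt <- match_recognition(substr(versions$alt, lo, hi), enzyme)
  key_ref <- paste(m_ref$pos, m_ref$strand)
  key_alt <- paste(m_alt$pos, m_alt$strand)
  m <- m_ref[key_ref %in% key_alt, , drop = FALSE]
  m$pos <- m$pos + lo - 1L
  m
}

#' Local uniqueness of the allele-specific site
#'
#' Fails when the candidate's enzyme has a constitutive recognition match
#' (present for both alleles) whose span intersects the window
#' `exclusion_radius` bp either side of the SNP: such a site would be cut
#' regardless of genotype and confound nearby band patterns.
#'
#' @param flank a `flank_set`.
#' @param candidate one row from [allele_specific_sites()].
#' @param catalog enzyme catalog.
#' @param exclusion_radius radius in bp (default 150).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
uniqueness_check <- function(flank, candidate, catalog, exclusion_radius = 150L) {
  enz <- as.list(catalog[catalog$name == candidate$enzyme, ])
  L <- nchar(enz$recognition)
  snp_idx <- flank$snp_offset + 1L
  lo <- max(1L, snp_idx - exclusion_radius - (L - 1L))
  hi <- min(nchar(flank$reference_flank), snp_idx + exclusion_radius + (L - 1L))
  m <- constitutive_matches(flank, enz, lo, hi)
  if (nrow(m) == 0L) return(TRUE)
  span_lo <- snp_idx - exclusion_radius
  span_hi <- snp_idx + exclusion_radius
  !any(m$pos <= span_hi & m$pos + L - 1L >= span_lo)
}

#' Primer-design constraints
#'
#' Defaults encode the design rules of the assay: primer length 15-25 nt,
#' GC between 20 and 80 percent, Tm between 57 and 63 degrees C with at
#' most 3 degrees between the pair, primers placed in conserved flank
#' sequence 150-600 bp from the recognition site on each side, amplicon
#' 590-1000 bp, and both digest fragments at least 100 bp. Ranking weights:
#' score = |Tm_f - tm_target| + |Tm_r - tm_target| + |dTm| +
#' amp_weight * |amplicon - amp_target|.
#'
#' @param len_min,len_max primer length bounds (nt).
#' @param gc_min,gc_max GC-fraction bounds.
#' @param tm_min,tm_max primer Tm bounds (deg C).
#' @param dtm_max maximum pair Tm difference (deg C).
#' @param dist_min,dist_max primer-to-recognition-site gap bounds (bp).
#' @param amp_min,amp_max amplicon length bounds (bp).
#' @param frag_min minimum digest fragment (bp).
#' @param tm_target,amp_target,amp_weight ranking parameters.
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(len_min = 15L, len_max = 25L,
                               gc_min = 0.20, gc_max = 0.80,
                               tm_min = 57, tm_max = 63, dtm_max = 3,
                               dist_min = 150L, dist_max = 600L,
                               amp_min = 590L, amp_max = 1000L,
                               frag_min = 100L,
                               tm_target = 60, amp_target = 750L,
                               amp_weight = 1 / 150) {
  structure(as.list(environment()), class = "primer_constraints")
}

# enumerate one side's primer windows; side = "F" scans ends left of the
# site, side = "R" scans starts right of it. Returns the per-constraint
# pruning tally in attribute "tally".
enumerate_primers <- function(seq, conserved, side, m_start, m_end, cns) {
  flank_len <- nchar(seq)
  csum <- c(0L, cumsum(conserved))
  all_conserved <- function(s, e) (csum[e + 1L] - csum[s]) == (e - s + 1L)
  rows <- list()
  tally <- c(conserved = 0L, gc = 0L, tm = 0L)
  for (len in cns$len_min:cns$len_max) {
    if (side == "F") {
      ends <- (m_start - cns$dist_max - 1L):(m_start - cns$dist_min - 1L)
      ends <- ends[ends - len + 1L >= 1L]
      starts <- ends - len + 1L
    } else {
      starts <- (m_end + cns$dist_min + 1L):(m_end + cns$dist_max + 1L)
      starts <- starts[starts + len - 1L <= flank_len]
      ends <- starts + len - 1L
    }
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- ends[k]
      if (s < 1L || e > flank_len) next
      if (!all_conserved(s, e)) { tally["conserved"] <- tally["conserved"] + 1L; next }
      sub <- substr(seq, s, e)
      gc <- gc_fraction(sub)
      if (gc < cns$gc_min || gc > cns$gc_max) { tally["gc"] <- tally["gc"] + 1L; next }
      primer <- if (side == "F") sub else revcomp(sub)
      tm <- melting_temperature(primer)
      if (tm < cns$tm_min || tm > cns$tm_max) { tally["tm"] <- tally["tm"] + 1L; next }
      rows[[length(rows) + 1L]] <- c(s, e, gc, tm)
    }
  }
  out <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    as.data.frame(matrix(numeric(0), ncol = 4))
  names(out) <- c("start", "end", "gc", "tm")
  attr(out, "tally") <- tally
  out
}

#' Design PCR-RFLP primer pairs for a candidate
#'
#' Exhaustively enumerates primer windows lying entirely in conserved flank
#' sequence (invariant and unambiguous across the reference and all sample
#' flanks) at the configured distance from the recognition site on each
#' side, keeps pairs meeting every constraint, and returns complete marker
#' specifications ranked by the documented score (deterministic, coordinate
#' tie-break).
#'
#' @param flank a `flank_set`.
#' @param candidate one row from [allele_specific_sites()].
#' @param catalog enzyme catalog.
#' @param constraints a [primer_constraints()].
#' @param max_pairs maximum number of ranked specs returned.
#' @return data.frame of marker specs (possibly 0 rows; the
#'   `"failure_tally"` attribute reports which constraint pruned most).
#' @export
design_primers <- function(flank, candidate, catalog,
                           constraints = primer_constraints(),
                           max_pairs = 50L) {
  cns <- constraints
  enz <- as.list(catalog[catalog$name == candidate$enzyme, ])
  L <- nchar(enz$recognition)
  snp_idx <- flank$snp_offset + 1L
  m_start <- snp_idx + candidate$match_offset
  m_end <- m_start + L - 1L
  cut_off <- cut_offset_for_strand(enz, candidate$strand)
  seq <- flank$reference_flank
  conserved <- flank_conserved(flank)

  fwd <- enumerate_primers(seq, conserved, "F", m_start, m_end, cns)
  rev <- enumerate_primers(seq, conserved, "R", m_start, m_end, cns)
  tally <- attr(fwd, "tally") + attr(rev, "tally")
  tally <- c(tally, amplicon = 0L, dtm = 0L, fragment = 0L)
  empty <- data.frame()
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    attr(empty, "failure_tally") <- tally
    return(empty)
  }
  rev <- rev[order(rev$end), , drop = FALSE]
  lo <- findInterval(fwd$start + cns$amp_min - 1L - 0.5, rev$end) + 1L
  hi <- findInterval(fwd$start + cns$amp_max - 1L + 0.5, rev$end)
  n_per <- pmax(0L, hi - lo + 1L)
  if (sum(n_per) == 0L) {
    tally["amplicon"] <- nrow(fwd) * nrow(rev)
    attr(empty, "failure_tally") <- tally
    return(empty)
  }
  fi <- rep.int(seq_len(nrow(fwd)), n_per)
  ri <- unlist(mapply(function(a, b) if (b >= a) a:b else integer(0),
                      lo, hi, SIMPLIFY = FALSE), use.names = FALSE)
  amp_len <- rev$end[ri] - fwd$start[fi] + 1L
  dtm <- abs(fwd$tm[fi] - rev$tm[ri])
  frag_up <- (m_start - fwd$start[fi]) + cut_off
  frag_down <- amp_len - frag_up
  ok_dtm <- dtm <= cns$dtm_max
  ok_frag <- frag_up >= cns$frag_min & frag_down >= cns$frag_min &
    frag_up <= amp_len - 1L & frag_down <= amp_len - 1L
  tally["dtm"] <- sum(!ok_dtm)
  tally["fragment"] <- sum(ok_dtm & !ok_frag)
  keep <- ok_dtm & ok_frag
  if (!any(keep)) {
    attr(empty, "failure_tally") <- tally
    return(empty)
  }
  fi <- fi[keep]; ri <- ri[keep]
  amp_len <- amp_len[keep]; dtm <- dtm[keep]
  frag_up <- frag_up[keep]; frag_down <- frag_down[keep]
  score <- abs(fwd$tm[fi] - cns$tm_target) + abs(rev$tm[ri] - cns$tm_target) +
    dtm + cns$amp_weight * abs(amp_len - cns$amp_target)
  ord <- order(score, fwd$start[fi], rev$end[ri])
  ord <- ord[seq_len(min(length(ord), max_pairs))]
  fi <- fi[ord]; ri <- ri[ord]
  out <- data.frame(
    snp_id = candidate$snp_id, enzyme = candidate$enzyme,
    digest_allele = candidate$digest_allele, strand = candidate$strand,
    forward = vapply(seq_along(fi), function(k) substr(seq, fwd$start[fi[k]], fwd$end[fi[k]]), character(1)),
    reverse = vapply(seq_along(ri), function(k) revcomp(substr(seq, rev$start[ri[k]], rev$end[ri[k]])), character(1)),
    f_start = fwd$start[fi], f_end = fwd$end[fi],
    r_start = rev$start[ri], r_end = rev$end[ri],
    tm_forward = fwd$tm[fi], tm_reverse = rev$tm[ri],
    gc_forward = fwd$gc[fi], gc_reverse = rev$gc[ri],
    amplicon_length = amp_len[ord], cut_position = frag_up[ord],
    fragment_up = frag_up[ord], fragment_down = frag_down[ord],
    score = score[ord], stringsAsFactors = FALSE)
  attr(out, "failure_tally") <- tally
  out
}

#' Check an amplicon for non-target digestion sites
#'
#' Fails when the marker's enzyme has a constitutive recognition match
#' (present for both SNP alleles) inside the amplicon other than the
#' allele-specific one: such a site would be digested in every genotype and
#' corrupt the band pattern.
#'
#' @param marker one row from [design_primers()].
#' @param flank the `flank_set` the marker was designed from.
#' @param catalog enzyme catalog.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
nontarget_site_check <- function(marker, flank, catalog) {
  enz <- as.list(catalog[catalog$name == marker$enzyme, ])
  L <- nchar(enz$recognition)
  m <- constitutive_matches(flank, enz, marker$f_start, marker$r_end)
  nrow(m[m$pos + L - 1L >= marker$f_start & m$pos <= marker$r_end, , drop = FALSE]) == 0L
}

#' Predict the digest band pattern for a genotype
#'
#' Homozygotes for the digest allele are fully cut (two fragments); the
#' other homozygote is uncut (one band at the amplicon size); heterozygotes
#' show all three bands.
#'
#' @param marker a marker spec (row from [design_primers()] or the packaged
#'   panel) with `amplicon_length`, `fragment_up`, `fragment_down`.
#' @param genotype one of `"digest-hom"`, `"other-hom"`, `"het"`,
#'   `"missing"`.
#' @return Numeric vector of band sizes (sorted decreasing); empty with
#'   attribute `missing = TRUE` for a missing genotype.
#' @export
predict_digest <- function(marker, genotype) {
  genotype <- match.arg(genotype, c("digest-hom", "other-hom", "het", "missing"))
  up <- marker$fragment_up; down <- marker$fragment_down
  amp <- marker$amplicon_length
  bands <- switch(genotype,
                  "digest-hom" = c(up, down),
                  "other-hom" = amp,
                  "het" = c(amp, up, down),
                  "missing" = numeric(0))
  bands <- sort(bands, decreasing = TRUE)
  if (genotype == "missing") attr(bands, "missing") <- TRUE
  bands
}
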
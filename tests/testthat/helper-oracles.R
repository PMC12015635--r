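# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the HWE oracle enumerates configurations with
# log-factorial multinomial weights (the implementation uses a ratio
# recurrence), and the alignment oracle slides over every offset with no
# seeding (the implementation seeds with exact k-mers).

# exact conditional heterozygote distribution by direct enumeration
oracle_hwe <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  nm <- min(2 * n_ref_hom + n_het, 2 * n_alt_hom + n_het)
  hets <- seq.int(nm %% 2L, min(nm, 2L * n - nm), by = 2L)
  logw <- vapply(hets, function(h) {
    na <- (nm - h) / 2
    nb <- n - h - na
    lfactorial(n) - lfactorial(na) - lfactorial(h) - lfactorial(nb) + h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  p_obs <- probs[hets == n_het]
  list(p_hwe = min(1, sum(probs[probs <= p_obs * (1 + 1e-9)])),
       p_deficit = min(1, sum(probs[hets <= n_het])),
       p_excess = min(1, sum(probs[hets >= n_het])),
       probs = probs, hets = hets)
}

# brute-force duplicate search: global-local alignment of the query at every
# window offset of every contig/strand, no seeding
oracle_scan <- function(query, genome, identity_min = 0.9) {
  scoring <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                      baseOnly = TRUE)
  qlen <- nchar(query)
  hits <- NULL
  for (ctg in names(genome)) {
    seqc <- genome[[ctg]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else capsforge::revcomp(query)
      step <- max(1L, qlen %/% 4L)
      for (off in seq(1L, max(1L, nchar(seqc) - qlen + 1L), by = step)) {
        lo <- max(1L, off - 12L)
        hi <- min(nchar(seqc), off + qlen - 1L + 12L)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(substr(seqc, lo, hi)),
          type = "global-local", substitutionMatrix = scoring,
          gapOpening = 2.5, gapExtension = 0.5)
        alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
        ident <- Biostrings::nmatch(aln) / alen
        if (ident >= identity_min) {
          hits <- rbind(hits, data.frame(
            contig = ctg, start = lo + BiocGenerics::start(aln@subject@range) - 1L,
            identity = ident, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(hits)) return(hits)
  # collapse hits reported from overlapping offsets
  hits <- hits[order(hits$contig, hits$start, -hits$identity), ]
  keep <- rep(TRUE, nrow(hits))
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (hits$contig[i] == hits$contig[prev] &&
          abs(hits$start[i] - hits$start[prev]) < qlen %/% 2L) keep[i] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

# exhaustive maximum independent set over a conflict graph given as a
# logical adjacency matrix (n <= 12)
oracle_max_independent_set <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      pr <- utils::combn(sel, 2)
      ok <- !any(adj[cbind(pr[1, ], pr[2, ])])
    }
    if (ok) best <- length(sel)
  }
  best
}

# minimal genotype matrix from a dosage matrix
tiny_gm <- function(dosage, contig = "c1", pos = NULL, ref = "A", alt = "G",
                    depth = NULL) {
  m <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  sites <- data.frame(contig = rep(contig, m), pos = pos,
                      ref = rep(ref, length.out = m),
                      alt = rep(alt, length.out = m),
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, dosage, paste0("S", seq_len(ncol(dosage))), depth)
}

# dosage matrix with given per-site genotype counts, in column order
counts_to_dosage <- function(n_ref_hom, n_het, n_alt_hom, n_missing = 0) {
  matrix(c(rep(2L, n_ref_hom), rep(1L, n_het), rep(0L, n_alt_hom),
           rep(NA_integer_, n_missing)), nrow = 1)
}
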
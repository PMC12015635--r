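#' Filtering thresholds for the candidate-SNP cascade
#'
#' Defaults reproduce the cascade the pipeline was built around: at least
#' 15 of 22 samples genotyped, MAF at least 0.20, removal of sites leaning
#' toward heterozygote excess (`p_excess < 0.5`), full retention at 17+
#' typed samples, a deficit-leaning requirement below that, and a read-depth
#' rule (11 samples at depth >= 2) for sites at the missingness floor.
#'
#' @param min_typed minimum number of genotyped samples per site.
#' @param maf_min minimum minor allele frequency.
#' @param excess_keep_threshold retain sites with `p_excess >=` this value.
#' @param tier_full typed-sample count granting unconditional retention.
#' @param depth_min minimum read depth for the tier-C depth rule.
#' @param depth_n_min minimum number of samples at `depth_min` for tier C.
#' @param max_nonref_af maximum alternate-allele frequency (drops fixed
#'   sites).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_typed = 15L, maf_min = 0.20,
                          excess_keep_threshold = 0.5, tier_full = 17L,
                          depth_min = 2, depth_n_min = 11L,
                          max_nonref_af = 0.999) {
  stopifnot(min_typed >= 1, maf_min >= 0, maf_min <= 0.5,
            excess_keep_threshold >= 0, excess_keep_threshold <= 1,
            tier_full >= min_typed, depth_min >= 0, depth_n_min >= 0,
            max_nonref_af > 0, max_nonref_af <= 1)
  structure(list(min_typed = as.integer(min_typed), maf_min = maf_min,
                 excess_keep_threshold = excess_keep_threshold,
                 tier_full = as.integer(tier_full), depth_min = depth_min,
                 depth_n_min = as.integer(depth_n_min),
                 max_nonref_af = max_nonref_af),
            class = "filter_params")
}

#' Per-site genotype counts and minor allele frequency
#'
#' MAF is computed over typed samples only: `min(ref count, alt count) /
#' (2 * n_typed)`. At a 50:50 tie the alternate allele is reported as minor.
#'
#' @param gm a `genotype_matrix`.
#' @return data.frame with `snp_id`, `n_typed`, `n_ref_hom`, `n_het`,
#'   `n_alt_hom`, `maf`, `minor_allele` (one row per site; `maf` is `NA`
#'   when no sample is typed).
#' @export
site_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  n_typed <- rowSums(!is.na(d))
  n_ref_hom <- rowSums(d == 2L, na.rm = TRUE)
  n_het <- rowSums(d == 1L, na.rm = TRUE)
  n_alt_hom <- rowSums(d == 0L, na.rm = TRUE)
  ref_count <- 2L * n_ref_hom + n_het
  alt_count <- 2L * n_alt_hom + n_het
  maf <- ifelse(n_typed > 0, pmin(ref_count, alt_count) / (2 * n_typed), NA_real_)
  alt1 <- sub(",.*", "", gm$sites$alt)
  minor <- ifelse(alt_count <= ref_count, alt1, gm$sites$ref)
  data.frame(snp_id = gm$sites$snp_id, n_typed = n_typed,
             n_ref_hom = n_ref_hom, n_het = n_het, n_alt_hom = n_alt_hom,
             maf = maf, minor_allele = minor,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Basic site filter: SNP, biallelic, not fixed, missingness, MAF
#'
#' Retains biallelic SNPs that are not fixed for the alternate allele, are
#' typed in at least `min_typed` samples, and have MAF at least `maf_min`.
#' Each rejected site carries its first failing reason (checked in the
#' order indel, multiallelic, fixed, missingness, maf).
#'
#' @param gm a `genotype_matrix`.
#' @param params a [filter_params()].
#' @return `list(matrix = <filtered genotype_matrix>, decisions =
#'   <data.frame with snp_id, pass, reason>)`.
#' @export
basic_filter <- function(gm, params = filter_params()) {
  st <- site_stats(gm)
  alts <- strsplit(gm$sites$alt, ",", fixed = TRUE)
  is_multi <- lengths(alts) > 1L
  is_indel <- nchar(gm$sites$ref) != 1L |
    vapply(alts, function(a) any(nchar(a) != 1L), logical(1))
  is_snp <- !is_indel & gm$sites$ref %in% c("A", "C", "G", "T") &
    vapply(alts, function(a) all(a %in% c("A", "C", "G", "T")), logical(1))
  alt_af <- ifelse(st$n_typed > 0,
                   (2 * st$n_alt_hom + st$n_het) / (2 * st$n_typed), NA_real_)
  reason <- rep(NA_character_, n_sites(gm))
  reason[is.na(reason) & (is_indel | !is_snp)] <- "indel"
  reason[is.na(reason) & is_multi] <- "multiallelic"
  reason[is.na(reason) & !is.na(alt_af) & alt_af > params$max_nonref_af] <- "fixed"
  reason[is.na(reason) & st$n_typed < params$min_typed] <- "missingness"
  reason[is.na(reason) & !is.na(st$maf) & st$maf < params$maf_min] <- "maf"
  reason[is.na(reason) & st$n_typed == 0] <- "missingness"
  pass <- is.na(reason)
  list(matrix = subset_sites(gm, pass),
       decisions = data.frame(snp_id = gm$sites$snp_id, pass = pass,
                              reason = ifelse(pass, "pass", reason),
                              stringsAsFactors = FALSE))
}

# Conditional distribution of the heterozygote count given sample size and
# minor-allele count, by the stable ratio recurrence; returns probabilities
# indexed by het counts sharing the parity of n_minor.
hwe_het_distribution <- function(n, n_minor) {
  if (n_minor == 0L) return(stats::setNames(1, "0"))
  hets <- seq.int(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  probs <- numeric(length(hets))
  # start from the largest heterozygote count and recurse downward:
  # P(h-2)/P(h) = h*(h-1) / (4 * (hom_minor+1) * (hom_major+1))
  i0 <- length(hets)
  probs[i0] <- 1
  for (i in rev(seq_len(i0 - 1L))) {
    h <- hets[i + 1L]
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * (hom_minor + 1) * (hom_major + 1))
  }
  probs <- probs / sum(probs)
  stats::setNames(probs, hets)
}

#' Exact test of Hardy-Weinberg proportions with one-tailed variants
#'
#' Conditional on the observed allele counts, the heterozygote count has a
#' known exact distribution under Hardy-Weinberg proportions. `p_hwe` is the
#' two-sided p-value summing all configurations no more probable than the
#' observed one; `p_deficit` is `P(het <= observed)` (heterozygote-deficit
#' tail) and `p_excess` is `P(het >= observed)` (heterozygote-excess tail).
#' A monomorphic site has a single configuration and all three p-values 1.
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype counts (non-negative).
#' @return `list(p_hwe, p_deficit, p_excess)`.
#' @export
#' @examples
#' hwe_exact(1, 1, 3)
hwe_exact <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("hwe_exact: genotype counts must be non-negative")
  }
  n <- n_ref_hom + n_het + n_alt_hom
  if (n < 1) stop("hwe_exact: at least one typed sample required")
  n_minor <- min(2 * n_ref_hom + n_het, 2 * n_alt_hom + n_het)
  dist <- hwe_het_distribution(n, n_minor)
  hets <- as.integer(names(dist))
  p_obs <- dist[[as.character(n_het)]]
  eps <- p_obs * 1e-12
  list(p_hwe = min(1, sum(dist[dist <= p_obs + eps])),
       p_deficit = min(1, sum(dist[hets <= n_het])),
       p_excess = min(1, sum(dist[hets >= n_het])))
}

#' Exact HWE tests for every site of a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @return data.frame with `snp_id`, `p_hwe`, `p_deficit`, `p_excess`.
#' @export
hwe_test <- function(gm) {
  st <- site_stats(gm)
  res <- t(vapply(seq_len(nrow(st)), function(i) {
    if (st$n_typed[i] == 0L) return(c(NA_real_, NA_real_, NA_real_))
    unlist(hwe_exact(st$n_ref_hom[i], st$n_het[i], st$n_alt_hom[i]))
  }, numeric(3)))
  data.frame(snp_id = st$snp_id, p_hwe = res[, 1], p_deficit = res[, 2],
             p_excess = res[, 3], stringsAsFactors = FALSE)
}

#' Heterozygote-excess screen
#'
#' Removes sites leaning toward heterozygote excess — the signature of
#' pseudo-SNPs from co-mapping duplicated regions. A site is retained iff
#' `p_excess >= excess_keep_threshold` (boundary inclusive).
#'
#' @param hwe data.frame from [hwe_test()].
#' @param params a [filter_params()].
#' @return Logical vector of retention decisions, one per row of `hwe`.
#' @export
excess_screen <- function(hwe, params = filter_params()) {
  !is.na(hwe$p_excess) & hwe$p_excess >= params$excess_keep_threshold
}

#' Tiered retention by genotyping quality
#'
#' Tier A (`n_typed >= tier_full`): retained unconditionally. Tier B
#' (`min_typed < n_typed < tier_full`): retained iff the site leans toward
#' heterozygote deficit (`p_deficit < p_excess`). Tier C (`n_typed ==
#' min_typed`): additionally requires at least `depth_n_min` samples called
#' at depth `>= depth_min`; a tier-C site without depth data is rejected.
#'
#' @param gm a `genotype_matrix` (depth needed for tier C).
#' @param hwe data.frame from [hwe_test()] aligned with `gm` sites.
#' @param params a [filter_params()].
#' @return data.frame with `snp_id`, `tier` (`"A"`, `"B"`, `"C"` or `NA`),
#'   `keep`, `reason`.
#' @export
tier_filter <- function(gm, hwe, params = filter_params()) {
  st <- site_stats(gm)
  stopifnot(identical(st$snp_id, hwe$snp_id))
  n <- nrow(st)
  tier <- rep(NA_character_, n)
  keep <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  deficit_leaning <- hwe$p_deficit < hwe$p_excess
  for (i in seq_len(n)) {
    if (st$n_typed[i] >= params$tier_full) {
      tier[i] <- "A"; keep[i] <- TRUE; reason[i] <- "pass"
    } else if (st$n_typed[i] > params$min_typed) {
      tier[i] <- "B"
      keep[i] <- isTRUE(deficit_leaning[i])
      reason[i] <- if (keep[i]) "pass" else "excess_leaning"
    } else if (st$n_typed[i] == params$min_typed) {
      tier[i] <- "C"
      if (!isTRUE(deficit_leaning[i])) {
        reason[i] <- "excess_leaning"
      } else if (is.null(gm$depth)) {
        reason[i] <- "no_depth_data"
      } else {
        dp <- gm$depth[i, ]
        ok <- sum(!is.na(gm$dosage[i, ]) & !is.na(dp) & dp >= params$depth_min)
        if (ok >= params$depth_n_min) {
          keep[i] <- TRUE; reason[i] <- "pass"
        } else {
          reason[i] <- "low_depth"
        }
      }
    } else {
      reason[i] <- "missingness"
    }
  }
  data.frame(snp_id = st$snp_id, tier = tier, keep = keep, reason = reason,
             stringsAsFactors = FALSE)
}

#' Multilocus inbreeding coefficient estimate
#'
#' \eqn{\hat F = 1 - \sum_s H_s^{obs} / \sum_s 2\hat p_s \hat q_s n_s},
#' pooling observed and Hardy-Weinberg-expected heterozygote counts over
#' sites (allele frequencies estimated from typed samples per site).
#'
#' @param gm a `genotype_matrix`.
#' @return Scalar estimate of F.
#' @export
inbreeding_estimate <- function(gm) {
  st <- site_stats(gm)
  poly <- st$n_typed > 0 & st$maf > 0
  if (!any(poly, na.rm = TRUE)) stop("inbreeding_estimate: no polymorphic site")
  st <- st[which(poly), , drop = FALSE]
  p <- (2 * st$n_ref_hom + st$n_het) / (2 * st$n_typed)
  expected <- 2 * p * (1 - p) * st$n_typed
  1 - sum(st$n_het) / sum(expected)
}
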
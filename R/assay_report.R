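#' Packaged A. lyrata marker panel
#'
#' The 17 validated PCR-RFLP marker specifications for the Rondeau
#' (Ontario) *Arabidopsis lyrata* ssp. *lyrata* population that this
#' pipeline was built to reproduce: locus, SNP ID, primer sequences,
#' annealing temperature (from gradient PCR, annotation only), amplicon
#' size, enzyme, digest allele and up-/downstream digest fragment sizes.
#' The locus-3 row is internally inconsistent (fragments 187 + 718 do not
#' sum to the printed amplicon size 701); it is shipped as published and
#' flagged by `fragments_consistent`.
#'
#' @return data.frame with one row per locus.
#' @export
caps_marker_panel <- function() {
  path <- system.file("extdata", "alyrata_marker_panel.tsv", package = "capsforge")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$fragments_consistent <- df$fragment_up + df$fragment_down == df$amplicon_length
  df
}

#' Packaged A. lyrata per-locus minor allele frequencies
#'
#' Minor allele frequencies, reference-allele and minor-allele identities
#' for the 17 packaged marker loci, scored on 20 plants from the Rondeau
#' population.
#'
#' @return data.frame with columns `locus`, `maf`, `ref_allele`,
#'   `minor_allele`.
#' @export
caps_maf_panel <- function() {
  path <- system.file("extdata", "alyrata_maf_panel.tsv", package = "capsforge")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Score a band pattern back to a genotype
#'
#' Matches the observed band multiset to the three predicted patterns
#' within a per-band size tolerance: the two digest fragments mean a
#' digest-allele homozygote, the single amplicon band the other homozygote,
#' and all three bands a heterozygote. Anything else (including no bands)
#' is `"unreadable"` — a value, not an error, mirroring how an ambiguous
#' gel lane is scored.
#'
#' @param bands numeric vector of observed band sizes (bp).
#' @param marker a marker spec row.
#' @param tolerance per-band size tolerance; the default of 5 percent of
#'   each predicted fragment is a gel-resolution proxy. Pass `0` for exact
#'   in-silico matching.
#' @return One of `"digest-hom"`, `"other-hom"`, `"het"`, `"unreadable"`.
#' @export
genotype_from_bands <- function(bands, marker, tolerance = 0.05) {
  bands <- sort(as.numeric(bands), decreasing = TRUE)
  match_pattern <- function(pred) {
    if (length(bands) != length(pred)) return(FALSE)
    pred <- sort(pred, decreasing = TRUE)
    tol <- if (tolerance < 1) pred * tolerance else rep(tolerance, length(pred))
    all(abs(bands - pred) <= tol)
  }
  for (g in c("het", "digest-hom", "other-hom")) {
    if (match_pattern(predict_digest(marker, g))) return(g)
  }
  "unreadable"
}

#' Minor allele frequency from assay genotypes
#'
#' Allele counts use readable genotypes only. A 50:50 tie reports MAF 0.5
#' with both alleles listed.
#'
#' @param genotypes character vector of per-sample calls
#'   (`"digest-hom"`/`"other-hom"`/`"het"`/`"unreadable"`).
#' @param digest_allele,other_allele the two SNP alleles.
#' @return `list(maf, minor_allele, n_readable)`.
#' @export
maf_from_genotypes <- function(genotypes, digest_allele, other_allele) {
  readable <- genotypes[genotypes %in% c("digest-hom", "other-hom", "het")]
  if (length(readable) == 0L) stop("maf_from_genotypes: no readable genotype")
  n_dig <- 2L * sum(readable == "digest-hom") + sum(readable == "het")
  n_oth <- 2L * sum(readable == "other-hom") + sum(readable == "het")
  total <- n_dig + n_oth
  if (n_dig < n_oth) {
    list(maf = n_dig / total, minor_allele = digest_allele,
         n_readable = length(readable))
  } else if (n_oth < n_dig) {
    list(maf = n_oth / total, minor_allele = other_allele,
         n_readable = length(readable))
  } else {
    list(maf = 0.5,
         minor_allele = paste(sort(c(digest_allele, other_allele)), collapse = "/"),
         n_readable = length(readable))
  }
}

#' Aggregate marker-panel MAF summary
#'
#' @param mafs numeric vector of per-locus minor allele frequencies.
#' @param threshold MAF threshold for the count (default 0.30).
#' @return `list(n_loci, mean_maf, sd_maf, min_maf, n_at_threshold,
#'   sd_defined)`; with a single locus the SD is reported as 0 with
#'   `sd_defined = FALSE`.
#' @export
summarize_markers <- function(mafs, threshold = 0.30) {
  if (length(mafs) == 0L) stop("summarize_markers: no loci")
  sd_defined <- length(mafs) > 1L
  list(n_loci = length(mafs),
       mean_maf = mean(mafs),
       sd_maf = if (sd_defined) stats::sd(mafs) else 0,
       min_maf = min(mafs),
       n_at_threshold = sum(mafs >= threshold),
       sd_defined = sd_defined)
}

#' Run the complete marker-development pipeline
#'
#' Stage order: basic variant filters, heterozygote-excess screen, tiered
#' retention, flank construction, duplicate screen, allele-specific enzyme
#' selection with the local-uniqueness rule, linkage pruning, primer design
#' with the non-target digest check. Per-stage input/output counts are
#' logged (the funnel), every dropped site carries a reason, and a
#' machine-readable manifest records seeds and thresholds.
#'
#' @param genome named character vector of contigs (or a FASTA path).
#' @param gm a `genotype_matrix` (or a VCF path).
#' @param catalog an `enzyme_catalog`.
#' @param params a [filter_params()].
#' @param constraints a [primer_constraints()].
#' @param flank_radius flank radius in bp.
#' @param extra_genomes optional named list of additional genomes for the
#'   duplicate screen (the marker's own reference is always included).
#' @param identity_min duplicate-screen identity threshold.
#' @param r2_max,ld_window linkage-pruning parameters.
#' @param enzyme_rank optional enzyme-accessibility ranking for pruning
#'   tie-breaks (named by enzyme).
#' @return `list(report, funnel, dropped, manifest)`.
#' @export
run_pipeline <- function(genome, gm, catalog = load_enzyme_catalog(),
                         params = filter_params(),
                         constraints = primer_constraints(),
                         flank_radius = 1000L, extra_genomes = list(),
                         identity_min = 0.90, r2_max = 0.2,
                         ld_window = 1e6, enzyme_rank = NULL) {
  if (is.character(genome) && length(genome) == 1L) genome <- read_fasta(genome)
  if (is.character(gm) && length(gm) == 1L) gm <- read_vcf(gm, genome)
  stopifnot(inherits(gm, "genotype_matrix"))
  funnel <- NULL
  dropped <- NULL
  log_stage <- function(stage, n_in, n_out) {
    funnel <<- rbind(funnel, data.frame(stage = stage, n_in = n_in,
                                        n_out = n_out, stringsAsFactors = FALSE))
  }
  log_drop <- function(ids, stage, reason) {
    if (length(ids)) {
      dropped <<- rbind(dropped, data.frame(snp_id = ids, stage = stage,
                                            reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }

  # 1. basic filters
  bf <- basic_filter(gm, params)
  log_stage("basic_filter", n_sites(gm), n_sites(bf$matrix))
  bad <- bf$decisions[!bf$decisions$pass, ]
  log_drop(bad$snp_id, "basic_filter", bad$reason)
  cur <- bf$matrix

  # 2. heterozygote-excess screen
  hwe <- hwe_test(cur)
  keep <- excess_screen(hwe, params)
  log_stage("excess_screen", n_sites(cur), sum(keep))
  log_drop(cur$sites$snp_id[!keep], "excess_screen", "excess_leaning")
  cur <- subset_sites(cur, keep)
  hwe <- hwe[keep, , drop = FALSE]

  # 3. tiered retention
  tiers <- tier_filter(cur, hwe, params)
  log_stage("tier_filter", n_sites(cur), sum(tiers$keep))
  log_drop(tiers$snp_id[!tiers$keep], "tier_filter", tiers$reason[!tiers$keep])
  cur <- subset_sites(cur, tiers$keep)
  tier_label <- stats::setNames(tiers$tier[tiers$keep], tiers$snp_id[tiers$keep])

  # 4. flanks + duplicate screen
  genomes <- c(list(reference = genome), extra_genomes)
  flanks <- list()
  dup_pass <- logical(n_sites(cur))
  for (i in seq_len(n_sites(cur))) {
    fl <- extract_flanks(genome, gm, match(cur$sites$snp_id[i], gm$sites$snp_id),
                         radius = flank_radius)
    flanks[[cur$sites$snp_id[i]]] <- fl
    hits <- duplicate_scan(fl, genomes, identity_min = identity_min)
    verdict <- duplicate_verdict(hits)
    dup_pass[i] <- verdict$pass
    if (!verdict$pass) log_drop(cur$sites$snp_id[i], "duplicate_screen", verdict$reason)
  }
  log_stage("duplicate_screen", n_sites(cur), sum(dup_pass))
  cur <- subset_sites(cur, dup_pass)

  # 5. allele-specific restriction sites + local uniqueness
  candidates <- list()
  has_enzyme <- logical(n_sites(cur))
  for (i in seq_len(n_sites(cur))) {
    id <- cur$sites$snp_id[i]
    fl <- flanks[[id]]
    cands <- allele_specific_sites(fl, catalog)
    if (nrow(cands) > 0L) {
      ok <- vapply(seq_len(nrow(cands)), function(j) {
        uniqueness_check(fl, cands[j, ], catalog)
      }, logical(1))
      cands <- cands[ok, , drop = FALSE]
    }
    if (nrow(cands) == 0L) {
      log_drop(id, "enzyme_selection", "no unique allele-specific site")
    } else {
      candidates[[id]] <- cands
      has_enzyme[i] <- TRUE
    }
  }
  log_stage("enzyme_selection", n_sites(cur), sum(has_enzyme))
  cur <- subset_sites(cur, has_enzyme)

  # 6. linkage pruning
  pr <- prune_linked(cur$sites[c("snp_id", "contig", "pos")], cur$dosage,
                     r2_max = r2_max, window = ld_window,
                     enzyme_rank = enzyme_rank)
  log_stage("linkage_pruning", n_sites(cur), length(pr$kept))
  if (!is.null(pr$dropped)) {
    log_drop(pr$dropped$snp_id, "linkage_pruning",
             paste0("linked to ", pr$dropped$linked_to,
                    " (r2=", round(pr$dropped$r_squared, 3), ", ",
                    pr$dropped$rule, ")"))
  }
  cur <- subset_sites(cur, cur$sites$snp_id %in% pr$kept)

  # 7. primer design + non-target digest check
  st <- site_stats(cur)
  report <- NULL
  designed <- logical(n_sites(cur))
  for (i in seq_len(n_sites(cur))) {
    id <- cur$sites$snp_id[i]
    fl <- flanks[[id]]
    best <- NULL
    for (j in seq_len(nrow(candidates[[id]]))) {
      specs <- design_primers(fl, candidates[[id]][j, ], catalog, constraints)
      if (nrow(specs) == 0L) next
      for (k in seq_len(nrow(specs))) {
        if (nontarget_site_check(specs[k, ], fl, catalog)) {
          best <- specs[k, ]
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) {
      log_drop(id, "primer_design", "no feasible primer pair")
    } else {
      best$tier <- unname(tier_label[id])
      best$n_typed <- st$n_typed[i]
      best$maf <- st$maf[i]
      best$contig <- cur$sites$contig[i]
      best$pos <- cur$sites$pos[i]
      report <- rbind(report, best)
      designed[i] <- TRUE
    }
  }
  log_stage("primer_design", n_sites(cur), sum(designed))
  if (is.null(report)) {
    report <- data.frame()
  } else {
    report <- report[order(report$contig, report$pos), , drop = FALSE]
    report$locus <- seq_len(nrow(report))
    rownames(report) <- NULL
  }
  manifest <- list(package = "capsforge",
                   version = as.character(utils::packageVersion("capsforge")),
                   n_samples = length(gm$samples),
                   params = unclass(params),
                   constraints = unclass(constraints),
                   flank_radius = flank_radius,
                   identity_min = identity_min,
                   r2_max = r2_max, ld_window = ld_window)
  list(report = report, funnel = funnel, dropped = dropped,
       manifest = manifest)
}
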
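# Evaluate expr under a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study population.
#' Defaults describe the mating-system conditions the pipeline's filters
#' assume: a 22-plant diploid sample from a predominantly selfing population
#' with inbreeding coefficient F = 0.41, sequenced to a mean depth of 3.5x
#' (so that roughly 3% of calls are missing), with a background of
#' sub-threshold rare variants alongside the planted marker sites.
#'
#' @param n_contigs number of contigs in the reference.
#' @param contig_length length of each contig in bp.
#' @param gc_content GC fraction of the simulated reference, in `[0,1]`.
#' @param n_samples number of diploid individuals.
#' @param inbreeding_f inbreeding coefficient F in `[0,1]` used for genotype
#'   draws (genotype frequencies `p^2+Fpq`, `2pq(1-F)`, `q^2+Fpq`).
#' @param n_sites number of background (non-planted) SNP sites.
#' @param maf_low,maf_high bounds of the uniform alternate-allele-frequency
#'   spectrum for background sites.
#' @param mean_depth mean per-call read depth (Poisson model; depth 0 means a
#'   missing genotype).
#' @param flank_radius flank radius in bp used downstream; contigs must hold
#'   a full flank around any planted site.
#' @param seed integer master seed; identical config implies byte-identical
#'   simulation output.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 7L, contig_length = 12000L,
                       gc_content = 0.5, n_samples = 22L,
                       inbreeding_f = 0.41, n_sites = 40L,
                       maf_low = 0.02, maf_high = 0.12,
                       mean_depth = 3.5, flank_radius = 1000L,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1L || is.na(x) || x < min) {
      stop("sim_config: invalid '", nm, "' (need a count >= ", min, ")")
    }
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("sim_config: invalid '", nm, "' (need a fraction in [0,1])")
    }
  }
  chk_count(n_contigs, "n_contigs"); chk_count(contig_length, "contig_length")
  chk_count(n_samples, "n_samples"); chk_count(n_sites, "n_sites", min = 0)
  chk_frac(gc_content, "gc_content"); chk_frac(inbreeding_f, "inbreeding_f")
  chk_frac(maf_low, "maf_low"); chk_frac(maf_high, "maf_high")
  if (maf_low > maf_high) stop("sim_config: invalid 'maf_low' (exceeds maf_high)")
  if (mean_depth <= 0) stop("sim_config: invalid 'mean_depth' (must be > 0)")
  if (contig_length < 2 * flank_radius + 1) {
    stop("sim_config: invalid 'contig_length' (must be >= 2*flank_radius + 1)")
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 gc_content = gc_content, n_samples = as.integer(n_samples),
                 inbreeding_f = inbreeding_f, n_sites = as.integer(n_sites),
                 maf_low = maf_low, maf_high = maf_high,
                 mean_depth = mean_depth,
                 flank_radius = as.integer(flank_radius),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Generate a random reference genome
#'
#' I.i.d. bases at the configured GC fraction; no repeat structure beyond
#' what [plant_duplicate()] adds explicitly, so duplicate screening is a
#' controlled experiment rather than an incidental one.
#'
#' @param config a [sim_config()].
#' @return Named character vector of contig sequences (`contig_1`, ...).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genome <- vapply(seq_len(config$n_contigs), function(i) {
      paste(random_bases(config$contig_length, config$gc_content), collapse = "")
    }, character(1))
    names(genome) <- paste0("contig_", seq_len(config$n_contigs))
    genome
  })
}

# All recognition-site matches of `enzyme` in `seq` that overlap the 1-based
# index `idx` (both strands), as start positions.
matches_overlapping <- function(seq, enzyme, idx) {
  L <- nchar(enzyme$recognition)
  pos <- match_recognition(seq, enzyme, both_strands = TRUE)$pos
  pos[pos <= idx & idx <= pos + L - 1L]
}

#' Plant an allele-specific restriction site into a genome
#'
#' Writes a concrete instance of the enzyme's recognition sequence into the
#' genome so that the `cut_allele` version of the SNP completes the site and
#' the `uncut_allele` version destroys it, and clears any other recognition
#' site of the same enzyme within `clear_radius` bp of the SNP (so the
#' planted marker can pass the downstream uniqueness rule).
#'
#' @param genome named character vector of contigs.
#' @param contig contig name.
#' @param pos 1-based SNP position.
#' @param enzyme one row of an enzyme catalog (see [load_enzyme_catalog()]).
#' @param cut_allele base completing the recognition site.
#' @param uncut_allele base destroying it.
#' @param snp_offset 0-based offset of the SNP inside the recognition
#'   sequence; chosen automatically when `NULL`.
#' @param clear_radius radius (bp) within which accidental same-enzyme sites
#'   are scrubbed (default 150, the uniqueness-rule radius).
#' @param seed RNG seed for concrete-base choices at degenerate pattern
#'   positions and for scrub substitutions.
#' @return `list(genome = <edited genome>, truth = <one-row data.frame>)`.
#' @export
plant_caps_site <- function(genome, contig, pos, enzyme, cut_allele,
                            uncut_allele, snp_offset = NULL,
                            clear_radius = 150L, seed = 1L) {
  stopifnot(contig %in% names(genome))
  pat <- strsplit(toupper(enzyme$recognition), "", fixed = TRUE)[[1]]
  L <- length(pat)
  ok_off <- which(vapply(pat, function(ch) {
    cut_allele %in% IUPAC_SETS[[ch]] && !uncut_allele %in% IUPAC_SETS[[ch]]
  }, logical(1))) - 1L
  if (length(ok_off) == 0L) {
    stop("plant_caps_site: no position of ", enzyme$name,
         " site '", enzyme$recognition, "' is broken by ",
         cut_allele, "->", uncut_allele)
  }
  if (is.null(snp_offset)) snp_offset <- ok_off[1] else if (!snp_offset %in% ok_off) {
    stop("plant_caps_site: substitution does not break the site at offset ", snp_offset)
  }
  site_start <- pos - snp_offset
  if (site_start < 1L || site_start + L - 1L > nchar(genome[[contig]])) {
    stop("plant_caps_site: recognition site would fall outside contig")
  }
  with_seed(seed, {
    concrete <- vapply(pat, function(ch) {
      s <- IUPAC_SETS[[ch]]
      if (length(s) == 1L) s else sample(s, 1L)
    }, character(1))
    concrete[snp_offset + 1L] <- cut_allele
    seqc <- genome[[contig]]
    substr(seqc, site_start, site_start + L - 1L) <- paste(concrete, collapse = "")

    # scrub: within the clear radius, the cut-allele sequence must match the
    # site exactly once (at the planted span) and the uncut-allele sequence
    # never; no constitutive second site either.
    win_lo <- max(1L, pos - clear_radius - L + 1L)
    win_hi <- min(nchar(seqc), pos + clear_radius + L - 1L)
    planted_span <- c(site_start, site_start + L - 1L)
    for (iter in 1:200) {
      win_cut <- substr(seqc, win_lo, win_hi)
      win_uncut <- win_cut
      substr(win_uncut, pos - win_lo + 1L, pos - win_lo + 1L) <- uncut_allele
      hits_cut <- match_recognition(win_cut, enzyme, both_strands = TRUE)$pos + win_lo - 1L
      hits_uncut <- match_recognition(win_uncut, enzyme, both_strands = TRUE)$pos + win_lo - 1L
      offending <- unique(c(setdiff(hits_cut, planted_span[1]), hits_uncut))
      if (length(offending) == 0L) break
      # mutate one base inside the first offending match, outside the planted span
      span <- offending[1]:(offending[1] + L - 1L)
      editable <- setdiff(span, planted_span[1]:planted_span[2])
      editable <- setdiff(editable, pos)
      if (length(editable) == 0L) {
        stop("plant_caps_site: cannot scrub overlapping site at ", offending[1])
      }
      j <- editable[1]
      cur <- substr(seqc, j, j)
      substr(seqc, j, j) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    if (length(offending) != 0L) stop("plant_caps_site: scrub failed to converge")
    genome[[contig]] <- seqc
    truth <- data.frame(contig = contig, pos = pos, ref = cut_allele,
                        alt = uncut_allele, enzyme = enzyme$name,
                        cut_allele = cut_allele,
                        snp_id = snp_id(contig, pos, cut_allele, uncut_allele),
                        stringsAsFactors = FALSE)
    list(genome = genome, truth = truth)
  })
}

#' Plant a near-identical duplicated segment
#'
#' Copies `[start, end]` of `contig` over the destination interval with
#' per-base substitution probability `1 - identity`, creating a decoy for the
#' duplicate screen. Source and destination must not overlap.
#'
#' @param genome named character vector of contigs.
#' @param contig,start,end source interval (1-based, inclusive).
#' @param dest_contig,dest_start destination (segment of equal length is
#'   overwritten).
#' @param identity requested sequence identity in `(0, 1]`.
#' @param seed RNG seed for the substitution mask.
#' @return `list(genome, truth)` where `truth` records the realized identity.
#' @export
plant_duplicate <- function(genome, contig, start, end, dest_contig,
                            dest_start, identity, seed = 1L) {
  stopifnot(contig %in% names(genome), dest_contig %in% names(genome))
  if (identity <= 0 || identity > 1) stop("plant_duplicate: identity must be in (0,1]")
  len <- end - start + 1L
  if (start < 1L || end > nchar(genome[[contig]])) stop("plant_duplicate: source outside contig")
  dest_end <- dest_start + len - 1L
  if (dest_start < 1L || dest_end > nchar(genome[[dest_contig]])) {
    stop("plant_duplicate: destination outside contig")
  }
  if (identical(contig, dest_contig) && start <= dest_end && dest_start <= end) {
    stop("plant_duplicate: source and destination overlap")
  }
  with_seed(seed, {
    src <- strsplit(substr(genome[[contig]], start, end), "", fixed = TRUE)[[1]]
    copy <- src
    mut <- stats::runif(len) > identity
    if (any(mut)) {
      copy[mut] <- vapply(src[mut], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                          character(1))
    }
    realized <- mean(copy == src)
    seqd <- genome[[dest_contig]]
    substr(seqd, dest_start, dest_end) <- paste(copy, collapse = "")
    genome[[dest_contig]] <- seqd
    truth <- data.frame(src_contig = contig, src_start = start, src_end = end,
                        dest_contig = dest_contig, dest_start = dest_start,
                        dest_end = dest_end, requested_identity = identity,
                        realized_identity = realized, stringsAsFactors = FALSE)
    list(genome = genome, truth = truth)
  })
}

#' Simulate genotype dosages under partial selfing
#'
#' Independent sites; at a site with alternate-allele frequency `q`
#' (`p = 1 - q`), genotypes are drawn with frequencies `p^2 + Fpq`
#' (reference homozygote), `2pq(1 - F)` (heterozygote) and `q^2 + Fpq`
#' (alternate homozygote) — the single-locus equilibrium of a mixed-mating
#' population with inbreeding coefficient F.
#'
#' @param true_freqs vector of per-site alternate-allele frequencies in (0,1).
#' @param inbreeding_f inbreeding coefficient F in `[0,1]`.
#' @param n_samples number of diploid individuals.
#' @param seed RNG seed.
#' @return Integer matrix sites x samples of reference-allele dosages
#'   (2 = ref-hom, 1 = het, 0 = alt-hom).
#' @export
simulate_genotypes <- function(true_freqs, inbreeding_f, n_samples, seed = 1L) {
  if (any(true_freqs <= 0 | true_freqs >= 1)) {
    stop("simulate_genotypes: frequencies must lie in (0,1)")
  }
  if (inbreeding_f < 0 || inbreeding_f > 1) stop("simulate_genotypes: F must be in [0,1]")
  with_seed(seed, {
    q <- true_freqs; p <- 1 - q
    p_refhom <- p^2 + inbreeding_f * p * q
    p_het <- 2 * p * q * (1 - inbreeding_f)
    m <- length(q)
    u <- matrix(stats::runif(m * n_samples), nrow = m)
    dosage <- matrix(0L, nrow = m, ncol = n_samples)
    dosage[u < p_refhom + p_het] <- 1L
    dosage[u < p_refhom] <- 2L
    dosage
  })
}

#' Add Poisson read depth and depth-driven missingness
#'
#' Each call receives an independent Poisson depth with the configured mean;
#' a call with depth 0 becomes missing. This is the simplest mechanism that
#' reproduces the missing-genotype load of low-coverage sequencing and feeds
#' the tiered depth filter.
#'
#' @param gm a `genotype_matrix` without depth.
#' @param mean_depth mean reads per call (> 0).
#' @param seed RNG seed.
#' @return The matrix with a `depth` component and `NA` dosage where depth
#'   is 0.
#' @export
simulate_depth_missingness <- function(gm, mean_depth, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (mean_depth <= 0) stop("simulate_depth_missingness: mean_depth must be > 0")
  with_seed(seed, {
    dp <- matrix(stats::rpois(length(gm$dosage), mean_depth), nrow = nrow(gm$dosage))
    dosage <- gm$dosage
    dosage[dp == 0L] <- NA_integer_
    genotype_matrix(gm$sites[setdiff(names(gm$sites), "snp_id")],
                    dosage, gm$samples, dp)
  })
}

#' Simulate a complete marker-development study
#'
#' Builds a reference genome and a partial-selfing population containing:
#' clean planted CAPS markers (one per contig, centred so a full flank
#' fits), duplicate decoys (CAPS sites whose 201 bp neighbourhood is copied
#' elsewhere at high identity, so the duplicate screen must reject them),
#' linked decoys (CAPS sites whose dosages are a noisy copy of a planted
#' marker's with extra missing calls, so LD pruning must drop them), and a
#' background of rare variants that the MAF filter should remove.
#'
#' @param config a [sim_config()]; `n_contigs` must be at least
#'   `n_markers + n_dup_decoys`.
#' @param catalog enzyme catalog (default: packaged catalog).
#' @param n_markers number of clean planted markers.
#' @param n_dup_decoys number of duplicate decoys.
#' @param n_link_decoys number of linked decoys (at most `n_markers`).
#' @param marker_freq_low,marker_freq_high uniform bounds for planted-site
#'   alternate-allele frequencies.
#' @param dup_identity requested identity of duplicate copies.
#' @param enzyme_names enzymes used for planting (defaults to six-base
#'   cutters so amplicons rarely contain incidental constitutive sites).
#' @return `list(genome, matrix, truth)`; `truth` holds `markers`,
#'   `dup_decoys`, `link_decoys`, `duplicates`, `background`, `true_freqs`,
#'   `true_f` and `seed`.
#' @export
simulate_caps_study <- function(config = sim_config(),
                                catalog = load_enzyme_catalog(),
                                n_markers = 5L, n_dup_decoys = 2L,
                                n_link_decoys = 2L,
                                marker_freq_low = 0.35,
                                marker_freq_high = 0.5,
                                dup_identity = 0.95,
                                enzyme_names = c("NdeI", "AflIII", "AseI",
                                                 "EcoRI", "HindIII", "SpeI",
                                                 "EcoRV", "ScaI", "NheI")) {
  stopifnot(inherits(config, "sim_config"))
  n_planted <- n_markers + n_dup_decoys
  if (config$n_contigs < n_planted) {
    stop("simulate_caps_study: need at least ", n_planted, " contigs")
  }
  if (n_link_decoys > n_markers) stop("simulate_caps_study: more link decoys than markers")
  genome <- generate_reference(config)
  R <- config$flank_radius
  mid <- as.integer(config$contig_length %/% 2L)
  enz_pool <- rep_len(enzyme_names, n_planted + n_link_decoys)

  # Planted sites get a clean same-enzyme neighbourhood over the whole span
  # any feasible amplicon can reach (primer at most dist_max + len_max from
  # the recognition site), so a planted marker is designable by
  # construction and not just locally unique.
  plant_radius <- 660L
  plant_one <- function(genome, contig, pos, enz_name, sub_seed) {
    enz <- catalog[catalog$name == enz_name, ]
    if (nrow(enz) != 1L) stop("simulate_caps_study: enzyme not in catalog: ", enz_name)
    enz <- as.list(enz)
    pat <- strsplit(enz$recognition, "", fixed = TRUE)[[1]]
    # choose the first breakable offset and a breaking substitution
    for (off in seq_along(pat) - 1L) {
      set <- IUPAC_SETS[[pat[off + 1L]]]
      out <- setdiff(c("A", "C", "G", "T"), set)
      if (length(out) > 0L) {
        return(plant_caps_site(genome, contig, pos, enz,
                               cut_allele = set[1], uncut_allele = out[1],
                               snp_offset = off, clear_radius = plant_radius,
                               seed = sub_seed))
      }
    }
    stop("simulate_caps_study: enzyme ", enz_name, " has no breakable position")
  }

  markers <- NULL; dups <- NULL; dup_truth <- NULL; links <- NULL
  k <- 0L
  for (i in seq_len(n_markers)) {
    k <- k + 1L
    res <- plant_one(genome, paste0("contig_", i), mid, enz_pool[k],
                     config$seed + 1000L + k)
    genome <- res$genome
    res$truth$role <- "marker"
    markers <- rbind(markers, res$truth)
  }
  # linked decoys share a contig with their marker, far enough that the
  # marker's amplicon cannot reach them
  link_pos <- max(R + 200L, mid - 3500L)
  for (i in seq_len(n_link_decoys)) {
    k <- k + 1L
    res <- plant_one(genome, paste0("contig_", i), link_pos, enz_pool[k],
                     config$seed + 1000L + k)
    genome <- res$genome
    res$truth$role <- "link_decoy"
    res$truth$linked_to <- markers$snp_id[i]
    links <- rbind(links, res$truth)
  }
  for (i in seq_len(n_dup_decoys)) {
    k <- k + 1L
    ctg <- paste0("contig_", n_markers + i)
    res <- plant_one(genome, ctg, mid, enz_pool[k], config$seed + 1000L + k)
    genome <- res$genome
    res$truth$role <- "dup_decoy"
    dups <- rbind(dups, res$truth)
    # copy the 201 bp window around the decoy SNP elsewhere on the contig
    cp <- plant_duplicate(genome, ctg, mid - 100L, mid + 100L, ctg,
                          max(1L, mid - 4500L), dup_identity,
                          seed = config$seed + 2000L + i)
    genome <- cp$genome
    dup_truth <- rbind(dup_truth, cp$truth)
  }

  # background rare variants, kept out of marker flanks so planted flanks
  # stay fully conserved
  bg <- NULL
  if (config$n_sites > 0L) {
    bg <- with_seed(config$seed + 3000L, {
      planted_all <- rbind(markers[c("contig", "pos")],
                           if (!is.null(links)) links[c("contig", "pos")],
                           if (!is.null(dups)) dups[c("contig", "pos")])
      out <- NULL
      tries <- 0L
      while ((is.null(out) || nrow(out) < config$n_sites) && tries < 50L * config$n_sites) {
        tries <- tries + 1L
        ctg <- sample(names(genome), 1L)
        pos <- sample.int(config$contig_length, 1L)
        near <- planted_all$contig == ctg & abs(planted_all$pos - pos) <= R + 100L
        if (any(near)) next
        if (!is.null(out) && any(out$contig == ctg & out$pos == pos)) next
        ref <- substr(genome[[ctg]], pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        out <- rbind(out, data.frame(contig = ctg, pos = pos, ref = ref,
                                     alt = alt, stringsAsFactors = FALSE))
      }
      if (is.null(out) || nrow(out) < config$n_sites) {
        stop("simulate_caps_study: could not place background sites")
      }
      out$role <- "background"
      out
    })
  }

  planted_sites <- rbind(markers[c("contig", "pos", "ref", "alt", "role")],
                         if (!is.null(links)) links[c("contig", "pos", "ref", "alt", "role")],
                         if (!is.null(dups)) dups[c("contig", "pos", "ref", "alt", "role")])
  sites <- rbind(planted_sites, if (!is.null(bg)) bg[c("contig", "pos", "ref", "alt", "role")])

  freqs <- with_seed(config$seed + 4000L, {
    f_planted <- stats::runif(nrow(planted_sites), marker_freq_low, marker_freq_high)
    f_bg <- if (is.null(bg)) numeric(0) else stats::runif(nrow(bg), config$maf_low, config$maf_high)
    c(f_planted, f_bg)
  })

  dosage <- simulate_genotypes(freqs, config$inbreeding_f, config$n_samples,
                               seed = config$seed + 5000L)
  gm0 <- genotype_matrix(sites[c("contig", "pos", "ref", "alt")], dosage,
                         paste0("S", sprintf("%02d", seq_len(config$n_samples))))
  gm <- simulate_depth_missingness(gm0, config$mean_depth,
                                   seed = config$seed + 6000L)

  # link decoys: replace their dosages with a noisy, more-missing copy of
  # their marker's row so the pair is in strong LD and pruning favours the
  # marker (less missing data)
  if (!is.null(links)) {
    gm <- with_seed(config$seed + 7000L, {
      ids <- snp_id(sites$contig, sites$pos, sites$ref, sites$alt)
      for (i in seq_len(nrow(links))) {
        di <- which(ids == links$snp_id[i])
        mi <- which(ids == links$linked_to[i])
        row <- gm$dosage[mi, ]
        flip <- sample(which(!is.na(row)), 2L)
        row[flip] <- vapply(row[flip], function(d) sample(setdiff(0:2, d), 1L), integer(1))
        extra <- sample(which(!is.na(row)), 3L)
        row[extra] <- NA_integer_
        gm$dosage[di, ] <- row
        gm$depth[di, extra] <- 0L
      }
      gm
    })
  }

  sites$true_freq <- freqs
  truth <- list(markers = markers, dup_decoys = dups, link_decoys = links,
                duplicates = dup_truth, background = bg,
                sites = sites, true_freqs = freqs,
                true_f = config$inbreeding_f, seed = config$seed)
  list(genome = genome, matrix = gm, truth = truth)
}

#' Write a simulation to standard files
#'
#' Emits `reference.fa` (60-column FASTA), `variants.vcf` (VCF v4.2 with
#' `GT:DP` FORMAT, missing genotypes `./.`) and `truth.tsv` (one row per
#' simulated site with role, true frequency and planted-enzyme columns).
#'
#' @param genome named character vector of contigs.
#' @param gm a `genotype_matrix` with depth.
#' @param truth truth list from [simulate_caps_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_simulation <- function(genome, gm, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  vcf <- file.path(dir, "variants.vcf")
  tr <- file.path(dir, "truth.tsv")
  write_fasta(genome, fa)

  ord <- order(gm$sites$contig, gm$sites$pos)
  sites <- gm$sites[ord, , drop = FALSE]
  dosage <- gm$dosage[ord, , drop = FALSE]
  depth <- gm$depth[ord, , drop = FALSE]
  gt_str <- matrix(c("1/1", "0/1", "0/0")[dosage + 1L], nrow = nrow(dosage))
  gt_str[is.na(dosage)] <- "./."
  dp_str <- matrix(as.character(depth), nrow = nrow(depth))
  dp_str[is.na(depth)] <- "."
  cells <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = nrow(dosage))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=capsforge-simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$contig[i], sites$pos[i], sites$snp_id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", ".", "GT:DP", cells[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf)

  tdf <- truth$sites
  tdf$snp_id <- snp_id(tdf$contig, tdf$pos, tdf$ref, tdf$alt)
  enz_map <- rbind(truth$markers, truth$dup_decoys,
                   if (!is.null(truth$link_decoys)) {
                     truth$link_decoys[names(truth$markers)]
                   })
  tdf$enzyme <- enz_map$enzyme[match(tdf$snp_id, enz_map$snp_id)]
  tdf$cut_allele <- enz_map$cut_allele[match(tdf$snp_id, enz_map$snp_id)]
  utils::write.table(tdf, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, vcf = vcf, truth = tr))
}
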
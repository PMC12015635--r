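catalog <- load_enzyme_catalog()

test_that("the enzyme catalog validates entries and flags palindromes", {
  nde <- catalog[catalog$name == "NdeI", ]
  expect_equal(nde$recognition, "CATATG")
  expect_equal(nde$cut_top, 2)
  expect_equal(nde$cut_bottom, 4)
  expect_true(nde$palindromic)
  expect_false(catalog$palindromic[catalog$name == "MnlI"])

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\trecognition\tcut_top\tcut_bottom",
               "FakeI\tGGZCC\t1\t5"), bad)
  expect_error(load_enzyme_catalog(bad), "FakeI")

  empty <- tempfile(fileext = ".tsv")
  writeLines("name\trecognition\tcut_top\tcut_bottom", empty)
  expect_warning(cat0 <- load_enzyme_catalog(empty), "empty")
  expect_equal(nrow(cat0), 0)
})

test_that("recognition matching honours pattern-side degeneracy only", {
  mse <- as.list(catalog[catalog$name == "MseI", ])
  m <- match_recognition("GGTTAACC", mse)
  expect_equal(m$pos, 3)

  dde <- as.list(catalog[catalog$name == "DdeI", ]) # CTNAG
  expect_equal(match_recognition("ACTGAGT", dde)$pos, 2)
  # N in the subject never matches
  expect_equal(nrow(match_recognition("ACTNAGT", dde)), 0)

  # non-palindromic site found on the reverse strand in forward coordinates
  mnl <- as.list(catalog[catalog$name == "MnlI", ]) # CCTC
  m <- match_recognition("AAGAGGAA", mnl) # revcomp contains CCTC
  expect_equal(m$strand, "-")
  expect_equal(m$pos, 3)
  # overlapping occurrences are all reported
  expect_equal(match_recognition("CCTCCTC", mnl, both_strands = FALSE)$pos,
               c(1, 4))
})

# a fully conserved synthetic flank with a planted allele-specific NdeI site
design_fixture <- function(seed = 51, enzyme = "NdeI") {
  cfg <- sim_config(n_contigs = 1, contig_length = 2501, flank_radius = 1000,
                    seed = seed)
  genome <- generate_reference(cfg)
  enz <- as.list(catalog[catalog$name == enzyme, ])
  pos <- 1251L
  pat1 <- strsplit(enz$recognition, "")[[1]][1]
  cut <- capsforge:::IUPAC_SETS[[pat1]][1]
  uncut <- setdiff(c("A", "C", "G", "T"), capsforge:::IUPAC_SETS[[pat1]])[1]
  res <- plant_caps_site(genome, "contig_1", pos, enz, cut, uncut,
                         snp_offset = 0L, seed = seed)
  gm <- genotype_matrix(
    data.frame(contig = "contig_1", pos = pos, ref = cut, alt = uncut,
               stringsAsFactors = FALSE),
    matrix(c(2L, 1L, 0L, 2L), 1, 4), paste0("S", 1:4))
  fl <- extract_flanks(res$genome, gm, 1L, radius = 1000L)
  list(flank = fl, genome = res$genome, enzyme = enz, cut = cut,
       uncut = uncut, pos = pos)
}

test_that("allele-specific site discovery recovers a planted CAPS site", {
  fx <- design_fixture()
  cands <- allele_specific_sites(fx$flank, catalog)
  nde <- cands[cands$enzyme == "NdeI", ]
  expect_equal(nrow(nde), 1)
  expect_equal(nde$digest_allele, fx$cut)
  expect_equal(nde$match_offset, 0)
  expect_true(uniqueness_check(fx$flank, nde, catalog))

  # a SNP that does not touch any site yields no candidate for that enzyme
  fl2 <- fx$flank
  fl2$reference_flank <- paste(rep("A", 2001), collapse = "")
  fl2$site$ref <- "A"; fl2$site$alt <- "C"
  expect_equal(nrow(allele_specific_sites(fl2, catalog[catalog$name == "NdeI", ])), 0)
})

test_that("the uniqueness rule rejects a second site within 150 bp only", {
  fx <- design_fixture()
  cands <- allele_specific_sites(fx$flank, catalog)
  nde <- cands[cands$enzyme == "NdeI", ]

  plant_const <- function(fl, offset_from_snp) {
    i <- fl$snp_offset + 1L + offset_from_snp
    substr(fl$reference_flank, i, i + 5L) <- "CATATG"
    fl
  }
  near <- plant_const(fx$flank, 100L)
  expect_false(uniqueness_check(near, nde, catalog))
  far <- plant_const(fx$flank, 300L)
  expect_true(uniqueness_check(far, nde, catalog))
})

test_that("nearest-neighbor Tm matches an independent thermodynamic calculator", {
  # reference values computed with an independent implementation of the
  # unified NN parameter set (50 mM Na+, 250 nM primer)
  frozen <- c(CGTTCAAAAGCGTGTCCTGTG = 58.781,
              AGATTCCGTCTTGGATCATGGG = 57.7835,
              CTGAGAGTGAGTCCACCAGT = 56.6965,
              ATATATATATATATATATAT = 28.2278,
              GCGCGCGCGCGCGCGCGCGC = 80.9866,
              ACGTGCTAGCTAGGA = 49.1815)
  for (s in names(frozen)) {
    expect_equal(melting_temperature(s), frozen[[s]], tolerance = 0.05)
  }
  # published primer Tm lands in a plausible PCR band
  tm <- melting_temperature("CGTTCAAAAGCGTGTCCTGTG")
  expect_gt(tm, 50); expect_lt(tm, 70)
  # GC monotonicity and strand symmetry
  expect_lt(melting_temperature(strrep("AT", 10)),
            melting_temperature(strrep("GC", 10)))
  p <- "ACGTTGCAGGTCAATCCGT"
  expect_equal(melting_temperature(p), melting_temperature(revcomp(p)),
               tolerance = 1e-9)
  expect_error(melting_temperature("ACGTNACGTAAA"), "ambiguity")
})

test_that("primer design returns constraint-satisfying, ranked specs", {
  fx <- design_fixture()
  cands <- allele_specific_sites(fx$flank, catalog)
  nde <- cands[cands$enzyme == "NdeI", ]
  specs <- design_primers(fx$flank, nde, catalog)
  expect_gt(nrow(specs), 0)
  cns <- primer_constraints()
  top <- specs[1, ]
  for (p in c(top$forward, top$reverse)) {
    expect_gte(nchar(p), cns$len_min); expect_lte(nchar(p), cns$len_max)
    tm <- melting_temperature(p)
    expect_gte(tm, cns$tm_min); expect_lte(tm, cns$tm_max)
    expect_gte(gc_fraction(p), cns$gc_min); expect_lte(gc_fraction(p), cns$gc_max)
  }
  expect_lte(abs(top$tm_forward - top$tm_reverse), cns$dtm_max)
  expect_gte(top$amplicon_length, cns$amp_min)
  expect_lte(top$amplicon_length, cns$amp_max)
  expect_equal(top$fragment_up + top$fragment_down, top$amplicon_length)
  expect_gte(min(top$fragment_up, top$fragment_down), cns$frag_min)
  # ranking is deterministic
  specs2 <- design_primers(fx$flank, nde, catalog)
  expect_identical(specs, specs2)
  # scores are non-decreasing
  expect_true(all(diff(specs$score) >= -1e-12))
})

test_that("infeasible flanks yield an empty list with a constraint tally", {
  fx <- design_fixture()
  cands <- allele_specific_sites(fx$flank, catalog)
  nde <- cands[cands$enzyme == "NdeI", ]
  # mask one whole side as unconserved: no pair can be placed
  fl <- fx$flank
  fl$variants <- rbind(fl$variants, data.frame(
    pos = fl$flank_start, ref = "A", alt = "C",
    offset = 0L, ref_len = 1000L, all_ref_typed = FALSE))
  specs <- design_primers(fl, nde, catalog)
  expect_equal(nrow(specs), 0)
  tally <- attr(specs, "failure_tally")
  expect_gt(tally[["conserved"]], 0)

  # amplicon forced below the minimum: infeasible distances
  tight <- primer_constraints(dist_min = 150, dist_max = 200,
                              amp_min = 590, amp_max = 1000)
  specs2 <- design_primers(fx$flank, nde, catalog, tight)
  expect_equal(nrow(specs2), 0)
})

test_that("non-target constitutive sites inside the amplicon fail the check", {
  fx <- design_fixture()
  cands <- allele_specific_sites(fx$flank, catalog)
  nde <- cands[cands$enzyme == "NdeI", ]
  specs <- design_primers(fx$flank, nde, catalog)
  top <- specs[1, ]
  expect_true(nontarget_site_check(top, fx$flank, catalog))

  inside <- fx$flank
  i <- top$f_start + 20L
  substr(inside$reference_flank, i, i + 5L) <- "CATATG"
  expect_false(nontarget_site_check(top, inside, catalog))

  outside <- fx$flank
  j <- top$r_end + 20L
  substr(outside$reference_flank, j, j + 5L) <- "CATATG"
  expect_true(nontarget_site_check(top, outside, catalog))
})

test_that("digest prediction yields the three canonical band patterns", {
  panel <- caps_marker_panel()
  locus1 <- panel[panel$locus == 1, ]
  expect_equal(predict_digest(locus1, "digest-hom"), c(442, 200))
  expect_equal(predict_digest(locus1, "other-hom"), 642)
  expect_equal(predict_digest(locus1, "het"), c(642, 442, 200))
  missing <- predict_digest(locus1, "missing")
  expect_length(missing, 0)
  expect_true(attr(missing, "missing"))
})
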
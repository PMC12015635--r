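# a small deterministic scenario: one contig, focal SNP centred, one extra
# substitution and one untyped position inside the flank
flank_fixture <- function() {
  cfg <- sim_config(n_contigs = 1, contig_length = 3000, flank_radius = 500,
                    seed = 23)
  genome <- generate_reference(cfg)
  sites <- data.frame(contig = "contig_1",
                      pos = c(1500L, 1400L, 1600L),
                      ref = substring(genome[[1]], c(1500, 1400, 1600),
                                      c(1500, 1400, 1600)),
                      alt = NA_character_, stringsAsFactors = FALSE)
  sites$alt <- vapply(sites$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1],
                      character(1))
  dosage <- rbind(c(2L, 1L, 0L),      # focal SNP: S2 het, S3 alt-hom
                  c(2L, 2L, 1L),      # 1400: S3 het
                  c(2L, NA, 2L))      # 1600: S2 untyped
  gm <- genotype_matrix(sites, dosage, c("S1", "S2", "S3"))
  list(genome = genome, gm = gm)
}

test_that("sample flanks encode substitutions as IUPAC and missing as N", {
  fx <- flank_fixture()
  fl <- extract_flanks(fx$genome, fx$gm, 1L, radius = 500L)
  expect_equal(nchar(fl$reference_flank), 1001)
  expect_equal(fl$snp_offset, 500)
  expect_equal(substr(fl$reference_flank, 501, 501), fl$site$ref)

  s <- fx$gm$sites
  # S1 is hom-ref everywhere: flank equals reference
  expect_equal(fl$sample_flanks[["S1"]], fl$reference_flank)
  # S2: het at the focal SNP -> two-base code; untyped at 1600 -> N
  s2 <- fl$sample_flanks[["S2"]]
  expect_equal(substr(s2, 501, 501), iupac_code(c(s$ref[1], s$alt[1])))
  expect_equal(substr(s2, 601, 601), "N")
  # S3: alt-hom at focal SNP, het at 1400
  s3 <- fl$sample_flanks[["S3"]]
  expect_equal(substr(s3, 501, 501), s$alt[1])
  expect_equal(substr(s3, 401, 401), iupac_code(c(s$ref[2], s$alt[2])))

  # purity: identical inputs give identical flanks
  expect_identical(fl, extract_flanks(fx$genome, fx$gm, 1L, radius = 500L))

  # conserved map excludes the three variant columns and nothing else
  cons <- flank_conserved(fl)
  expect_false(any(cons[c(401, 501, 601)]))
  expect_equal(sum(!cons), 3)
})

test_that("flanks clip at contig edges with a warning", {
  fx <- flank_fixture()
  gm_edge <- genotype_matrix(
    data.frame(contig = "contig_1", pos = 40L,
               ref = substr(fx$genome[[1]], 40, 40),
               alt = "A", stringsAsFactors = FALSE),
    matrix(1L, 1, 3), c("S1", "S2", "S3"))
  gm_edge$sites$alt <- setdiff(c("A", "C", "G", "T"), gm_edge$sites$ref)[1]
  expect_warning(fl <- extract_flanks(fx$genome, gm_edge, 1L, radius = 500L),
                 "clipped")
  expect_equal(nchar(fl$reference_flank), 40 + 500)
  expect_equal(fl$snp_offset, 39)
})

test_that("flank FASTA export carries reference plus all samples", {
  fx <- flank_fixture()
  fl <- extract_flanks(fx$genome, fx$gm, 1L, radius = 500L)
  path <- tempfile(fileext = ".fa")
  write_flank_fasta(fl, path)
  out <- read_fasta(path)
  expect_length(out, 4)
  expect_match(names(out)[1], "reference")
  expect_equal(unname(out[1]), fl$reference_flank)
})

test_that("duplicate scan finds the self-hit and planted high-identity copies", {
  cfg <- sim_config(n_contigs = 2, contig_length = 4000, flank_radius = 500,
                    seed = 29)
  genome <- generate_reference(cfg)
  pos <- 2000L
  gm <- genotype_matrix(
    data.frame(contig = "contig_1", pos = pos,
               ref = substr(genome[[1]], pos, pos), alt = "N",
               stringsAsFactors = FALSE),
    matrix(c(2L, 1L, 0L), 1, 3), c("S1", "S2", "S3"))
  gm$sites$alt <- setdiff(c("A", "C", "G", "T"), gm$sites$ref)[1]

  # 95%-identity copy of the 201 bp window: flagged
  dup <- plant_duplicate(genome, "contig_1", pos - 100L, pos + 100L,
                         "contig_2", 1000L, identity = 0.95, seed = 5)
  fl <- extract_flanks(dup$genome, gm, 1L, radius = 500L)
  hits <- duplicate_scan(fl, list(reference = dup$genome))
  big <- hits[hits$window == 201, ]
  expect_gte(nrow(big), 2)
  expect_equal(sum(big$qualifying), 2)
  copy_hit <- big[big$contig == "contig_2", ]
  expect_gte(copy_hit$identity[1], 0.90)
  expect_false(duplicate_verdict(hits)$pass)

  # clean flank: only self-hits, verdict passes
  fl0 <- extract_flanks(genome, gm, 1L, radius = 500L)
  hits0 <- duplicate_scan(fl0, list(reference = genome))
  expect_true(all(hits0$identity[hits0$qualifying] == 1))
  expect_true(duplicate_verdict(hits0)$pass)

  # 80%-identity copy: below threshold, not flagged
  low <- plant_duplicate(genome, "contig_1", pos - 100L, pos + 100L,
                         "contig_2", 1000L, identity = 0.80, seed = 6)
  fl80 <- extract_flanks(low$genome, gm, 1L, radius = 500L)
  hits80 <- duplicate_scan(fl80, list(reference = low$genome))
  expect_true(duplicate_verdict(hits80)$pass)

  # window larger than flank is an error
  expect_error(duplicate_scan(fl0, list(reference = genome),
                              window_large = 1201L), "exceeds")
})

test_that("seed-and-extend agrees with the brute-force all-offsets oracle", {
  cfg <- sim_config(n_contigs = 2, contig_length = 3000, flank_radius = 500,
                    seed = 37)
  genome <- generate_reference(cfg)
  pos <- 1500L
  dup <- plant_duplicate(genome, "contig_1", pos - 100L, pos + 100L,
                         "contig_2", 800L, identity = 0.95, seed = 7)
  gm <- genotype_matrix(
    data.frame(contig = "contig_1", pos = pos,
               ref = substr(genome[[1]], pos, pos), alt = "N",
               stringsAsFactors = FALSE),
    matrix(c(2L, 1L), 1, 2), c("S1", "S2"))
  gm$sites$alt <- setdiff(c("A", "C", "G", "T"), gm$sites$ref)[1]
  fl <- extract_flanks(dup$genome, gm, 1L, radius = 500L)
  query <- substr(fl$reference_flank, fl$snp_offset + 1L - 100L,
                  fl$snp_offset + 1L + 100L)

  hits <- duplicate_scan(fl, list(reference = dup$genome))
  got <- hits[hits$window == 201 & hits$qualifying, c("contig", "start")]
  want <- oracle_scan(query, dup$genome, identity_min = 0.90)
  expect_equal(nrow(got), nrow(want))
  got <- got[order(got$contig, got$start), ]
  want <- want[order(want$contig, want$start), ]
  expect_equal(got$contig, want$contig)
  expect_true(all(abs(got$start - want$start) <= 10))
})

test_that("the verdict is invariant to reverse-complementing a target genome", {
  cfg <- sim_config(n_contigs = 2, contig_length = 3000, flank_radius = 500,
                    seed = 41)
  genome <- generate_reference(cfg)
  pos <- 1500L
  dup <- plant_duplicate(genome, "contig_1", pos - 100L, pos + 100L,
                         "contig_2", 800L, identity = 0.95, seed = 9)
  gm <- genotype_matrix(
    data.frame(contig = "contig_1", pos = pos,
               ref = substr(genome[[1]], pos, pos), alt = "N",
               stringsAsFactors = FALSE),
    matrix(c(2L, 1L), 1, 2), c("S1", "S2"))
  gm$sites$alt <- setdiff(c("A", "C", "G", "T"), gm$sites$ref)[1]
  fl <- extract_flanks(dup$genome, gm, 1L, radius = 500L)

  flipped <- dup$genome
  flipped[["contig_2"]] <- revcomp(flipped[["contig_2"]])
  v1 <- duplicate_verdict(duplicate_scan(fl, list(g = dup$genome)))
  v2 <- duplicate_verdict(duplicate_scan(fl, list(g = flipped)))
  expect_equal(v1$pass, v2$pass)
  expect_false(v1$pass)
})
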
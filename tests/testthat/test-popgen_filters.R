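test_that("site_stats computes MAF over typed samples with alt-minor tie-break", {
  # symmetric 50:50 site
  st <- site_stats(tiny_gm(counts_to_dosage(5, 0, 5)))
  expect_equal(st$maf, 0.5)
  expect_equal(st$minor_allele, "G") # alt reported as minor at the tie

  # 14 ref-hom, 5 het, 1 alt-hom of 20 typed: alt count 7/40
  st <- site_stats(tiny_gm(counts_to_dosage(14, 5, 1, n_missing = 2)))
  expect_equal(st$n_typed, 20)
  expect_equal(st$maf, 0.175)

  st <- site_stats(tiny_gm(counts_to_dosage(8, 0, 0)))
  expect_equal(st$maf, 0)
})

test_that("basic_filter rejects indels, multiallelics, fixed and thin sites with reasons", {
  sites <- data.frame(
    contig = "c1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("A", "A", "A", "A", "A"),
    alt = c("AT", "C,G", "C", "C", "C"),
    stringsAsFactors = FALSE)
  dosage <- rbind(
    rep(1L, 22),
    rep(1L, 22),
    rep(0L, 22),                                  # fixed for alt
    c(rep(1L, 14), rep(NA_integer_, 8)),          # 14/22 typed
    c(rep(2L, 11), rep(1L, 9), rep(0L, 2)))       # clean, MAF 13/44
  gm <- genotype_matrix(sites, dosage, paste0("S", 1:22))
  out <- basic_filter(gm, filter_params())
  expect_equal(out$decisions$reason[1:4],
               c("indel", "multiallelic", "fixed", "missingness"))
  expect_true(out$decisions$pass[5])
  expect_equal(n_sites(out$matrix), 1)

  # MAF below 0.20 rejected, exactly 0.20 retained (boundary inclusive)
  low <- tiny_gm(counts_to_dosage(16, 3, 1))  # alt 5/40 = 0.125
  expect_equal(basic_filter(low)$decisions$reason, "maf")
  edge <- tiny_gm(counts_to_dosage(13, 6, 1)) # alt 8/40 = 0.20
  expect_true(basic_filter(edge)$decisions$pass)
})

test_that("exact HWE test matches spot values from direct enumeration", {
  r <- hwe_exact(0, 3, 2)
  expect_equal(r$p_excess, 2 / 3, tolerance = 1e-12)
  expect_equal(r$p_deficit, 1)
  expect_equal(r$p_hwe, 1)

  r <- hwe_exact(1, 1, 3)
  expect_equal(r$p_deficit, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p_excess, 1)
  expect_equal(r$p_hwe, 1 / 3, tolerance = 1e-12)

  r <- hwe_exact(5, 0, 0) # monomorphic: single configuration
  expect_equal(unlist(r), c(p_hwe = 1, p_deficit = 1, p_excess = 1))

  expect_error(hwe_exact(-1, 2, 3), "non-negative")
  expect_error(hwe_exact(0, 0, 0), "typed")
})

test_that("HWE tail p-values satisfy their structural invariants", {
  for (n in c(5L, 11L, 22L)) {
    for (nm in seq(0L, n)) {
      h0 <- nm %% 2L # smallest heterozygote count sharing the parity
      na <- (nm - h0) / 2
      r <- hwe_exact(n - h0 - na, h0, na)
      expect_gte(r$p_deficit + r$p_excess, 1)
      expect_true(all(unlist(r[c("p_hwe", "p_deficit", "p_excess")]) >= 0))
      expect_true(all(unlist(r[c("p_hwe", "p_deficit", "p_excess")]) <= 1))
    }
  }
})

test_that("excess screen retains deficit-leaning sites, boundary inclusive", {
  hwe <- data.frame(snp_id = c("a", "b", "c"),
                    p_hwe = c(1, 0.06, 1),
                    p_deficit = c(1, 1, 1),
                    p_excess = c(0.9, 0.03, 0.5))
  keep <- excess_screen(hwe, filter_params())
  expect_equal(keep, c(TRUE, FALSE, TRUE))
})

test_that("tier filter applies the typed-count, tail-comparison and depth rules", {
  p <- filter_params()
  mk <- function(n_ref_hom, n_het, n_alt_hom, n_missing, dp) {
    d <- counts_to_dosage(n_ref_hom, n_het, n_alt_hom, n_missing)
    tiny_gm(d, depth = matrix(dp, nrow = 1))
  }
  # 18 typed: kept regardless of tail lean
  gm <- mk(6, 10, 2, 4, rep(3, 22))
  tf <- tier_filter(gm, hwe_test(gm), p)
  expect_equal(tf$tier, "A")
  expect_true(tf$keep)

  # 16 typed, deficit-leaning: kept; excess-leaning: dropped
  gm <- mk(10, 1, 5, 6, rep(3, 22))
  tf <- tier_filter(gm, hwe_test(gm), p)
  expect_equal(tf$tier, "B")
  expect_true(tf$keep)
  gm <- mk(4, 10, 2, 6, rep(3, 22))
  tf <- tier_filter(gm, hwe_test(gm), p)
  expect_false(tf$keep)
  expect_equal(tf$reason, "excess_leaning")

  # 15 typed, deficit-leaning, only 10 samples at depth >= 2: rejected
  gm <- mk(10, 1, 4, 7, c(rep(2, 10), rep(1, 5), rep(0, 7)))
  tf <- tier_filter(gm, hwe_test(gm), p)
  expect_equal(tf$tier, "C")
  expect_false(tf$keep)
  expect_equal(tf$reason, "low_depth")
  # with 11 at depth >= 2: kept
  gm <- mk(10, 1, 4, 7, c(rep(2, 11), rep(1, 4), rep(0, 7)))
  tf <- tier_filter(gm, hwe_test(gm), p)
  expect_true(tf$keep)
  # tier-C site without depth data is rejected explicitly
  gm2 <- tiny_gm(counts_to_dosage(10, 1, 4, 7))
  tf <- tier_filter(gm2, hwe_test(gm2), p)
  expect_false(tf$keep)
  expect_equal(tf$reason, "no_depth_data")
})

test_that("filter cascade equals the one-shot conjunction of its predicates", {
  sim <- simulate_caps_study(sim_config(n_contigs = 7, seed = 11))
  gm <- sim$matrix
  p <- filter_params()
  bf <- basic_filter(gm, p)
  hwe1 <- hwe_test(bf$matrix)
  keep1 <- excess_screen(hwe1, p)
  s2 <- subset_sites(bf$matrix, keep1)
  tf <- tier_filter(s2, hwe_test(s2), p)
  cascade <- tf$snp_id[tf$keep]

  # conjunction evaluated on the full matrix in one pass
  st <- site_stats(gm)
  hwe_all <- hwe_test(gm)
  tf_all <- tier_filter(gm, hwe_all, p)
  conj <- gm$sites$snp_id[basic_filter(gm, p)$decisions$pass &
                            excess_screen(hwe_all, p) & tf_all$keep]
  expect_setequal(cascade, conj)
})

test_that("inbreeding estimator hits its degenerate limits", {
  expect_equal(inbreeding_estimate(tiny_gm(counts_to_dosage(0, 10, 0))), -1)
  expect_equal(inbreeding_estimate(tiny_gm(counts_to_dosage(5, 0, 5))), 1)
  expect_error(inbreeding_estimate(tiny_gm(counts_to_dosage(8, 0, 0))),
               "polymorphic")
})
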
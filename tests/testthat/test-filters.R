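test_that("site-quality filter applies 'under the floor' strictly", {
  gm <- make_gm(matrix(c(0, 1, 2), 3, 2), qual = c(19.9, 20))
  res <- filter_site_quality(gm, min_qual = 20)
  expect_equal(n_variants(res$gm), 1L)          # 19.9 removed, 20.0 retained
  expect_equal(res$gm$variants$qual, 20)
})

test_that("site-quality ledger counts planted violations exactly", {
  d <- matrix(rbinom(18, 2, 0.5), 3, 6)
  v <- data.frame(chrom = "chr1", pos = (1:6) * 10,
                  id = paste0("v", 1:6),
                  ref = c("A", "A", "AT", "A", "A", "A"),
                  alt = c("G", "G,T", "A", "G", "G", "G"),
                  qual = c(50, 50, 50, 10, 50, 50),
                  n_alleles = c(2L, 3L, 2L, 2L, 2L, 2L))
  gm <- genotype_matrix(d, v, data.frame(sample_id = paste0("s", 1:3)))
  res <- filter_site_quality(gm, 20)
  led <- res$ledger
  expect_equal(n_variants(res$gm), 3L)
  expect_equal(led$count[led$stage == "non_biallelic"], 1L)
  expect_equal(led$count[led$stage == "indel"], 1L)
  expect_equal(led$count[led$stage == "low_quality"], 1L)
  expect_equal(ledger_retained(led), 3L)
})

test_that("genotype QC thresholds are inclusive removals", {
  # site call rate: 0.98 removed, 0.995 retained (200 samples); filler
  # columns keep sample call rates high so no sample drops first
  n <- 200
  base <- rep(c(0, 2), n / 2)
  filler <- matrix(rep(base, 20), n, 20)
  v_ok <- base
  v_098 <- base; v_098[1:4] <- NA
  v_0995 <- base; v_0995[5] <- NA
  gm <- make_gm(cbind(filler, v_ok, v_098, v_0995))
  res <- filter_genotype_qc(gm)
  ids <- res$gm$variants$id
  expect_true("v21" %in% ids)
  expect_false("v22" %in% ids)   # call rate 0.98 <= 0.99 removed
  expect_true("v23" %in% ids)    # call rate 0.995 retained

  # MAF exactly 0.05 removed (inclusive)
  d2 <- matrix(0, 20, 2)
  d2[1, 1] <- 2                  # af = 2/40 = 0.05
  d2[1:6, 2] <- 1                # af = 6/40 = 0.15
  res2 <- filter_genotype_qc(make_gm(d2))
  expect_equal(res2$gm$variants$id, "v2")
  led <- res2$ledger
  expect_equal(led$count[led$stage == "minor_allele_frequency"], 1L)
})

test_that("sample removal precedes site-level MAF computation", {
  # sample s5 is mostly missing; with it, v1 has MAF > 0.05; without it,
  # v1 is monomorphic (MAF 0) and must be removed by the MAF rule
  d <- rbind(c(0, 1, 1, 0, 1, 1, 0, 1, 1, 0),
             c(0, 1, 1, 0, 1, 1, 0, 1, 1, 0),
             c(0, 1, 1, 0, 1, 1, 0, 1, 1, 0),
             c(0, 1, 1, 0, 1, 1, 0, 1, 1, 0),
             c(2, NA, NA, NA, NA, NA, NA, NA, NA, NA))
  gm <- make_gm(d)
  res <- filter_genotype_qc(gm, min_sample_call_rate = 0.5)
  expect_equal(ledger_retained(res$sample_ledger), 4L)
  expect_false("v1" %in% res$gm$variants$id)
  led <- res$ledger
  # with the documented order (samples first) the sites missing only in s5
  # have perfect call rates and survive; had call rate been computed first,
  # all of v2..v10 would have dropped at 0.8 <= 0.99
  expect_equal(n_variants(res$gm), 6L)
  expect_equal(led$count[led$stage == "minor_allele_frequency"], 4L)
  expect_equal(led$count[led$stage == "site_call_rate"], 0L)
  # conservation at every stage
  expect_equal(sum(led$count[led$type == "removed"]) + ledger_retained(led),
               led$count[led$stage == "input"])
})

test_that("heterozygous-haploid policy removes the site or blanks the cell", {
  d <- rbind(c(1, 0, 1), c(0, 1, 1), c(2, 1, 0), c(0, 1, 1))
  pl <- matrix(FALSE, 4, 3); pl[1, 1] <- TRUE  # het call at a haploid cell
  gm <- make_gm(d, ploidy = pl)
  rs <- filter_genotype_qc(gm, min_sample_call_rate = 0.3,
                           min_site_call_rate = 0.5, min_maf = 0.01,
                           hethap_policy = "remove_site")
  expect_false("v1" %in% rs$gm$variants$id)
  led <- rs$ledger
  expect_equal(led$count[led$stage == "heterozygous_haploid"], 1L)
  sm <- filter_genotype_qc(gm, min_sample_call_rate = 0.3,
                           min_site_call_rate = 0.5, min_maf = 0.01,
                           hethap_policy = "set_missing")
  expect_true("v1" %in% sm$gm$variants$id)
  expect_true(is.na(sm$gm$dosages["s1", "v1"]))
})

test_that("Hardy-Weinberg is reported by default and filters on request", {
  set.seed(3)
  # strong heterozygote excess at v1: fails HWE hard
  d <- cbind(rep(1, 40), rbinom(40, 2, 0.5))
  gm <- make_gm(d)
  res <- filter_genotype_qc(gm, min_site_call_rate = 0.5, min_maf = 0.01)
  expect_equal(n_variants(res$gm), 2L)  # reported, not removed
  expect_lt(res$hwe_p[1], 1e-7)
  led <- res$ledger
  expect_gte(led$count[led$stage == "hwe_fail_1e-07"], 1L)
  resf <- filter_genotype_qc(gm, min_site_call_rate = 0.5, min_maf = 0.01,
                             hwe_filter = 1e-7)
  expect_equal(resf$gm$variants$id, "v2")
})

test_that("exact Hardy-Weinberg test matches the enumeration oracle", {
  expect_equal(hwe_exact(10, 0, 0), 1)
  expect_equal(hwe_exact(3, 5, 2), hwe_exact(2, 5, 3))  # allele relabelling
  worst <- 0
  for (n in 1:25) {
    for (a in 0:n) {
      for (h in 0:(n - a)) {
        worst <- max(worst, abs(hwe_exact(a, h, n - a - h) -
                                  hwe_oracle(a, h, n - a - h)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("degenerate filters raise empty-cohort / empty-panel errors", {
  d <- matrix(rep(c(0, 1, NA, NA), each = 3), 3, 4)  # every sample 50% missing
  gm <- make_gm(d)
  expect_error(filter_genotype_qc(gm, min_sample_call_rate = 0.9),
               "empty cohort")
  gm2 <- make_gm(matrix(0, 5, 2))  # all monomorphic -> all fail MAF
  expect_error(filter_genotype_qc(gm2), "empty panel")
})

test_that("ledger conservation holds and negative counts are rejected", {
  led <- filter_ledger(10, c(a = 3, b = 2))
  expect_equal(ledger_retained(led), 5L)
  expect_error(filter_ledger(10, c(a = -1)), "nonnegative")
  expect_error(filter_ledger(3, c(a = 5)), "conservation")
})
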
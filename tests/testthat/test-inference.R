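test_that("Bonferroni thresholds reproduce the printed genome-wide cutoffs", {
  expect_equal(signif(bonferroni_threshold(0.05, 7586942), 3), 6.59e-9)
  expect_equal(signif(bonferroni_threshold(0.05, 7026774), 3), 7.12e-9)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  # threshold times test count returns alpha exactly
  for (m in c(3, 1e4, 7586942)) {
    expect_equal(bonferroni_threshold(0.05, m) * m, 0.05,
                 tolerance = 1e-15)
  }
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("Benjamini-Hochberg equals the min-over-tail oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(10)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone with p
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("genomic lambda behaves as a median ratio", {
  expect_equal(genomic_lambda(stats = rep(qchisq(0.5, 1), 7)), 1)
  s <- rchisq(101, 1)
  expect_equal(genomic_lambda(stats = 2 * s), 2 * genomic_lambda(stats = s))
  set.seed(123)
  lam <- genomic_lambda(runif(1e5))
  expect_gt(lam, 0.98); expect_lt(lam, 1.02)
})

test_that("QQ points and Manhattan coordinates are well-formed", {
  qq <- qq_points(0.5)
  expect_equal(qq$expected, -log10(0.5))
  expect_equal(qq$observed, -log10(0.5))
  p <- runif(50)
  expect_equal(nrow(qq_points(p)), 50L)
  df <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                   pos = rep(c(10, 20, 30, 40, 50), 2),
                   p = runif(10))
  mt <- manhattan_table(df)
  expect_true(all(diff(mt$cum_pos) > 0))
})

test_that("region collapsing merges by gap and matches the partition oracle", {
  df <- data.frame(chrom = "chr1", pos = c(100, 200), p = c(1e-10, 1e-10))
  r <- collapse_regions(df, 1e-8, max_gap = 5e5)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 100); expect_equal(r$end, 200)
  expect_equal(r$n_snps, 2L); expect_equal(r$min_p, 1e-10)
  df2 <- data.frame(chrom = "chr1", pos = c(100, 1.1e6), p = c(1e-10, 1e-10))
  expect_equal(nrow(collapse_regions(df2, 1e-8, max_gap = 5e5)), 2L)
  set.seed(77)
  for (rep in 1:20) {
    m <- sample(5:60, 1)
    df3 <- data.frame(chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
                      pos = sample.int(3e6, m), p = runif(m, 0, 1e-9))
    gap <- sample(c(1e4, 1e5, 5e5), 1)
    r3 <- collapse_regions(df3, 1e-8, max_gap = gap)
    expect_equal(nrow(r3), regions_oracle(df3$chrom, df3$pos, gap))
    # row order of the input must not matter
    r3b <- collapse_regions(df3[sample(m), ], 1e-8, max_gap = gap)
    expect_equal(r3, r3b)
  }
})

test_that("gene annotation overlaps by >= 1 bp with no flanking", {
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(150, 201, 100),
                      end = c(300, 300, 200),
                      gene = c("GENE_IN", "GENE_ADJ", "GENE_OTHER"))
  regions <- collapse_regions(
    data.frame(chrom = "chr1", pos = c(100, 200), p = c(1e-10, 1e-10)),
    1e-8)
  ann <- annotate_regions(regions, genes)
  expect_equal(ann$genes, "GENE_IN")  # adjacent gene at 201 is not listed
})

test_that("BED and GFF3 encodings of the same intervals annotate identically", {
  bed <- tempfile(fileext = ".bed")
  gff <- tempfile(fileext = ".gff3")
  # one gene at 1-based [150, 300]: BED is 0-based half-open
  writeLines("chr1\t149\t300\tGENE1", bed)
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t150\t300\t.\t+\t.\tID=g1;Name=GENE1"), gff)
  regions <- collapse_regions(
    data.frame(chrom = "chr1", pos = c(100, 200), p = c(1e-10, 1e-10)), 1e-8)
  a1 <- annotate_regions(regions, bed)
  a2 <- annotate_regions(regions, gff)
  expect_equal(a1$genes, "GENE1")
  expect_equal(a1$genes, a2$genes)
})

test_that("annotation agrees with an all-pairs overlap oracle", {
  set.seed(5)
  genes <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                      start = sample.int(1e6, 40))
  genes$end <- genes$start + sample.int(5e4, 40)
  genes$gene <- paste0("g", seq_len(40))
  snps <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                     pos = sample.int(1e6, 30), p = runif(30, 0, 1e-9))
  regions <- collapse_regions(snps, 1e-8, max_gap = 1e5)
  ann <- annotate_regions(regions, genes)
  for (i in seq_len(nrow(ann))) {
    hits <- genes$gene[genes$chrom == ann$chrom[i] &
                         genes$start <= ann$end[i] &
                         genes$end >= ann$start[i]]
    got <- if (ann$genes[i] == "") character(0) else
      strsplit(ann$genes[i], ",")[[1]]
    expect_setequal(got, hits)
  }
})
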
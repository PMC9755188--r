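# shared fixture builders and independent oracles

make_gm <- function(dosages, chrom = NULL, pos = NULL, qual = NULL,
                    breed = NULL, sex = NULL, ploidy = NULL) {
  d <- as.matrix(dosages)
  n <- nrow(d); p <- ncol(d)
  genotype_matrix(
    d,
    data.frame(chrom = if (is.null(chrom)) rep("chr1", p) else chrom,
               pos = if (is.null(pos)) seq_len(p) * 100 else pos,
               id = paste0("v", seq_len(p)),
               ref = "A", alt = "G",
               qual = if (is.null(qual)) rep(50, p) else qual,
               n_alleles = 2L, is_snv = TRUE),
    data.frame(sample_id = paste0("s", seq_len(n)),
               breed = if (is.null(breed)) rep("b1", n) else breed,
               sex = if (is.null(sex)) rep("unknown", n) else sex),
    ploidy = ploidy)
}

random_gm <- function(n, p, seed, maf_range = c(0.1, 0.5), miss = 0) {
  set.seed(seed)
  f <- runif(p, maf_range[1], maf_range[2])
  d <- matrix(rbinom(n * p, 2, rep(f, each = n)), n, p)
  if (miss > 0) d[runif(n * p) < miss] <- NA
  make_gm(d)
}

# dense GLS oracle: beta/se/p for one SNP at fixed variance ratio r
dense_gls_oracle <- function(y, W, x, K, r) {
  n <- length(y)
  V <- r * K + diag(n)
  Vi <- solve(V)
  X <- cbind(W, x)
  A <- solve(t(X) %*% Vi %*% X)
  b <- A %*% t(X) %*% Vi %*% y
  res <- y - X %*% b
  df <- n - ncol(W) - 1
  s2 <- drop(t(res) %*% Vi %*% res) / df
  k <- ncol(X)
  se <- sqrt(s2 * A[k, k])
  stat <- (b[k] / se)^2
  list(beta = b[k], se = se, stat = stat,
       p = pf(stat, 1, df, lower.tail = FALSE))
}

# dense REML objective (profiled error variance), direct matrix evaluation
dense_reml_oracle <- function(y, X, K, r) {
  n <- length(y)
  V <- r * K + diag(n)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  b <- solve(A, t(X) %*% Vi %*% y)
  res <- y - X %*% b
  rss <- drop(t(res) %*% Vi %*% res)
  nc <- n - ncol(X)
  se2 <- rss / nc
  -0.5 * (nc * log(2 * pi * se2) + nc +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(A)$modulus))
}

# weighted normal-equations oracle for one SNP column
wls_oracle <- function(y, W, x, wt) {
  X <- cbind(W, x)
  Wm <- diag(wt)
  A <- solve(t(X) %*% Wm %*% X)
  b <- A %*% t(X) %*% Wm %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- drop(t(res) %*% Wm %*% res) / df
  k <- ncol(X)
  se <- sqrt(s2 * A[k, k])
  tval <- b[k] / se
  list(beta = b[k], se = se, p = 2 * pt(-abs(tval), df))
}

# full-enumeration exact Hardy-Weinberg oracle (closed-form probabilities)
hwe_oracle <- function(a, h, b) {
  n <- a + h + b
  nA <- 2 * a + h
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hs, function(x) {
    aa <- (nA - x) / 2; bb <- n - aa - x
    if (aa < 0 || bb < 0) return(-Inf)
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(x + 1) - lgamma(bb + 1) +
      x * log(2) +
      lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp)
  obs <- pr[hs == h]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# min-over-tail Benjamini-Hochberg oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  }
  q
}

# brute-force gap partition oracle for region collapsing
regions_oracle <- function(chrom, pos, max_gap) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  n_regions <- 0L
  last_chrom <- NULL; last_pos <- NULL
  for (i in seq_along(pos)) {
    if (is.null(last_chrom) || chrom[i] != last_chrom ||
        pos[i] - last_pos > max_gap) {
      n_regions <- n_regions + 1L
    }
    last_chrom <- chrom[i]; last_pos <- pos[i]
  }
  n_regions
}

# small toy VCF with planted filter violations; returns the path
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\tv1\tA\tG\t30\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tA\tG,T\t50\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t300\tv3\tAT\tA\t40\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "chr1\t400\tv4\tA\tG\t19.9\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "chr1\t500\tv5\tA\tG\t20\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    "chr1\t600\tv6\tA\tG\t60\tPASS\t.\tGT\t./.\t0/1\t1/1"
  )
  writeLines(lines, path)
  path
}
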
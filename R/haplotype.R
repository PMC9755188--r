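# haplotypes over a w-SNP window are coded as integers 0..2^w-1, bit k set
# when site k carries the alternate allele; printed as strings over {R, A}

hap_string <- function(code, w) {
  vapply(code, function(h) {
    paste(ifelse(bitwAnd(h, 2^(seq_len(w) - 1)) > 0, "A", "R"), collapse = "")
  }, character(1))
}

# enumerate unordered compatible haplotype pairs for one multilocus genotype
# g in {0,1,2}^w; returns 2-column matrix of codes (h1 <= h2)
compatible_pairs <- function(g) {
  w <- length(g)
  het <- which(g == 1)
  base <- sum(2^(which(g == 2) - 1))
  H <- length(het)
  if (H == 0) return(matrix(base, 1, 2))
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), H)))
  h1 <- base + combos %*% 2^(het - 1)
  h2 <- base + (1 - combos) %*% 2^(het - 1)
  pairs <- cbind(pmin(h1, h2), pmax(h1, h2))
  unique(pairs)
}

#' EM haplotype-frequency estimation for one SNP window
#'
#' Standard expectation-maximisation over unphased multilocus genotypes:
#' the E-step distributes each individual over its compatible phase pairs
#' with probabilities proportional to the product of current haplotype
#' frequencies (doubled for heterozygous pairs); the M-step re-estimates
#' frequencies from expected haplotype counts. Converges when the largest
#' frequency change drops below `tol` (default 1e-8) or after `max_iter`
#' iterations. Individuals with any missing genotype in the window are
#' excluded (count reported). After convergence, haplotypes with frequency
#' below `rare_freq` are pooled into a single rare class.
#'
#' @param block n x w dosage matrix (entries 0/1/2/NA).
#' @param rare_freq pooling threshold, default 0.01.
#' @param tol,max_iter convergence controls.
#' @return object of class `haplotype_window`: `freq` (named), `dosage`
#'   (expected per-sample haplotype dosages, rows sum to 2), `kept` (row
#'   index of retained individuals), `n_excluded`, `loglik`, `n_iter`,
#'   `converged`.
#' @export
haplotype_em <- function(block, rare_freq = 0.01, tol = 1e-8, max_iter = 1000) {
  block <- as.matrix(block)
  w <- ncol(block)
  keep <- which(stats::complete.cases(block))
  n_exc <- nrow(block) - length(keep)
  if (length(keep) == 0) {
    out <- structure(list(freq = NULL, dosage = NULL, kept = integer(0),
                          n_excluded = n_exc, loglik = NA_real_,
                          n_iter = 0L, converged = FALSE, skipped = TRUE),
                     class = "haplotype_window")
    return(out)
  }
  B <- block[keep, , drop = FALSE]

  key <- apply(B, 1, paste, collapse = "")
  groups <- split(seq_along(key), key)
  genos <- lapply(groups, function(ix) B[ix[1], ])
  counts <- lengths(groups)
  pairs <- lapply(genos, compatible_pairs)

  nh <- 2^w
  # flatten all (group, phase pair) combinations for vectorised E-steps
  gidx <- rep(seq_along(pairs), vapply(pairs, nrow, integer(1)))
  P <- do.call(rbind, pairs)
  h1 <- P[, 1] + 1; h2 <- P[, 2] + 1
  mult <- ifelse(h1 == h2, 1, 2)
  glev <- seq_along(pairs)
  gfac <- factor(gidx, levels = glev)
  hboth <- c(h1, h2)
  n2 <- 2 * sum(counts)

  f <- rep(1 / nh, nh)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ph <- f[h1] * f[h2] * mult
    tot <- rowsum(ph, gfac)[, 1]
    bad <- tot <= 0
    if (any(bad)) {
      ph[gidx %in% glev[bad]] <- 1
      tot <- rowsum(ph, gfac)[, 1]
    }
    wgt <- ph / tot[gidx]
    ll <- sum(counts * log(pmax(tot, 1e-300)))
    inc <- counts[gidx] * wgt
    rs <- rowsum(c(inc, inc), hboth)
    exp_cnt <- numeric(nh)
    exp_cnt[as.integer(rownames(rs))] <- rs[, 1]
    f_new <- exp_cnt / n2
    delta <- max(abs(f_new - f))
    f <- f_new
    ll_old <- ll
    if (delta < tol) { converged <- TRUE; break }
  }
  n_iter <- it

  # expected per-sample haplotype dosages under the final frequencies
  ph <- f[h1] * f[h2] * mult
  tot <- rowsum(ph, gfac)[, 1]
  wgt <- ifelse(tot[gidx] > 0, ph / tot[gidx], 1)
  Dg <- matrix(0, length(pairs), nh)  # per distinct genotype
  ij1 <- cbind(gidx, h1); ij2 <- cbind(gidx, h2)
  for (k in seq_along(gidx)) {
    Dg[ij1[k, 1], ij1[k, 2]] <- Dg[ij1[k, 1], ij1[k, 2]] + wgt[k]
    Dg[ij2[k, 1], ij2[k, 2]] <- Dg[ij2[k, 1], ij2[k, 2]] + wgt[k]
  }
  D <- matrix(0, length(keep), nh)
  for (gi in seq_along(groups)) {
    D[groups[[gi]], ] <- matrix(Dg[gi, ], length(groups[[gi]]), nh,
                                byrow = TRUE)
  }
  colnames(D) <- hap_string(0:(nh - 1), w)
  names(f) <- colnames(D)

  # pool rare haplotypes
  rare <- f < rare_freq
  if (any(rare) && sum(!rare) >= 1) {
    Dp <- cbind(D[, !rare, drop = FALSE],
                rare = rowSums(D[, rare, drop = FALSE]))
    fp <- c(f[!rare], rare = sum(f[rare]))
    if (sum(f[rare]) == 0) {
      Dp <- Dp[, -ncol(Dp), drop = FALSE]
      fp <- fp[-length(fp)]
    }
    D <- Dp; f <- fp
  }

  structure(list(freq = f, dosage = D, kept = keep, n_excluded = n_exc,
                 loglik = ll_old, n_iter = n_iter, converged = converged,
                 skipped = FALSE),
            class = "haplotype_window")
}

#' @export
print.haplotype_window <- function(x, ...) {
  if (x$skipped) { cat("haplotype_window: skipped (no complete genotypes)\n")
    return(invisible(x)) }
  cat("haplotype_window: ", length(x$kept), " individuals (",
      x$n_excluded, " excluded), ", length(x$freq), " haplotype classes, ",
      x$n_iter, " EM iterations\n", sep = "")
  print(round(x$freq, 4))
  invisible(x)
}

# direct observed-data log-likelihood of a frequency vector (for checks)
haplotype_loglik <- function(block, freq_full) {
  B <- block[stats::complete.cases(block), , drop = FALSE]
  ll <- 0
  for (i in seq_len(nrow(B))) {
    pr <- compatible_pairs(B[i, ])
    ph <- freq_full[pr[, 1] + 1] * freq_full[pr[, 2] + 1] *
      ifelse(pr[, 1] == pr[, 2], 1, 2)
    ll <- ll + log(max(sum(ph), 1e-300))
  }
  ll
}

#' Sliding-window haplotype association scan
#'
#' Fixed-width windows (default 4 SNPs) slide by one SNP within each
#' chromosome, so a chromosome with s sites yields `max(0, s - 3)` windows.
#' Per window, haplotype frequencies and expected per-sample haplotype
#' dosages come from [haplotype_em()]; the test is an omnibus F comparing
#' the regression of the phenotype on covariates plus (H - 1) haplotype
#' dosage columns against covariates alone (one column is dropped because
#' dosages sum to 2). Windows with a single non-rare haplotype, or whose
#' dosages are collinear with the covariates, are degenerate rows with
#' `p = 1`. Per-SNP significance is the minimum p over windows covering the
#' SNP.
#'
#' @param gm a [genotype_matrix()] (variants sorted).
#' @param y numeric per-sample phenotype.
#' @param pcs matrix of eigenvector covariates (columns), e.g. the first k
#'   columns of a [grm_eigen()] basis; may be `NULL` for intercept-only.
#' @param window_size SNPs per window, default 4.
#' @param rare_freq haplotype pooling threshold, default 0.01.
#' @return list of class `hap_scan`: `windows` (an [assoc_scan()] at window
#'   level, `pos` = window start, `end` = window end) and `snps` (per-SNP
#'   data.frame with the min-over-windows p and the count of covering
#'   windows).
#' @export
haplotype_scan <- function(gm, y, pcs = NULL, window_size = 4,
                           rare_freq = 0.01) {
  y <- as.numeric(y)
  n <- n_samples(gm)
  if (length(y) != n) stop("phenotype not aligned to samples")
  W0 <- cbind(intercept = rep(1, n), pcs)
  v <- gm$variants
  d <- gm$dosages

  rows <- list()
  snp_p <- rep(NA_real_, n_variants(gm))
  snp_nw <- integer(n_variants(gm))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) < window_size) next
    for (s in seq_len(length(idx) - window_size + 1)) {
      cols <- idx[s:(s + window_size - 1)]
      em <- haplotype_em(d[, cols, drop = FALSE], rare_freq = rare_freq)
      pos0 <- v$pos[cols[1]]; pos1 <- v$pos[cols[window_size]]
      if (em$skipped) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, pos = pos0, end = pos1, n_hap = 0L, stat = NA_real_,
          df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
          flag = "skipped", stringsAsFactors = FALSE)
        next
      }
      kept <- em$kept
      H <- ncol(em$dosage)
      res <- hap_window_ftest(y[kept], W0[kept, , drop = FALSE], em$dosage)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = pos0, end = pos1, n_hap = H, stat = res$stat,
        df1 = res$df1, df2 = res$df2, p = res$p, flag = res$flag,
        stringsAsFactors = FALSE)
      if (!is.na(res$p)) {
        upd <- is.na(snp_p[cols]) | res$p < snp_p[cols]
        snp_p[cols][upd] <- res$p
        snp_nw[cols] <- snp_nw[cols] + 1L
      }
    }
  }
  win <- do.call(rbind, rows)
  win$beta <- NA_real_; win$se <- NA_real_
  windows <- assoc_scan(win, model = "haplotype",
                        covariates = paste0("intercept+",
                                            ncol(W0) - 1, "PCs"))
  snps <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, p = snp_p,
                     n_windows = snp_nw, stringsAsFactors = FALSE)
  structure(list(windows = windows, snps = snps), class = "hap_scan")
}

# omnibus F-test: y ~ W + (H-1) haplotype dosage columns  vs  y ~ W
hap_window_ftest <- function(y, W, hap_dosage) {
  H <- ncol(hap_dosage)
  if (H < 2)
    return(list(stat = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = 1, flag = "degenerate"))
  Xh <- hap_dosage[, -H, drop = FALSE]  # drop one class: rows sum to 2
  qr0 <- qr(W)
  r0 <- qr.resid(qr0, y)
  X1 <- cbind(W, Xh)
  qr1 <- qr(X1)
  q <- qr1$rank - qr0$rank
  n <- length(y)
  df2 <- n - qr1$rank
  if (q < 1 || df2 < 1)
    return(list(stat = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = 1, flag = "degenerate"))
  r1 <- qr.resid(qr1, y)
  rss0 <- sum(r0^2); rss1 <- sum(r1^2)
  if (rss1 <= 0)
    return(list(stat = Inf, df1 = q, df2 = df2,
                p = .Machine$double.xmin, flag = ""))
  Fstat <- ((rss0 - rss1) / q) / (rss1 / df2)
  list(stat = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE), flag = "")
}

#' @export
print.hap_scan <- function(x, ...) {
  cat("haplotype scan: ", nrow(x$windows), " windows over ",
      nrow(x$snps), " SNPs\n", sep = "")
  print(x$windows)
  invisible(x)
}
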
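#' Breed-averaged dosages and weighted-least-squares inputs
#'
#' Builds the breeds x SNPs matrix of mean non-missing alternate-allele
#' dosages (the "SNP average allelic frequency" on the 0-2 dosage scale),
#' the breed weights (each breed's share of genotyped individuals), and the
#' principal components of the genomic relationship matrix of the breed
#' rows. SNPs for which some breed has no genotyped call are dropped with a
#' reported count.
#'
#' @param gm a [genotype_matrix()]; every sample's breed must appear in
#'   `panel`.
#' @param panel a [breed_panel()]. Panel breeds absent from the cohort are
#'   dropped with a message.
#' @param n_pcs how many principal components to precompute (default 5).
#' @return object of class `wls_inputs`: `X` (breeds x SNPs), `breeds`,
#'   `weights`, `pcs`, `variants`, `panel`, `n_dropped`.
#' @export
breed_average_dosage <- function(gm, panel, n_pcs = 5) {
  breeds_gm <- gm$samples$breed
  if (anyNA(breeds_gm)) stop("samples without a breed label")
  missing_b <- setdiff(unique(breeds_gm), panel$breed)
  if (length(missing_b))
    stop("breeds not in the panel: ", paste(missing_b, collapse = ", "))
  present <- panel$breed[panel$breed %in% breeds_gm]
  if (length(present) < nrow(panel))
    message(nrow(panel) - length(present), " panel breeds have no genotyped samples and are dropped")

  fb <- factor(breeds_gm, levels = present)
  d <- gm$dosages
  cnt <- rowsum((!is.na(d)) * 1, fb)        # breeds x snps non-missing counts
  sums <- rowsum(ifelse(is.na(d), 0, d), fb)
  X <- sums / cnt                            # NaN where a breed has no calls
  complete <- colSums(cnt == 0) == 0
  n_dropped <- sum(!complete)
  X <- X[, complete, drop = FALSE]
  variants <- gm$variants[complete, , drop = FALSE]

  nb <- as.integer(table(fb))
  weights <- nb / sum(nb)

  k <- max(min(n_pcs, nrow(X) - 1), 0)
  if (k > 0) {
    eig <- grm_eigen(centered_grm(X))
    pcs <- eig$vectors[, seq_len(k), drop = FALSE]
    colnames(pcs) <- paste0("pc", seq_len(k))
  } else {
    eig <- NULL
    pcs <- matrix(numeric(0), nrow(X), 0)
  }

  structure(list(X = X, breeds = present, n = nb, weights = weights,
                 pcs = pcs, variants = variants, panel = panel,
                 n_dropped = n_dropped, eig = eig),
            class = "wls_inputs")
}

#' @export
print.wls_inputs <- function(x, ...) {
  cat("wls_inputs: ", nrow(x$X), " breeds x ", ncol(x$X), " SNPs (",
      x$n_dropped, " SNPs dropped for breed-level missingness)\n", sep = "")
  invisible(x)
}

#' Weighted least squares breed-phenotype scan
#'
#' Per SNP j, fits `y ~ pc1 + ... + pc_k + x_j` by weighted least squares
#' over breeds, with weights equal to each breed's share of the genotyped
#' sample population, and reports the SNP slope with its t-test on
#' `n - n_pcs - 2` degrees of freedom (two-sided). Constant dosage columns
#' are degenerate rows with `p = 1`.
#'
#' @param inputs a [breed_average_dosage()] result.
#' @param y per-breed prevalence vector aligned to `inputs$breeds`, or the
#'   name of a disease column of the panel.
#' @param n_pcs number of principal-component covariates, default 5.
#' @return an [assoc_scan()] with model tag `"wls"`.
#' @export
wls_scan <- function(inputs, y, n_pcs = 5) {
  if (is.character(y) && length(y) == 1) {
    y <- inputs$panel[[y]][match(inputs$breeds, inputs$panel$breed)]
  }
  y <- as.numeric(y)
  n <- nrow(inputs$X)
  if (length(y) != n) stop("phenotype not aligned to breeds")
  if (anyNA(y)) stop("breeds without a reported prevalence; subset first")
  if (n_pcs > ncol(inputs$pcs)) stop("requested more PCs than available")
  if (n <= n_pcs + 2) stop("fewer breeds than model parameters")

  W <- cbind(intercept = rep(1, n),
             inputs$pcs[, seq_len(n_pcs), drop = FALSE])
  wt <- inputs$weights
  sw <- sqrt(wt)
  Xw <- W * sw
  yw <- y * sw
  Gw <- inputs$X * sw
  qrX <- qr(Xw)
  ry <- qr.resid(qrX, yw)
  rG <- qr.resid(qrX, Gw)
  sxx <- colSums(rG^2)
  scale0 <- pmax(colSums(Gw^2), .Machine$double.eps)
  degen <- sxx / scale0 < 1e-12
  beta <- colSums(rG * ry) / sxx
  df <- n - n_pcs - 2
  rss <- pmax(sum(ry^2) - beta^2 * sxx, 0)
  s2 <- rss / df
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  beta[degen] <- NA; se[degen] <- NA; tval[degen] <- NA; p[degen] <- 1

  v <- inputs$variants
  res <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref,
                    alt = v$alt, beta = beta, se = se, stat = tval^2,
                    p = p, flag = ifelse(degen, "degenerate", ""),
                    stringsAsFactors = FALSE)
  res$stat[degen] <- NA
  assoc_scan(res, model = "wls",
             covariates = paste0("intercept+", n_pcs, "PCs"))
}
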
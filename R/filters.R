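#' Filter ledger
#'
#' Bookkeeping table for the two-stage filtering protocol: one row per stage
#' with the number of units removed, plus input/retained rows and (for the
#' genotype-QC stage) Hardy-Weinberg failure counts at reporting thresholds.
#' Conservation (input = retained + sum removed) is enforced at construction.
#'
#' @param input input count.
#' @param removed named integer vector of removals by reason, in stage order.
#' @param extra optional named counts that are reported but are not removals
#'   (e.g. Hardy-Weinberg failures).
#' @param unit `"variants"` or `"samples"`.
#' @return data.frame of class `filter_ledger` with columns `stage`, `count`,
#'   `type`.
#' @export
filter_ledger <- function(input, removed, extra = NULL, unit = "variants") {
  removed <- stats::setNames(as.integer(removed), names(removed))
  if (any(removed < 0) || input < 0) stop("ledger counts must be nonnegative")
  retained <- input - sum(removed)
  if (retained < 0) stop("ledger conservation violated: removed exceed input")
  df <- data.frame(
    stage = c("input", names(removed), "retained"),
    count = c(input, removed, retained),
    type = c("input", rep("removed", length(removed)), "retained"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra) && length(extra)) {
    df <- rbind(df, data.frame(stage = names(extra),
                               count = as.integer(extra),
                               type = "reported", stringsAsFactors = FALSE))
  }
  attr(df, "unit") <- unit
  class(df) <- c("filter_ledger", "data.frame")
  df
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("filter ledger (", attr(x, "unit"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Retained count from a ledger
#' @param ledger a [filter_ledger()].
#' @return integer retained count.
#' @export
ledger_retained <- function(ledger) ledger$count[ledger$type == "retained"]

#' Write a ledger as TSV
#' @param ledger a [filter_ledger()].
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Site-quality stage: biallelic SNVs above a quality floor
#'
#' Retains biallelic single-nucleotide variants with site quality at or above
#' `min_qual`; the quality rule is strict (a score *under* the floor is
#' removed, so a variant exactly at the floor is retained). Removal reasons
#' are assessed in order: multi-allelic, then indel, then low quality.
#'
#' @param gm a [genotype_matrix()].
#' @param min_qual quality floor, default 20.
#' @return list with elements `gm` (filtered) and `ledger`.
#' @export
filter_site_quality <- function(gm, min_qual = 20) {
  if (min_qual < 0) stop("min_qual must be >= 0")
  v <- gm$variants
  multi <- v$n_alleles > 2L
  indel <- !multi & !v$is_snv
  lowq <- !multi & !indel & !is.na(v$qual) & v$qual < min_qual
  keep <- !multi & !indel & !lowq
  ledger <- filter_ledger(
    input = nrow(v),
    removed = c(non_biallelic = sum(multi), indel = sum(indel),
                low_quality = sum(lowq))
  )
  list(gm = gm_subset(gm, variants = keep), ledger = ledger)
}

#' Genotype-level QC: call rates, minor allele frequency, heterozygous haploids
#'
#' Mirrors the standard protocol: samples with a genotyping rate at or below
#' `min_sample_call_rate` are removed first; then sites with call rate at or
#' below `min_site_call_rate`; then sites with minor allele frequency at or
#' below `min_maf` (computed from non-missing calls after sample removal;
#' sites monomorphic after sample removal have MAF 0 and fall to this rule);
#' finally heterozygous calls at haploid cells are handled per policy.
#' All three numeric thresholds are inclusive removals.
#'
#' Hardy-Weinberg is reported, not filtered, by default: the ledger counts
#' sites failing each `hwe_report` threshold among the retained sites. Passing
#' `hwe_filter` additionally removes sites below that p-value.
#'
#' @param gm a [genotype_matrix()].
#' @param min_sample_call_rate default 0.90.
#' @param min_site_call_rate default 0.99.
#' @param min_maf default 0.05.
#' @param hethap_policy `"remove_site"` (default) drops any site with a
#'   heterozygous call in a haploid cell; `"set_missing"` blanks the offending
#'   cells before call-rate/MAF computation instead.
#' @param hwe_report p-value thresholds at which Hardy-Weinberg failures are
#'   counted in the ledger; default `c(1e-7, 5e-5)`.
#' @param hwe_filter optional p-value below which sites are removed.
#' @return list with `gm`, `ledger` (sites), `sample_ledger` (samples) and
#'   `hwe_p` (exact-test p-values for the retained sites).
#' @export
filter_genotype_qc <- function(gm,
                               min_sample_call_rate = 0.90,
                               min_site_call_rate = 0.99,
                               min_maf = 0.05,
                               hethap_policy = c("remove_site", "set_missing"),
                               hwe_report = c(1e-7, 5e-5),
                               hwe_filter = NULL) {
  hethap_policy <- match.arg(hethap_policy)
  stopifnot(min_sample_call_rate > 0, min_sample_call_rate < 1,
            min_site_call_rate > 0, min_site_call_rate < 1,
            min_maf > 0, min_maf < 1)
  n0 <- n_samples(gm); p0 <- n_variants(gm)

  # heterozygous haploid handling (set_missing acts before any rate is computed)
  hethap_site <- rep(FALSE, p0)
  if (!is.null(gm$ploidy)) {
    hh <- gm$ploidy & !is.na(gm$dosages) & gm$dosages == 1
    if (hethap_policy == "set_missing") {
      gm$dosages[hh] <- NA_real_
    } else {
      hethap_site <- colSums(hh) > 0
    }
  }

  # 1. sample call rate (inclusive removal at the threshold)
  scr <- rowMeans(!is.na(gm$dosages))
  drop_sample <- scr <= min_sample_call_rate
  sample_ledger <- filter_ledger(n0, c(low_call_rate = sum(drop_sample)),
                                 unit = "samples")
  if (all(drop_sample)) stop("empty cohort: all samples removed by call rate")
  if (any(drop_sample)) gm <- gm_subset(gm, samples = !drop_sample)

  d <- gm$dosages
  # 2. site call rate
  site_cr <- colMeans(!is.na(d))
  rm_cr <- site_cr <= min_site_call_rate
  # 3. MAF on non-missing calls after sample removal
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  rm_maf <- !rm_cr & maf <= min_maf
  # 4. het-haploid site removal
  rm_hh <- !rm_cr & !rm_maf & hethap_site
  keep <- !rm_cr & !rm_maf & !rm_hh

  removed <- c(site_call_rate = sum(rm_cr),
               minor_allele_frequency = sum(rm_maf),
               heterozygous_haploid = sum(rm_hh))

  if (!any(keep)) stop("empty panel: all sites removed")
  gm2 <- gm_subset(gm, variants = keep)

  hwe_p <- hwe_exact_gm(gm2)
  extra <- stats::setNames(
    vapply(hwe_report, function(t) sum(hwe_p < t, na.rm = TRUE), integer(1)),
    sprintf("hwe_fail_%g", hwe_report)
  )

  if (!is.null(hwe_filter)) {
    rm_hwe <- !is.na(hwe_p) & hwe_p < hwe_filter
    removed <- c(removed, hardy_weinberg = sum(rm_hwe))
    gm2 <- gm_subset(gm2, variants = !rm_hwe)
    hwe_p <- hwe_p[!rm_hwe]
    if (n_variants(gm2) == 0) stop("empty panel: all sites removed")
  }

  ledger <- filter_ledger(p0, removed, extra = extra)
  list(gm = gm2, ledger = ledger, sample_ledger = sample_ledger, hwe_p = hwe_p)
}

# exact HWE p per site of a genotype matrix (diploid cells only)
hwe_exact_gm <- function(gm) {
  d <- gm$dosages
  if (!is.null(gm$ploidy)) d[gm$ploidy] <- NA_real_
  n0 <- colSums(!is.na(d) & d == 0)
  n1 <- colSums(!is.na(d) & d == 1)
  n2 <- colSums(!is.na(d) & d == 2)
  p <- rep(NA_real_, ncol(d))
  tot <- n0 + n1 + n2
  ok <- tot > 0
  p[ok] <- mapply(hwe_exact, n0[ok], n1[ok], n2[ok])
  p
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: the p-value sums
#' the probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("total genotype count must be > 0")
  nr <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)  # rare allele count
  if (nr == 0) return(1)
  hs <- seq(nr %% 2, nr, by = 2)  # feasible het counts share parity with nr
  # log P(h | n, nr) up to a common constant:
  # P proportional to 2^h * n! / (h! * ((nr-h)/2)! * ((2n-nr-h)/2)!)
  lp <- hs * log(2) - lgamma(hs + 1) - lgamma((nr - hs) / 2 + 1) -
    lgamma((2 * n - nr - hs) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hs)]
  if (is.na(obs)) stop("genotype counts inconsistent with allele parity")
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}
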
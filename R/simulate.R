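#' Simulation configuration for a multi-breed cohort
#'
#' Defaults emulate the shape of a typical mid-size canine WGS repository
#' panel: 27 breeds totalling 230 dogs with strongly unbalanced breed sizes
#' (1 to 59 dogs per breed), two-level Balding-Nichols divergence (breeds
#' nested in clades), a small fraction of missing calls, site quality scores
#' with a tail below the usual floor of 20, and breed disease prevalences
#' produced by a logistic liability model driven by planted large-effect
#' variants plus breed-level noise.
#'
#' @param n_breeds number of breeds.
#' @param n_samples total cohort size; breed sizes are drawn as a skewed
#'   multinomial clipped to `size_range` unless `samples_per_breed` is given.
#'   `NULL` draws each breed's size uniformly from `size_range` instead
#'   (no fixed total).
#' @param samples_per_breed optional explicit vector of breed sizes
#'   (overrides `n_samples`).
#' @param size_range inclusive bounds on drawn breed sizes.
#' @param n_snps,n_chromosomes panel dimensions.
#' @param n_clades number of breed clades (two-level divergence).
#' @param fst total breed-level fixation index; split evenly over the clade
#'   and within-clade levels so that the compounded divergence equals `fst`.
#' @param fst_clade,fst_breed optional explicit per-level values overriding
#'   the even split.
#' @param n_causal number of planted causal SNPs.
#' @param beta liability slope per unit of breed allele-dosage shift.
#' @param prevalence_intercept logit of the baseline prevalence.
#' @param breed_liability_sd sd of non-genetic breed-level liability noise
#'   (logit scale). Default 0: prevalence is an exact logistic function of
#'   the planted allele-frequency shifts. Set a positive value to model
#'   breed effects unrelated to the planted variants (required for a
#'   non-degenerate phenotype when `n_causal = 0`, e.g. in null calibration
#'   studies).
#' @param missingness per-call missing probability.
#' @param qual_mean,qual_sd site quality score distribution (normal,
#'   truncated at 0); the defaults leave ~5% of sites under 20.
#' @param sex_probs probabilities of female/male/unknown.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 27, n_samples = 230,
                       samples_per_breed = NULL, size_range = c(1, 59),
                       n_snps = 5000, n_chromosomes = 10, n_clades = 4,
                       fst = 0.2, fst_clade = NULL, fst_breed = NULL,
                       n_causal = 1, beta = 1.5,
                       prevalence_intercept = stats::qlogis(0.15),
                       breed_liability_sd = 0,
                       missingness = 0.02, qual_mean = 45, qual_sd = 15,
                       sex_probs = c(female = 0.24, male = 0.73,
                                     unknown = 0.03)) {
  stopifnot(fst > 0, fst < 1, n_causal <= n_snps)
  if (is.null(fst_clade)) fst_clade <- 1 - sqrt(1 - fst)
  if (is.null(fst_breed)) fst_breed <- 1 - (1 - fst) / (1 - fst_clade)
  cfg <- list(n_breeds = n_breeds, n_samples = n_samples,
              samples_per_breed = samples_per_breed, size_range = size_range,
              n_snps = n_snps, n_chromosomes = n_chromosomes,
              n_clades = n_clades, fst = fst, fst_clade = fst_clade,
              fst_breed = fst_breed, n_causal = n_causal, beta = beta,
              prevalence_intercept = prevalence_intercept,
              breed_liability_sd = breed_liability_sd,
              missingness = missingness, qual_mean = qual_mean,
              qual_sd = qual_sd, sex_probs = sex_probs)
  class(cfg) <- "sim_config"
  cfg
}

# Beta draw around mean p with Balding-Nichols dispersion F
bn_draw <- function(p, F) {
  if (F < 1e-8) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

#' Balding-Nichols breed allele frequencies
#'
#' Ancestral frequencies `p0 ~ U(0.05, 0.95)`; each clade draws its
#' frequency from `Beta(p0(1-F1)/F1, (1-p0)(1-F1)/F1)` and each breed draws
#' likewise around its clade's frequency with `F2`. The compounded
#' breed-level divergence is `F1 + F2 - F1*F2`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `p0` (length n_snps), `p_clade` (clades x SNPs),
#'   `p_breed` (breeds x SNPs), `clade_of_breed`.
#' @export
simulate_breed_frequencies <- function(cfg, seed = 1) {
  with_seed(seed, {
    p0 <- stats::runif(cfg$n_snps, 0.05, 0.95)
    clade_of_breed <- rep(seq_len(cfg$n_clades), length.out = cfg$n_breeds)
    p_clade <- t(vapply(seq_len(cfg$n_clades),
                        function(cl) bn_draw(p0, cfg$fst_clade),
                        numeric(cfg$n_snps)))
    p_breed <- t(vapply(seq_len(cfg$n_breeds), function(b) {
      bn_draw(p_clade[clade_of_breed[b], ], cfg$fst_breed)
    }, numeric(cfg$n_snps)))
    rownames(p_breed) <- paste0("breed", sprintf("%02d", seq_len(cfg$n_breeds)))
    list(p0 = p0, p_clade = p_clade, p_breed = p_breed,
         clade_of_breed = clade_of_breed)
  })
}

# draw breed sizes: explicit; uniform over size_range when no total is
# requested; otherwise a skewed multinomial clipped to size_range
draw_breed_sizes <- function(cfg) {
  if (!is.null(cfg$samples_per_breed)) {
    sz <- as.integer(cfg$samples_per_breed)
    if (length(sz) != cfg$n_breeds) stop("samples_per_breed length mismatch")
    return(sz)
  }
  lo <- cfg$size_range[1]; hi <- cfg$size_range[2]
  if (is.null(cfg$n_samples)) {
    return(sample(lo:hi, cfg$n_breeds, replace = TRUE))
  }
  # heavily skewed shares reproduce repository-style imbalance
  shares <- sort(stats::rexp(cfg$n_breeds), decreasing = TRUE)
  sz <- pmin(pmax(round(shares / sum(shares) * cfg$n_samples), lo), hi)
  # nudge to the exact total while respecting the bounds
  gap <- cfg$n_samples - sum(sz)
  i <- 1
  while (gap != 0) {
    j <- (i - 1) %% cfg$n_breeds + 1
    if (gap > 0 && sz[j] < hi) { sz[j] <- sz[j] + 1L; gap <- gap - 1 }
    if (gap < 0 && sz[j] > lo) { sz[j] <- sz[j] - 1L; gap <- gap + 1 }
    i <- i + 1
    if (i > 100000) stop("cannot reach the requested total within size bounds")
  }
  sz
}

#' Simulate genotypes for a breed-structured cohort
#'
#' Per-individual dosages are Binomial(2, p_breed) at each site;
#' missingness is applied uniformly at random; site quality scores and
#' sexes are drawn per the configuration; variants are laid out on
#' `n_chromosomes` chromosomes with increasing positions.
#'
#' @param freqs a [simulate_breed_frequencies()] result.
#' @param cfg the [sim_config()].
#' @param seed integer seed.
#' @return list with `gm` (a [genotype_matrix()]) and `sizes` (breed sizes).
#' @export
simulate_genotypes <- function(freqs, cfg, seed = 1) {
  with_seed(seed, {
    sizes <- draw_breed_sizes(cfg)
    breeds <- rownames(freqs$p_breed)
    breed_of_sample <- rep(breeds, sizes)
    n <- length(breed_of_sample)
    p <- cfg$n_snps

    P <- freqs$p_breed[rep(seq_along(sizes), sizes), , drop = FALSE]
    d <- matrix(stats::rbinom(n * p, 2, as.vector(P)), n, p)
    if (cfg$missingness > 0) {
      d[stats::runif(n * p) < cfg$missingness] <- NA
    }

    per_chr <- rep(p %/% cfg$n_chromosomes, cfg$n_chromosomes)
    extra <- p - sum(per_chr)
    if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1
    chrom <- rep(sprintf("chr%02d", seq_len(cfg$n_chromosomes)), per_chr)
    pos <- unlist(lapply(per_chr, function(m) cumsum(sample(500:3000, m,
                                                            replace = TRUE))))
    qual <- round(pmax(stats::rnorm(p, cfg$qual_mean, cfg$qual_sd), 0), 1)
    variants <- data.frame(chrom = chrom, pos = pos,
                           id = paste0("snp", sprintf("%06d", seq_len(p))),
                           ref = "A", alt = "G", qual = qual,
                           n_alleles = 2L, is_snv = TRUE,
                           stringsAsFactors = FALSE)
    sex <- sample(names(cfg$sex_probs), n, replace = TRUE,
                  prob = cfg$sex_probs)
    samples <- data.frame(
      sample_id = sprintf("dog%04d", seq_len(n)),
      breed = breed_of_sample, sex = sex, stringsAsFactors = FALSE)
    gm <- genotype_matrix(d, variants, samples, sort_variants = FALSE)
    list(gm = gm, sizes = sizes)
  })
}

#' Simulate breed disease prevalences from planted causal variants
#'
#' Liability of breed b is `L_b = sum_j beta_j (2 p_bj - 2 p0_j)` over the
#' planted causal SNPs (effects operate through breed-level allele
#' frequencies, since the phenotype is a breed attribute), plus optional
#' non-genetic breed noise `eps_b ~ N(0, breed_liability_sd)` (zero by
#' default); prevalence is `plogis(intercept + L_b)`.
#'
#' @param freqs a [simulate_breed_frequencies()] result.
#' @param sizes breed sample counts.
#' @param cfg the [sim_config()].
#' @param seed integer seed.
#' @return list with `panel` (a [breed_panel()] with column `disease`) and
#'   `truth` (class `sim_truth`: causal indices, betas, per-breed liability
#'   and prevalence, ancestral and breed frequencies of the causal SNPs).
#' @export
simulate_prevalence <- function(freqs, sizes, cfg, seed = 1) {
  with_seed(seed, {
    nb <- nrow(freqs$p_breed)
    # large-effect shared variants are common ones: draw causals from
    # mid-range ancestral frequency
    eligible <- which(freqs$p0 >= 0.2 & freqs$p0 <= 0.8)
    if (length(eligible) < cfg$n_causal) eligible <- seq_len(cfg$n_snps)
    causal <- sort(sample(eligible, cfg$n_causal))
    betas <- rep(cfg$beta, cfg$n_causal)
    shift <- 2 * sweep(freqs$p_breed[, causal, drop = FALSE], 2,
                       freqs$p0[causal])
    L <- drop(shift %*% betas) + stats::rnorm(nb, 0, cfg$breed_liability_sd)
    prev <- stats::plogis(cfg$prevalence_intercept + L)
    panel <- breed_panel(rownames(freqs$p_breed), sizes,
                         data.frame(disease = prev))
    truth <- structure(list(causal_index = causal, beta = betas,
                            liability = L, prevalence = prev,
                            p0_causal = freqs$p0[causal],
                            p_breed_causal = freqs$p_breed[, causal,
                                                           drop = FALSE],
                            intercept = cfg$prevalence_intercept),
                       class = "sim_truth")
    list(panel = panel, truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Orchestrates frequency, genotype and prevalence simulation; optionally
#' writes the VCF, phenotype TSV, sample metadata TSV and truth JSON to a
#' directory. All outputs are reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param dir optional output directory (created if missing).
#' @return list with `gm`, `panel`, `truth`, `freqs` and (when `dir` is
#'   given) `paths`.
#' @export
generate_study <- function(cfg = sim_config(), seed = 1, dir = NULL) {
  freqs <- simulate_breed_frequencies(cfg, seed = seed)
  geno <- simulate_genotypes(freqs, cfg, seed = seed + 1)
  phen <- simulate_prevalence(freqs, geno$sizes, cfg, seed = seed + 2)
  out <- list(gm = geno$gm, panel = phen$panel, truth = phen$truth,
              freqs = freqs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "cohort.vcf"),
                  phenotype = file.path(dir, "phenotypes.tsv"),
                  meta = file.path(dir, "meta.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_vcf(geno$gm, paths$vcf)
    utils::write.table(as.data.frame(phen$panel), paths$phenotype,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(geno$gm$samples, paths$meta, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tr <- phen$truth
    jsonlite::write_json(
      list(causal_index = tr$causal_index, beta = tr$beta,
           causal_id = geno$gm$variants$id[tr$causal_index],
           liability = tr$liability, prevalence = tr$prevalence,
           p0_causal = tr$p0_causal, intercept = tr$intercept,
           seed = seed),
      paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Inject breed-label errors into a cohort
#'
#' Relabels `n` randomly chosen samples with a breed other than their own
#' (drawn from the other breeds present), to exercise breed verification.
#' Only samples from breeds that keep at least two correctly labelled
#' members are chosen, so the injected errors are detectable in principle.
#'
#' @param gm a [genotype_matrix()].
#' @param n number of samples to mislabel.
#' @param seed integer seed.
#' @return list with `gm` (relabelled) and `injected` (data.frame with
#'   `sample_id`, `true_breed`, `assigned_breed`).
#' @export
inject_mislabels <- function(gm, n, seed = 1) {
  with_seed(seed, {
    breeds <- gm$samples$breed
    tab <- table(breeds)
    eligible <- which(tab[breeds] >= 3)  # leave >= 2 true members behind
    if (length(eligible) < n) stop("not enough samples in multi-member breeds")
    pick <- sample(eligible, n)
    target_pool <- names(tab)[tab >= 2]
    assigned <- vapply(pick, function(i) {
      sample(setdiff(target_pool, breeds[i]), 1)
    }, character(1))
    injected <- data.frame(sample_id = gm$samples$sample_id[pick],
                           true_breed = breeds[pick],
                           assigned_breed = assigned,
                           stringsAsFactors = FALSE)
    gm$samples$breed[pick] <- assigned
    list(gm = gm, injected = injected)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", length(x$causal_index), " causal SNPs at index ",
      paste(x$causal_index, collapse = ", "), "; beta = ",
      paste(x$beta, collapse = ", "), "\n", sep = "")
  cat(sprintf("  breed prevalence range: %.3f - %.3f\n",
              min(x$prevalence), max(x$prevalence)))
  invisible(x)
}
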
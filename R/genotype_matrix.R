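#' Genotype matrix container
#'
#' The central data structure: a samples x variants matrix of alternate-allele
#' dosages (0, 1, 2 or `NA` for a missing call) together with ordered variant
#' and sample annotation tables and an optional per-cell haploidy mask (male
#' non-pseudoautosomal X/Y cells).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qual`, `n_alleles`, `is_snv`; one row per column of `dosages`.
#'   Missing optional columns are filled with defaults.
#' @param samples data.frame with columns `sample_id`, `breed`, `sex`
#'   (`"female"`, `"male"` or `"unknown"`); one row per row of `dosages`.
#' @param ploidy optional logical matrix of the same dimension as `dosages`;
#'   `TRUE` marks a haploid cell. `NULL` means all-diploid.
#' @param sort_variants sort columns by (chrom, pos)? Default `TRUE`; the
#'   sorted order is an invariant the scans rely on.
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples, ploidy = NULL,
                            sort_variants = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (nrow(variants) != ncol(dosages))
    stop("variant annotation has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  if (nrow(samples) != nrow(dosages))
    stop("sample annotation has ", nrow(samples), " rows but dosage matrix has ",
         nrow(dosages), " rows")
  bad <- !(is.na(dosages) | dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosage entries outside {0, 1, 2, NA}: first offender at index ",
         which(bad)[1])

  if (is.null(variants$id))
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  if (is.null(variants$qual)) variants$qual <- NA_real_
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "T"
  if (is.null(variants$n_alleles)) variants$n_alleles <- 2L
  if (is.null(variants$is_snv))
    variants$is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
      variants$n_alleles == 2L
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$n_alleles < 2)) stop("n_alleles must be >= 2")

  if (is.null(samples$breed)) samples$breed <- NA_character_
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (!all(samples$sex %in% c("female", "male", "unknown")))
    stop("sex must be one of 'female', 'male', 'unknown'")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])

  if (!is.null(ploidy)) {
    ploidy <- as.matrix(ploidy)
    if (!identical(dim(ploidy), dim(dosages)))
      stop("ploidy mask dimension mismatch")
    storage.mode(ploidy) <- "logical"
  }

  if (sort_variants && ncol(dosages) > 1) {
    o <- order(variants$chrom, variants$pos)
    if (!identical(o, seq_len(ncol(dosages)))) {
      dosages <- dosages[, o, drop = FALSE]
      variants <- variants[o, , drop = FALSE]
      if (!is.null(ploidy)) ploidy <- ploidy[, o, drop = FALSE]
    }
  }
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  dimnames(dosages) <- list(samples$sample_id, variants$id)

  structure(list(dosages = dosages, variants = variants, samples = samples,
                 ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " variants\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$variants$chrom), collapse = ", "), "\n",
      sep = "")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  nb <- length(unique(x$samples$breed[!is.na(x$samples$breed)]))
  cat("  breeds: ", nb, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants
#' @param gm a `genotype_matrix`
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`
#' @param samples index vector (logical, integer or sample ids) over samples
#' @param variants index vector (logical or integer) over variants
#' @return the subsetted `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  si <- seq_len(n_samples(gm))
  vi <- seq_len(n_variants(gm))
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, gm$samples$sample_id)
    si <- si[samples]
    if (anyNA(si)) stop("unknown sample in subset")
  }
  if (!is.null(variants)) vi <- vi[variants]
  genotype_matrix(gm$dosages[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$samples[si, , drop = FALSE],
                  ploidy = if (!is.null(gm$ploidy)) gm$ploidy[si, vi, drop = FALSE],
                  sort_variants = FALSE)
}

# mean-impute missing dosages per variant; returns list(mat, n_imputed)
impute_dosages <- function(gm) {
  d <- gm$dosages
  n_imp <- sum(is.na(d))
  if (n_imp > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  list(mat = d, n_imputed = n_imp)
}

# numeric sex covariate: female 0, male 1, unknown -> mean of known (logged)
sex_covariate <- function(samples) {
  s <- samples$sex
  x <- ifelse(s == "male", 1, ifelse(s == "female", 0, NA))
  n_unknown <- sum(is.na(x))
  if (n_unknown > 0) {
    fill <- if (all(is.na(x))) 0.5 else mean(x, na.rm = TRUE)
    x[is.na(x)] <- fill
  }
  attr(x, "n_imputed") <- n_unknown
  x
}
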
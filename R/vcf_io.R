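#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.x file (plain or gzipped) and maps each genotype call to
#' an alternate-allele dosage. Multi-allelic records are retained with their
#' allele count recorded (`n_alleles`); the dosage is the count of non-reference
#' alleles in the call. Missing calls (`./.` or `.`) become `NA`.
#'
#' Haploidy: when a chromosome configuration declares a chromosome haploid in
#' males (non-pseudoautosomal X, Y), cells of male samples on that chromosome
#' are marked haploid in the ploidy mask. Single-allele calls (e.g. `"1"`) are
#' stored on the diploid dosage scale (0 or 2) with the mask set.
#'
#' @param path path to a VCF file.
#' @param meta optional data.frame with `sample_id`, `breed`, `sex` to attach;
#'   defaults to unknown breed/sex for all samples in the file.
#' @param chrom_config optional chromosome configuration, see
#'   [read_chrom_config()].
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, meta = NULL, chrom_config = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("structural error: VCF has no sample genotype columns: ", path)
  sample_ids <- colnames(gt)[-1]

  alt <- fix$ALT
  n_alleles <- 1L + ifelse(is.na(alt) | alt == ".", 0L,
                           nchar(gsub("[^,]", "", alt)) + 1L)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF,
    alt = alt,
    qual = qual,
    n_alleles = pmax(n_alleles, 2L),
    stringsAsFactors = FALSE
  )
  variants$is_snv <- variants$n_alleles == 2L &
    nchar(variants$ref) == 1L &
    nchar(sub(",.*", "", variants$alt)) == 1L
  if (anyNA(variants$pos))
    stop("parse error: non-numeric POS at record ", which(is.na(variants$pos))[1])

  # GT string -> dosage. First field before ':'.
  gtv <- sub(":.*", "", gt[, -1, drop = FALSE])
  dos <- gt_to_dosage(gtv)
  dosages <- t(dos)  # records x samples -> samples x records

  if (is.null(meta)) {
    meta <- data.frame(sample_id = sample_ids, breed = NA_character_,
                       sex = "unknown", stringsAsFactors = FALSE)
  } else {
    m <- match(sample_ids, meta$sample_id)
    if (anyNA(m))
      stop("sample metadata missing for: ",
           paste(sample_ids[is.na(m)], collapse = ", "))
    meta <- meta[m, , drop = FALSE]
  }

  ploidy <- NULL
  if (!is.null(chrom_config)) {
    hap_chroms <- chrom_config$haploid_in_males
    if (length(hap_chroms)) {
      male <- meta$sex == "male"
      on_hap <- variants$chrom %in% hap_chroms
      if (any(male) && any(on_hap)) {
        ploidy <- outer(male, on_hap, `&`)
      }
    }
  }

  genotype_matrix(dosages, variants, meta, ploidy = ploidy)
}

# vectorised GT parsing over a character matrix (records x samples)
gt_to_dosage <- function(gtv) {
  u <- unique(as.vector(gtv))
  map <- vapply(u, function(g) {
    if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a)) stop("parse error: bad genotype field '", g, "'")
    d <- sum(a > 0)
    if (length(a) == 1) d <- 2 * d  # haploid call on diploid dosage scale
    d
  }, numeric(1))
  out <- map[match(as.vector(gtv), u)]
  dim(out) <- dim(gtv)
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Plain-text VCF; dosages map back to unphased genotype calls
#' (0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`). Haploid cells are
#' written as single-allele calls except heterozygous-haploid cells, which are
#' written as `0/1` so that the anomaly round-trips.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  if (n_variants(gm) == 0 || n_samples(gm) == 0)
    stop("empty panel: nothing to write")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=breedscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  ), con)
  v <- gm$variants
  d <- gm$dosages
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  if (!is.null(gm$ploidy)) {
    hap <- gm$ploidy
    gt[hap & !is.na(d) & d == 0] <- "0"
    gt[hap & !is.na(d) & d == 2] <- "1"
    gt[hap & is.na(d)] <- "."
    # het haploid left as 0/1 on purpose
  }
  qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE, digits = 10))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, qual, "PASS", ".", "GT",
                sep = "\t")
  gt_cols <- apply(gt, 2, paste, collapse = "\t")
  writeLines(paste(body, gt_cols, sep = "\t"), con)
  invisible(path)
}

#' Chromosome ploidy configuration
#'
#' JSON file with fields `haploid_in_males` (array of chromosome names that
#' are haploid in males outside pseudoautosomal regions, typically X and Y).
#' No pseudoautosomal inference is attempted; the declaration is taken as-is.
#'
#' @param path path to a JSON file.
#' @return a list with element `haploid_in_males`.
#' @export
read_chrom_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$haploid_in_males)) cfg$haploid_in_males <- character(0)
  cfg
}

#' Per-variant and per-sample QC summaries
#'
#' Mean depth (when a per-cell depth matrix is supplied), missingness fraction
#' and site quality per variant; mean depth and missingness per sample.
#'
#' @param gm a [genotype_matrix()].
#' @param depths optional numeric matrix of per-cell read depths, same
#'   dimensions as the dosage matrix.
#' @return list with data.frames `variants` and `samples`.
#' @export
qc_summaries <- function(gm, depths = NULL) {
  if (n_variants(gm) == 0 || n_samples(gm) == 0) stop("empty genotype matrix")
  d <- gm$dosages
  vs <- data.frame(
    id = gm$variants$id,
    chrom = gm$variants$chrom,
    pos = gm$variants$pos,
    missingness = colMeans(is.na(d)),
    qual = gm$variants$qual,
    stringsAsFactors = FALSE
  )
  ss <- data.frame(
    sample_id = gm$samples$sample_id,
    missingness = rowMeans(is.na(d)),
    stringsAsFactors = FALSE
  )
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (!identical(dim(depths), dim(d))) stop("depth matrix dimension mismatch")
    vs$mean_depth <- colMeans(depths, na.rm = TRUE)
    ss$mean_depth <- rowMeans(depths, na.rm = TRUE)
  }
  list(variants = vs, samples = ss)
}

#' Write genotype data to standard formats
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix (without extension).
#' @param format `"vcf"` (writes `<prefix>.vcf`) or `"plink"` (writes
#'   `<prefix>.bed/.bim/.fam`).
#' @return the paths written, invisibly.
#' @export
write_outputs <- function(gm, prefix, format = c("vcf", "plink")) {
  format <- match.arg(format)
  if (n_variants(gm) == 0 || n_samples(gm) == 0)
    stop("empty panel: nothing to write")
  if (format == "vcf") {
    p <- paste0(prefix, ".vcf")
    write_vcf(gm, p)
    invisible(p)
  } else {
    invisible(write_plink(gm, prefix))
  }
}

#' Write PLINK bed/bim/fam
#'
#' SNP-major bed with the alternate allele as A1, so dosages round-trip
#' exactly (2 alt alleles -> homozygous A1). Sex codes 1 = male, 2 = female,
#' 0 = unknown; breed is stored as the family id.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix for the `.bed`, `.bim`, `.fam` triplet.
#' @return character vector of the three paths, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  if (n_variants(gm) == 0 || n_samples(gm) == 0)
    stop("empty panel: nothing to write")
  n <- n_samples(gm); p <- n_variants(gm)
  v <- gm$variants; s <- gm$samples

  bim <- data.frame(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos,
                    a1 = sub(",.*", "", v$alt), a2 = v$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = ifelse(is.na(s$breed), "0", gsub("[ \t]", "_", s$breed)),
                    iid = s$sample_id, pat = 0, mat = 0,
                    sex = ifelse(s$sex == "male", 1L,
                                 ifelse(s$sex == "female", 2L, 0L)),
                    pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # 2-bit codes per sample, 4 samples per byte, LSB first:
  # 00 hom A1 (dosage 2), 10 het (1), 11 hom A2 (0), 01 missing
  code <- matrix(3L, n, p)
  d <- gm$dosages
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[is.na(d)] <- 1L
  npad <- 4 * ceiling(n / 4)
  bytes <- raw(3 + ceiling(n / 4) * p)
  bytes[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  at <- 4L
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(p)) {
    cj <- c(code[, j], integer(npad - n))
    m4 <- matrix(cj, nrow = 4)
    vals <- as.integer(colSums(m4 * mult))
    nb <- length(vals)
    bytes[at:(at + nb - 1)] <- as.raw(vals)
    at <- at + nb
  }
  bed <- paste0(prefix, ".bed")
  writeBin(bytes, bed)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read PLINK bed/bim/fam
#'
#' Inverse of [write_plink()]. Dosage counts the A1 allele. Site quality is
#' not representable in PLINK and comes back as `NA`.
#'
#' @param prefix path prefix of the `.bed`, `.bim`, `.fam` triplet.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "character"))
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  body <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n / 4)
  if (length(body) != bpv * p) stop("bed file size mismatch")
  # unpack 2-bit fields
  q <- matrix(body, nrow = bpv)
  codes <- matrix(0L, 4 * bpv, p)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bpv, by = 4), ] <- q %% 4L
    q <- q %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, p)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0

  variants <- data.frame(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                         ref = bim$a2, alt = bim$a1, qual = NA_real_,
                         n_alleles = 2L,
                         is_snv = nchar(bim$a1) == 1 & nchar(bim$a2) == 1,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam$iid,
                        breed = ifelse(fam$fid == "0", NA_character_, fam$fid),
                        sex = ifelse(fam$sex == 1, "male",
                                     ifelse(fam$sex == 2, "female", "unknown")),
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples)
}
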
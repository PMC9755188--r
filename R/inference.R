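#' Bonferroni family-wise threshold
#'
#' `alpha / n_tests` at full precision; display rounding (3 significant
#' figures) is left to [format_threshold()]/printing.
#'
#' @param alpha family-wise level, default 0.05.
#' @param n_tests number of tests (>= 1).
#' @return the threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_i = min_{j>=i} m p_(j) / j`
#' along the sorted p-values, mapped back to input order.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values, monotone with the p-values.
#' @export
bh_fdr <- function(pvals) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' P-values are transformed to 1-df chi-square quantiles; lambda is their
#' median divided by the null chi-square median (0.4549364).
#'
#' @param pvals p-values (or use `stats` to pass chi-square statistics
#'   directly).
#' @param stats optional 1-df chi-square statistics, overriding `pvals`.
#' @return lambda.
#' @export
genomic_lambda <- function(pvals = NULL, stats = NULL) {
  if (is.null(stats)) {
    if (is.null(pvals) || !length(pvals)) stop("no p-values")
    pvals <- pvals[!is.na(pvals)]
    stats <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  }
  stats::median(stats) / stats::qchisq(0.5, df = 1)
}

#' QQ-plot coordinates
#'
#' @param pvals p-values.
#' @return data.frame with `expected` and `observed` -log10 p columns,
#'   sorted by significance.
#' @export
qq_points <- function(pvals) {
  p <- sort(pvals[!is.na(pvals)])
  m <- length(p)
  if (!m) stop("no p-values")
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p))
}

#' Manhattan-plot table
#'
#' Adds a cumulative genome coordinate (strictly increasing within and
#' across chromosomes, in order of appearance) to a result table.
#'
#' @param results a data.frame with `chrom`, `pos`, `p` (e.g. an
#'   [assoc_scan()]).
#' @return data.frame with an added `cum_pos` column.
#' @export
manhattan_table <- function(results) {
  df <- as.data.frame(results)
  if (!nrow(df)) stop("empty result table")
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos), , drop = FALSE]
  chroms <- unique(df$chrom)
  offset <- 0
  df$cum_pos <- NA_real_
  for (ch in chroms) {
    i <- df$chrom == ch
    df$cum_pos[i] <- df$pos[i] + offset
    offset <- offset + max(df$pos[i]) + 1
  }
  df
}

#' Collapse significant SNPs into regions
#'
#' SNPs with `p < threshold` on the same chromosome are merged while
#' consecutive gaps are at most `max_gap` base pairs; region bounds are the
#' terminal SNP positions (1-based inclusive) and the smallest p in the
#' region is recorded.
#'
#' @param results an [assoc_scan()] or data.frame with `chrom`, `pos`, `p`.
#' @param threshold significance threshold (e.g. a Bonferroni threshold).
#' @param max_gap merge gap in bp, default 500000.
#' @return data.frame of class `region_table` with `chrom`, `start`, `end`,
#'   `n_snps`, `min_p`.
#' @export
collapse_regions <- function(results, threshold, max_gap = 500000) {
  df <- as.data.frame(results)
  sig <- df[!is.na(df$p) & df$p < threshold, , drop = FALSE]
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), n_snps = integer(0),
                    min_p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sig)) {
    sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
    newreg <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                  diff(sig$pos) > max_gap)
    gid <- cumsum(newreg)
    out <- do.call(rbind, lapply(split(sig, gid), function(g) {
      data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
                 n_snps = nrow(g), min_p = min(g$p), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
  }
  class(out) <- c("region_table", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "max_gap") <- max_gap
  out
}

#' Annotate regions with overlapping genes
#'
#' Lists every gene interval overlapping each region by at least one base
#' pair. No flanking is added on either side (an adjacent gene is not
#' listed) and strand is ignored. Intervals may come from a BED file
#' (0-based half-open, converted at the boundary), a GFF3 file (1-based
#' inclusive), or a data.frame with `chrom`, `start`, `end`, `gene`
#' (1-based inclusive).
#'
#' @param regions a [collapse_regions()] result.
#' @param genes path to a `.bed`/`.gff3`/`.gff` file, or a data.frame.
#' @return `regions` with an added `genes` column (comma-separated names).
#' @export
annotate_regions <- function(regions, genes) {
  gi <- if (is.character(genes)) read_gene_intervals(genes) else {
    stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
    as.data.frame(genes)
  }
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- gi$chrom == regions$chrom[i] &
      gi$start <= regions$end[i] & gi$end >= regions$start[i]
    paste(unique(gi$gene[hit]), collapse = ",")
  }, character(1))
  regions
}

# read gene intervals from BED or GFF3 into 1-based inclusive coordinates
read_gene_intervals <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    return(read_gene_intervals_base(path, ext))
  }
  gr <- tryCatch(
    rtracklayer::import(path,
                        format = if (ext == "bed") "BED" else "GFF3"),
    error = function(e) stop("malformed annotation file '", path, "': ",
                             conditionMessage(e))
  )
  md <- as.data.frame(gr)
  name <- md$Name
  if (is.null(name)) name <- md$name
  if (is.null(name)) name <- md$gene_id
  if (is.null(name)) name <- md$ID
  if (is.null(name)) name <- paste0("feature", seq_len(nrow(md)))
  name <- ifelse(is.na(name) | name == "",
                 if (!is.null(md$ID)) md$ID else paste0("feature", seq_len(nrow(md))),
                 name)
  data.frame(chrom = as.character(md$seqnames), start = md$start,
             end = md$end, gene = as.character(name), stringsAsFactors = FALSE)
}

# fallback plain-text interval reader (BED 0-based half-open; GFF3 1-based)
read_gene_intervals_base <- function(path, ext) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  if (ext == "bed") {
    bad <- which(vapply(parts, length, integer(1)) < 3)
    if (length(bad)) stop("malformed annotation line ", bad[1], " in ", path)
    data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.integer(vapply(parts, `[`, "", 2)) + 1L,
      end = as.integer(vapply(parts, `[`, "", 3)),
      gene = vapply(parts, function(x) if (length(x) >= 4) x[4] else ".", ""),
      stringsAsFactors = FALSE)
  } else {
    bad <- which(vapply(parts, length, integer(1)) < 9)
    if (length(bad)) stop("malformed annotation line ", bad[1], " in ", path)
    attr9 <- vapply(parts, `[`, "", 9)
    name <- sub(".*Name=([^;]+).*", "\\1", attr9)
    noname <- !grepl("Name=", attr9)
    name[noname] <- sub(".*ID=([^;]+).*", "\\1", attr9[noname])
    data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.integer(vapply(parts, `[`, "", 4)),
      end = as.integer(vapply(parts, `[`, "", 5)),
      gene = name, stringsAsFactors = FALSE)
  }
}

#' Scan diagnostics bundle
#'
#' Genomic inflation, test count, Bonferroni threshold and QQ coordinates
#' for a finished scan.
#'
#' @param scan an [assoc_scan()].
#' @param alpha family-wise level, default 0.05.
#' @return list of class `scan_diagnostics`.
#' @export
scan_diagnostics <- function(scan, alpha = 0.05) {
  p <- scan$p[scan$flag == "" & !is.na(scan$p)]
  out <- list(model = attr(scan, "model"),
              n_tests = length(p),
              lambda_gc = genomic_lambda(p),
              bonferroni_alpha = bonferroni_threshold(alpha, length(p)),
              qq = qq_points(p))
  class(out) <- "scan_diagnostics"
  out
}

#' @export
print.scan_diagnostics <- function(x, ...) {
  cat(sprintf("%s: %d tests, lambda = %.3f, Bonferroni p < %.3g\n",
              x$model, x$n_tests, x$lambda_gc,
              format_threshold(x$bonferroni_alpha)))
  invisible(x)
}
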
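#' Association result table
#'
#' Universal scan output: one row per test unit (SNP or haplotype window)
#' with effect, standard error, test statistic, p-value and a flag column
#' (`""` or `"degenerate"` for collinear/constant units, which are kept so
#' that the output row count is predictable). Rows are sorted by
#' (chrom, pos).
#'
#' @param df data.frame with at least `chrom`, `pos`, `beta`, `se`, `stat`,
#'   `p`, `flag`.
#' @param model model tag (`"lmm"`, `"binary"`, `"haplotype"`, `"wls"`).
#' @param covariates character description of the covariate set.
#' @return data.frame of class `assoc_scan`.
#' @export
assoc_scan <- function(df, model, covariates = "") {
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  bad <- !is.na(df$p) & (df$p < 0 | df$p > 1)
  if (any(bad)) stop("p-values outside (0, 1]")
  # extreme statistics can underflow pf/pt to exactly 0; keep p in (0, 1]
  zero <- !is.na(df$p) & df$p == 0
  df$p[zero] <- .Machine$double.xmin
  attr(df, "model") <- model
  attr(df, "covariates") <- covariates
  class(df) <- c("assoc_scan", "data.frame")
  df
}

#' @export
print.assoc_scan <- function(x, ...) {
  covs <- attr(x, "covariates")
  cat("assoc_scan [", attr(x, "model") %||% "?", "]: ", nrow(x), " tests",
      if (!is.null(covs) && nzchar(covs))
        paste0(" | covariates: ", covs), "\n", sep = "")
  top <- x[order(x$p), ][seq_len(min(5, nrow(x))), ]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.assoc_scan <- function(object, alpha = 0.05, ...) {
  p <- object$p[object$flag == ""]
  n <- length(p)
  thr <- bonferroni_threshold(alpha, n)
  out <- list(model = attr(object, "model"), n_tests = n,
              lambda_gc = genomic_lambda(p),
              bonferroni = thr,
              n_significant = sum(p < thr),
              n_degenerate = sum(object$flag != ""))
  class(out) <- "summary.assoc_scan"
  out
}

#' @export
print.summary.assoc_scan <- function(x, ...) {
  cat("model: ", x$model, "\n", sep = "")
  cat("tests: ", x$n_tests, " (", x$n_degenerate, " degenerate)\n", sep = "")
  cat(sprintf("genomic inflation lambda: %.3f\n", x$lambda_gc))
  cat(sprintf("Bonferroni threshold: %.3g; significant: %d\n",
              format_threshold(x$bonferroni), x$n_significant))
  invisible(x)
}

#' Manhattan / QQ plots for a scan
#'
#' @param x an `assoc_scan`.
#' @param type `"manhattan"` or `"qq"`.
#' @param alpha family-wise level for the Bonferroni line.
#' @param ... passed to the underlying plot call.
#' @export
plot.assoc_scan <- function(x, type = c("manhattan", "qq"), alpha = 0.05, ...) {
  type <- match.arg(type)
  ok <- x$flag == "" & !is.na(x$p)
  if (type == "qq") {
    qq <- qq_points(x$p[ok])
    graphics::plot(qq$expected, qq$observed,
                   xlab = expression(Expected ~ -log[10](p)),
                   ylab = expression(Observed ~ -log[10](p)),
                   pch = 20, ...)
    graphics::abline(0, 1, col = "grey50")
  } else {
    mt <- manhattan_table(x[ok, , drop = FALSE])
    chrom_f <- factor(mt$chrom, levels = unique(mt$chrom))
    graphics::plot(mt$cum_pos, -log10(mt$p), col = (as.integer(chrom_f) %% 2) + 1,
                   pch = 20, xlab = "genome position", xaxt = "n",
                   ylab = expression(-log[10](p)), ...)
    thr <- bonferroni_threshold(alpha, sum(ok))
    graphics::abline(h = -log10(thr), col = "red", lty = 2)
  }
  invisible(x)
}

#' Write a scan as TSV
#' @param x an `assoc_scan`.
#' @param path output path.
#' @export
write_scan <- function(x, path) {
  df <- as.data.frame(x)
  df$model <- attr(x, "model")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
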
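#' Centered genomic relatedness matrix
#'
#' `K = (1/p) * sum_s (g_s - mean(g_s)) (g_s - mean(g_s))'` over the p sites,
#' i.e. the centered (not standardised) genomic relationship matrix used by
#' mixed-model association tools. Missing dosages are mean-imputed per site
#' first (count reported); monomorphic sites contribute zero and are counted.
#'
#' @param gm a [genotype_matrix()] or a plain samples x sites numeric matrix.
#' @param standardized divide each centered site by its standard deviation
#'   before averaging (variant offered behind a flag; default `FALSE`).
#' @return object of class `grm`: list with `K`, `n_sites_used`,
#'   `n_monomorphic`, `n_imputed`.
#' @export
centered_grm <- function(gm, standardized = FALSE) {
  if (inherits(gm, "genotype_matrix")) {
    imp <- impute_dosages(gm)
    X <- imp$mat
    n_imputed <- imp$n_imputed
  } else {
    X <- as.matrix(gm)
    n_imputed <- sum(is.na(X))
    if (n_imputed > 0) {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
  }
  p <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  mono <- sdv == 0
  if (all(mono)) stop("zero polymorphic sites: cannot build a relatedness matrix")
  Xc <- sweep(X, 2, mu)
  if (standardized) {
    Xc[, !mono] <- sweep(Xc[, !mono, drop = FALSE], 2, sdv[!mono], `/`)
  }
  K <- tcrossprod(Xc) / p
  K <- (K + t(K)) / 2
  structure(list(K = K, n_sites_used = p, n_monomorphic = sum(mono),
                 n_imputed = n_imputed),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("centered GRM: ", nrow(x$K), " samples, ", x$n_sites_used, " sites (",
      x$n_monomorphic, " monomorphic, ", x$n_imputed, " imputed calls)\n",
      sep = "")
  invisible(x)
}

#' Eigendecomposition of a relatedness matrix
#'
#' Full symmetric eigendecomposition with eigenvalues in nonincreasing order.
#' Small numerical negatives (above -1e-10) are clamped to zero and counted.
#'
#' @param K a `grm` object or symmetric numeric matrix.
#' @return object of class `structure_basis`: list with `values`, `vectors`,
#'   `n_clamped`, `k_selected` (initially `NA`).
#' @export
grm_eigen <- function(K) {
  if (inherits(K, "grm")) K <- K$K
  if (!all(is.finite(K))) stop("non-finite entries in relatedness matrix")
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("relatedness matrix not symmetric")
  e <- eigen(K, symmetric = TRUE)
  neg <- e$values < 0 & e$values > -1e-10
  e$values[neg] <- 0
  structure(list(values = e$values, vectors = e$vectors,
                 n_clamped = sum(neg), k_selected = NA_integer_),
            class = "structure_basis")
}

#' @export
print.structure_basis <- function(x, ...) {
  cat("structure basis: ", length(x$values), " eigenvalues, top 5: ",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n",
      sep = "")
  if (!is.na(x$k_selected)) cat("  k selected: ", x$k_selected, "\n", sep = "")
  invisible(x)
}

#' Scree-based choice of the number of eigenvector covariates
#'
#' Operational elbow rule: the selected k is the position maximising the
#' second difference of the eigenvalue sequence over positions `2..k_max`
#' (the sharpest bend of the scree curve). When the second differences
#' decrease monotonically (no distinct elbow, e.g. geometric decay) the
#' smallest admissible k is returned with a low-confidence flag. A manual
#' `override` always wins and is recorded.
#'
#' @param eigenvalues nonincreasing numeric sequence (>= 3 values).
#' @param k_max largest k considered; default `min(10, length - 1)`.
#' @param override optional integer forcing the selection.
#' @return list with `k`, `low_confidence`, `overridden`.
#' @export
scree_select <- function(eigenvalues, k_max = NULL, override = NULL) {
  lam <- as.numeric(eigenvalues)
  if (length(lam) < 3) stop("need at least 3 eigenvalues")
  if (is.null(k_max)) k_max <- min(10L, length(lam) - 1L)
  k_max <- min(k_max, length(lam) - 1L)
  if (!is.null(override)) {
    return(list(k = as.integer(override), low_confidence = FALSE,
                overridden = TRUE))
  }
  ks <- 2:k_max
  d2 <- lam[ks - 1] - 2 * lam[ks] + lam[ks + 1]
  k <- ks[which.max(d2)]
  low <- k == 2 && length(d2) > 1 && all(diff(d2) < 0)
  list(k = as.integer(k), low_confidence = low, overridden = FALSE)
}

#' Write / read a GRM as TSV
#' @param grm a `grm` object.
#' @param path output path.
#' @export
write_grm <- function(grm, path) {
  utils::write.table(grm$K, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
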
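# ---- restricted-likelihood machinery -------------------------------------
#
# Model: y = W a + x b + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I).
# With K = U D U' everything is rotated by U once, after which the covariance
# is diagonal, V = r D + I (r = sg2/se2), and every evaluation is O(n).

as_K <- function(K) if (inherits(K, "grm")) K$K else as.matrix(K)

# restricted log-likelihood (profiled over se2) at fixed r, rotated data
reml_eval <- function(ys, Xs, dvals, r) {
  v <- r * dvals + 1
  Xv <- Xs / v
  A <- crossprod(Xs, Xv)
  b <- crossprod(Xv, ys)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(ok = FALSE, loglik = -Inf))
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2 / v)
  n <- length(ys); c <- ncol(Xs)
  nc <- n - c
  se2 <- rss / nc
  ll <- -0.5 * (nc * log(2 * pi * se2) + nc + sum(log(v)) +
                  2 * sum(log(diag(R))))
  list(ok = TRUE, loglik = ll, beta = drop(beta), rss = rss, se2 = se2,
       chol = R, v = v)
}

# profile the restricted likelihood over r on a log grid spanning
# [1e-5, 1e5], then golden-section refinement to 1e-6 relative tolerance
reml_optimize <- function(ys, Xs, dvals, grid_pts = 41) {
  lg <- seq(-5, 5, length.out = grid_pts)
  ll <- vapply(lg, function(g) reml_eval(ys, Xs, dvals, 10^g)$loglik,
               numeric(1))
  i <- which.max(ll)
  converged <- TRUE
  if (i == 1 || i == grid_pts) {
    converged <- FALSE
    lo <- lg[max(i - 1, 1)]; hi <- lg[min(i + 1, grid_pts)]
  } else {
    lo <- lg[i - 1]; hi <- lg[i + 1]
  }
  # golden-section on log10(r)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- reml_eval(ys, Xs, dvals, 10^x1)$loglik
  f2 <- reml_eval(ys, Xs, dvals, 10^x2)$loglik
  while (abs(b - a) > 1e-6 / log(10)) {  # ~1e-6 relative in r
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- reml_eval(ys, Xs, dvals, 10^x2)$loglik
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- reml_eval(ys, Xs, dvals, 10^x1)$loglik
    }
  }
  r <- 10^((a + b) / 2)
  fit <- reml_eval(ys, Xs, dvals, r)
  list(r = r, fit = fit, converged = converged)
}

#' Restricted-likelihood variance-ratio fit
#'
#' Fits the null mixed model `y = W a + u + e` with `u ~ N(0, sg2 K)` and
#' `e ~ N(0, se2 I)` by restricted maximum likelihood, profiling the
#' variance ratio `r = sg2/se2` on a log grid over `[1e-5, 1e5]` with
#' golden-section refinement. The relatedness matrix is eigendecomposed once;
#' each likelihood evaluation is O(n) after rotation.
#'
#' @param y numeric phenotype vector.
#' @param W covariate matrix including the intercept (default: intercept only).
#' @param K relatedness matrix (a `grm` or plain symmetric matrix).
#' @param eig optional precomputed [grm_eigen()] basis of `K`.
#' @return object of class `lmm_fit`: variance ratio `r`, components
#'   `sigma_g2`, `sigma_e2`, restricted log-likelihood `loglik`, covariate
#'   effects `alpha`, convergence flag, and the eigen basis for reuse.
#' @export
reml_variance_ratio <- function(y, W = NULL, K = NULL, eig = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  W <- as.matrix(W)
  if (n <= ncol(W) + 2) stop("too few samples for the covariate set")
  if (is.null(eig)) eig <- grm_eigen(as_K(K))
  dvals <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  opt <- reml_optimize(ys, Ws, dvals)
  if (!opt$fit$ok) stop("covariate matrix is rank deficient")
  if (!opt$converged)
    warning("variance-ratio refinement hit the search boundary; returning boundary value")
  fit <- opt$fit
  structure(list(r = opt$r, sigma_e2 = fit$se2, sigma_g2 = opt$r * fit$se2,
                 loglik = fit$loglik,
                 alpha = stats::setNames(fit$beta, colnames(W)),
                 converged = opt$converged, n = n, n_covar = ncol(W),
                 eig = eig),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("mixed-model REML fit\n")
  cat(sprintf("  variance ratio r = sg2/se2: %.4g%s\n", x$r,
              if (!x$converged) " (boundary)" else ""))
  cat(sprintf("  sigma_g2: %.4g   sigma_e2: %.4g\n", x$sigma_g2, x$sigma_e2))
  cat(sprintf("  restricted log-likelihood: %.4f (n = %d)\n", x$loglik, x$n))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$alpha

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_covar + 2, class = "logLik")
}

#' Restricted log-likelihood at a fixed variance ratio
#'
#' Exposed for diagnostics and for validating the rotated O(n) evaluation
#' against a dense evaluation of the same objective.
#'
#' @inheritParams reml_variance_ratio
#' @param r fixed variance ratio `sg2/se2`.
#' @return the restricted log-likelihood (profiled over the error variance).
#' @export
reml_loglik <- function(y, W, K, r, eig = NULL) {
  if (is.null(eig)) eig <- grm_eigen(as_K(K))
  U <- eig$vectors
  reml_eval(drop(crossprod(U, y)), crossprod(U, as.matrix(W)),
            pmax(eig$values, 0), r)$loglik
}

#' Mixed-model association scan
#'
#' Per-SNP generalised least squares given the variance ratio, Wald statistic
#' `(beta/se)^2` referred to `F(1, n - c - 1)` where c is the number of
#' covariates. By default the variance ratio is re-optimised for every SNP;
#' with `per_snp_r = FALSE` the null-model ratio is reused for every SNP
#' (the fast approximation commonly used at genome scale — accurate when
#' individual SNP effects are small). Missing dosages are mean-imputed per
#' site. SNPs collinear with the covariates (or constant) are kept as
#' degenerate rows with `p = 1`.
#'
#' @param gm a [genotype_matrix()].
#' @param y numeric per-sample phenotype (e.g. a broadcast breed prevalence,
#'   see [broadcast_phenotype()]).
#' @param covars covariate matrix including intercept; default intercept +
#'   sex (female 0, male 1, unknown mean-imputed).
#' @param K relatedness matrix (`grm` or matrix); ignored if `eig` given.
#' @param per_snp_r re-optimise the variance ratio per SNP (default `TRUE`).
#' @param eig optional precomputed [grm_eigen()] of `K`.
#' @return an [assoc_scan()] with attributes `null_fit` (the `lmm_fit`) and
#'   `model = "lmm"`.
#' @export
lmm_scan <- function(gm, y, covars = NULL, K = NULL, per_snp_r = TRUE,
                     eig = NULL) {
  y <- as.numeric(y)
  n <- n_samples(gm)
  if (length(y) != n) stop("phenotype not aligned to samples")
  if (anyNA(y)) stop("missing phenotype values; subset the cohort first")
  if (is.null(covars)) {
    sx <- sex_covariate(gm$samples)
    covars <- if (length(unique(sx)) > 1) {
      cbind(intercept = 1, sex = sx)
    } else {
      matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    }
  }
  W <- as.matrix(covars)
  c_w <- ncol(W)
  if (is.null(eig)) eig <- grm_eigen(as_K(K))
  dvals <- pmax(eig$values, 0)
  U <- eig$vectors

  G <- impute_dosages(gm)$mat
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  Gs <- crossprod(U, G)

  null_fit <- reml_variance_ratio(y, W, eig = eig)
  df2 <- n - c_w - 1
  p_snp <- ncol(G)

  beta <- se <- stat <- rep(NA_real_, p_snp)
  pval <- rep(1, p_snp)
  flag <- rep("", p_snp)
  r_used <- rep(null_fit$r, p_snp)

  if (!per_snp_r) {
    v <- null_fit$r * dvals + 1
    sw <- 1 / sqrt(v)
    qrX <- qr(Ws * sw)
    ry <- qr.resid(qrX, ys * sw)
    rG <- qr.resid(qrX, Gs * sw)
    sxx <- colSums(rG^2)
    scale0 <- pmax(colSums((Gs * sw)^2), .Machine$double.eps)
    degen <- sxx / scale0 < 1e-10
    sxy <- colSums(rG * ry)
    b <- sxy / sxx
    rss <- pmax(sum(ry^2) - b^2 * sxx, 0)
    s2 <- rss / df2
    ok <- !degen & s2 > 0
    beta[ok] <- b[ok]
    se[ok] <- sqrt(s2[ok] / sxx[ok])
    stat[ok] <- (beta[ok] / se[ok])^2
    pval[ok] <- stats::pf(stat[ok], 1, df2, lower.tail = FALSE)
    flag[degen] <- "degenerate"
    flag[!degen & !ok] <- "degenerate"
  } else {
    for (j in seq_len(p_snp)) {
      xs <- Gs[, j]
      Xs <- cbind(Ws, xs)
      qr0 <- qr(Xs)
      if (qr0$rank < ncol(Xs)) { flag[j] <- "degenerate"; next }
      opt <- reml_optimize(ys, Xs, dvals, grid_pts = 21)
      fit <- opt$fit
      r_used[j] <- opt$r
      # se of the SNP coefficient: (A^-1)_kk for the last column is 1/R_kk^2
      var_unscaled <- 1 / fit$chol[c_w + 1, c_w + 1]^2
      s2 <- fit$rss / df2
      if (!is.finite(s2) || s2 <= 0 || var_unscaled <= 0) {
        flag[j] <- "degenerate"; next
      }
      beta[j] <- fit$beta[c_w + 1]
      se[j] <- sqrt(s2 * var_unscaled)
      stat[j] <- (beta[j] / se[j])^2
      pval[j] <- stats::pf(stat[j], 1, df2, lower.tail = FALSE)
    }
  }

  v <- gm$variants
  res <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref,
                    alt = v$alt, beta = beta, se = se, stat = stat, p = pval,
                    flag = flag, stringsAsFactors = FALSE)
  out <- assoc_scan(res, model = "lmm",
                    covariates = paste(colnames(W), collapse = "+"))
  attr(out, "null_fit") <- null_fit
  attr(out, "per_snp_r") <- per_snp_r
  out
}

#' Dichotomise breed prevalences into cases and controls
#'
#' Breeds strongly protected from the trait (prevalence at or below
#' `low_cut`) become controls (0); breeds strongly predisposed (prevalence at
#' or above `high_cut`) become cases (1); intermediate breeds are excluded.
#' Cut points above 1 are interpreted as percentages.
#'
#' @param panel a [breed_panel()].
#' @param disease prevalence column name.
#' @param low_cut,high_cut prevalence cut points, `low_cut < high_cut`.
#' @param meta data.frame with `sample_id` and `breed` for per-sample labels.
#' @return list with `labels` (named per-sample 0/1 vector, NA = excluded),
#'   `case_breeds`, `control_breeds`, `excluded_breeds`.
#' @export
assign_binary_phenotype <- function(panel, disease, low_cut, high_cut, meta) {
  if (low_cut >= high_cut) stop("low_cut must be below high_cut")
  if (low_cut > 1) low_cut <- low_cut / 100
  if (high_cut > 1) high_cut <- high_cut / 100
  prev <- panel[[disease]]
  if (is.null(prev)) stop("unknown disease column: ", disease)
  grp <- ifelse(is.na(prev), NA,
                ifelse(prev <= low_cut, 0, ifelse(prev >= high_cut, 1, NA)))
  ctrl <- panel$breed[!is.na(grp) & grp == 0]
  case <- panel$breed[!is.na(grp) & grp == 1]
  if (length(ctrl) == 0 || length(case) == 0) {
    pv <- sort(prev[!is.na(prev)])
    stop("empty ", if (length(ctrl) == 0) "control" else "case",
         " group; nearest feasible cuts: low >= ", signif(min(pv), 3),
         ", high <= ", signif(max(pv), 3))
  }
  labels <- grp[match(meta$breed, panel$breed)]
  names(labels) <- meta$sample_id
  list(labels = labels, case_breeds = case, control_breeds = ctrl,
       excluded_breeds = setdiff(panel$breed[!is.na(prev)], c(case, ctrl)))
}

#' Binary case-control mixed-model scan
#'
#' The 0/1 phenotype is analysed with exactly the machinery of [lmm_scan()]
#' (the linear approximation to the liability model, accurate for small SNP
#' effects). Samples with `NA` labels (excluded breeds) are dropped here,
#' along with the matching rows/columns of the relatedness matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param labels per-sample 0/1 labels (NA = excluded), as from
#'   [assign_binary_phenotype()].
#' @param covars optional covariate matrix (default intercept + sex, built
#'   after subsetting).
#' @param K relatedness matrix over the full cohort.
#' @param ... passed to [lmm_scan()] (e.g. `per_snp_r`).
#' @return an [assoc_scan()] with model tag `"binary"`.
#' @export
binary_casecontrol_scan <- function(gm, labels, covars = NULL, K, ...) {
  if (length(labels) != n_samples(gm)) stop("labels not aligned to samples")
  keep <- !is.na(labels)
  lab <- labels[keep]
  if (!all(lab %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(lab)) < 2) stop("no contrast: all labels identical")
  gm2 <- gm_subset(gm, samples = keep)
  Ksub <- as_K(K)[keep, keep, drop = FALSE]
  if (!is.null(covars)) covars <- as.matrix(covars)[keep, , drop = FALSE]
  out <- lmm_scan(gm2, as.numeric(lab), covars = covars, K = Ksub, ...)
  attr(out, "model") <- "binary"
  out
}
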
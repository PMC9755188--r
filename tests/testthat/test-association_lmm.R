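test_that("rotated restricted likelihood equals the dense evaluation", {
  set.seed(15)
  n <- 14
  K <- tcrossprod(scale(matrix(rnorm(n * 40), n, 40), scale = FALSE)) / 40
  y <- rnorm(n)
  W <- cbind(1, rbinom(n, 1, 0.5))
  for (r in c(1e-3, 0.1, 1, 10, 1e3)) {
    expect_equal(reml_loglik(y, W, K, r), dense_reml_oracle(y, W, K, r),
                 tolerance = 1e-10)
  }
})

test_that("the variance ratio is near zero when there is no genetic effect", {
  # strongly structured relatedness keeps the ratio well identified, so the
  # null REML estimate concentrates at the zero boundary
  hits <- 0
  for (rep in 1:30) {
    cfg <- sim_config(n_breeds = 4, n_samples = 300,
                      size_range = c(75, 75), n_clades = 2, n_snps = 400,
                      fst = 0.5, missingness = 0)
    st <- generate_study(cfg, seed = 2000 + rep)
    K <- centered_grm(st$gm)$K
    set.seed(rep)
    y <- rnorm(300)  # individual-level noise: no genetic effect
    fit <- suppressWarnings(reml_variance_ratio(y, matrix(1, 300, 1), K))
    if (fit$r < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})

test_that("a zero relatedness matrix reduces the fit to ordinary least squares", {
  set.seed(5)
  n <- 20
  gm <- random_gm(n, 15, seed = 5)
  y <- rnorm(n)
  W <- cbind(intercept = rep(1, n))
  sc <- suppressWarnings(lmm_scan(gm, y, covars = W, K = matrix(0, n, n),
                                  per_snp_r = FALSE))
  for (j in c(1, 7, 15)) {
    f <- summary(lm(y ~ gm$dosages[, j]))
    expect_equal(sc$beta[j], f$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(sc$p[j], f$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("per-SNP GLS matches the dense oracle at the null variance ratio", {
  set.seed(12)
  n <- 12
  gm <- random_gm(n, 8, seed = 3)
  K <- tcrossprod(scale(matrix(rnorm(n * 30), n, 30), scale = FALSE)) / 30
  y <- rnorm(n)
  W <- cbind(1, rbinom(n, 1, 0.5))
  sc <- suppressWarnings(lmm_scan(gm, y, covars = W, K = K, per_snp_r = FALSE))
  r0 <- attr(sc, "null_fit")$r
  for (j in seq_len(8)) {
    o <- dense_gls_oracle(y, W, gm$dosages[, j], K, r0)
    expect_equal(sc$beta[j], o$beta, tolerance = 1e-8)
    expect_equal(sc$se[j], o$se, tolerance = 1e-8)
    expect_equal(sc$p[j], o$p, tolerance = 1e-8)
  }
})

test_that("per-SNP variance-ratio re-optimisation matches a direct search", {
  set.seed(31)
  n <- 25
  gm <- random_gm(n, 4, seed = 31)
  K <- centered_grm(random_gm(n, 100, seed = 32))$K
  y <- 0.5 * gm$dosages[, 2] + rnorm(n)
  W <- cbind(rep(1, n))
  sc <- suppressWarnings(lmm_scan(gm, y, covars = W, K = K, per_snp_r = TRUE))
  for (j in c(1, 2)) {
    x <- gm$dosages[, j]
    f <- function(lr) reml_loglik(y, cbind(W, x), K, 10^lr)
    lr_hat <- optimize(f, c(-5, 5), maximum = TRUE, tol = 1e-8)$maximum
    o <- dense_gls_oracle(y, W, x, K, 10^lr_hat)
    expect_equal(sc$beta[j], o$beta, tolerance = 1e-4)
    expect_equal(sc$p[j], o$p, tolerance = 1e-4)
  }
})

test_that("SNPs collinear with covariates become degenerate rows, not drops", {
  n <- 16
  set.seed(2)
  d <- cbind(rep(1, n), rbinom(n, 2, 0.5))  # first SNP constant
  gm <- make_gm(d)
  y <- rnorm(n)
  sc <- suppressWarnings(lmm_scan(gm, y, K = diag(0, n), per_snp_r = FALSE))
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$flag[1], "degenerate")
  expect_equal(sc$p[1], 1)
  scp <- suppressWarnings(lmm_scan(gm, y, K = diag(0, n), per_snp_r = TRUE))
  expect_equal(scp$flag[1], "degenerate")
})

test_that("breed prevalences dichotomise into cases and controls correctly", {
  panel <- breed_panel(c("low1", "low2", "mid", "high1", "high2"),
                       n = c(4, 3, 5, 2, 6),
                       prevalence = data.frame(hd = c(1.5, 2, 8, 15, 22)))
  meta <- data.frame(sample_id = paste0("s", 1:5),
                     breed = c("low1", "low2", "mid", "high1", "high2"))
  bp <- assign_binary_phenotype(panel, "hd", 0.02, 0.15, meta)
  expect_equal(bp$control_breeds, c("low1", "low2"))
  expect_equal(bp$case_breeds, c("high1", "high2"))
  expect_equal(bp$excluded_breeds, "mid")
  expect_equal(unname(bp$labels), c(0, 0, NA, 1, 1))
  expect_error(assign_binary_phenotype(panel, "hd", 0.2, 0.1, meta), "below")
  # stringent cuts select a subset of the lenient selection
  len <- assign_binary_phenotype(panel, "hd", 0.05, 0.10, meta)
  str <- assign_binary_phenotype(panel, "hd", 0.02, 0.20, meta)
  expect_true(all(c(str$case_breeds, str$control_breeds) %in%
                    c(len$case_breeds, len$control_breeds)))
  # nearest feasible cuts are reported when a group is empty
  expect_error(assign_binary_phenotype(panel, "hd", 0.001, 0.15, meta),
               "nearest feasible")
})

test_that("the binary scan shares machinery with the quantitative scan", {
  cfg <- sim_config(n_breeds = 6, n_samples = 48, size_range = c(8, 8),
                    n_snps = 60, fst = 0.25, missingness = 0)
  st <- generate_study(cfg, seed = 41)
  K <- centered_grm(st$gm)$K
  labels <- setNames(rep(c(0, 1), each = 24), st$gm$samples$sample_id)
  b <- suppressWarnings(binary_casecontrol_scan(st$gm, labels, K = K,
                                                per_snp_r = FALSE))
  q <- suppressWarnings(lmm_scan(st$gm, as.numeric(labels), K = K,
                                 per_snp_r = FALSE))
  expect_equal(b$p, q$p, tolerance = 1e-12)
  expect_equal(b$beta, q$beta, tolerance = 1e-12)
  expect_error(binary_casecontrol_scan(st$gm, labels * 0, K = K),
               "no contrast")
})

test_that("a variant fixed in cases' breeds and absent in controls' tops the scan", {
  cfg <- sim_config(n_breeds = 6, n_samples = 48, size_range = c(8, 8),
                    n_snps = 40, fst = 0.25, missingness = 0)
  st <- generate_study(cfg, seed = 6)
  gm <- st$gm
  labels <- ifelse(gm$samples$breed %in% c("breed01", "breed02", "breed03"),
                   1, 0)
  gm$dosages[, 17] <- labels * 2  # fixed in case breeds, absent in controls
  K <- centered_grm(gm)$K
  sc <- suppressWarnings(binary_casecontrol_scan(gm, labels, K = K,
                                                 per_snp_r = TRUE))
  expect_equal(which.min(sc$p), 17L)
})
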
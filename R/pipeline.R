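#' Validate and normalise a study configuration
#'
#' Fills defaults (quality floor 20, MAF 0.05, call rates 0.90/0.99, window
#' 4, 5 principal components, alpha 0.05, 500 kb region gap) and collects
#' *all* problems rather than stopping at the first.
#'
#' @param cfg named list: `vcf`, `phenotype`, `meta` (paths), `models`
#'   (subset of `"lmm"`, `"binary"`, `"haplotype"`, `"wls"`), `disease`
#'   (phenotype column), optional `genes` annotation path, thresholds, and
#'   `out_dir`.
#' @return list with `config` (normalised) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(cfg) {
  defaults <- list(min_qual = 20, min_maf = 0.05,
                   min_sample_call_rate = 0.90, min_site_call_rate = 0.99,
                   window = 4, n_pcs = 5, n_eigenvectors = NULL,
                   alpha = 0.05, max_gap = 500000,
                   low_cut = 0.02, high_cut = 0.10,
                   models = c("lmm", "binary", "haplotype", "wls"),
                   do_breed_verify = FALSE, n_boot = 100,
                   per_snp_r = FALSE, seed = 1,
                   genes = NULL, out_dir = NULL,
                   vcf = NULL, phenotype = NULL, meta = NULL,
                   disease = NULL)
  errors <- character(0)
  unknown <- setdiff(names(cfg), names(defaults))
  for (k in unknown) errors <- c(errors, paste0("unknown key: ", k))
  full <- utils::modifyList(defaults, cfg[setdiff(names(cfg), unknown)])

  if (is.null(full$models) || !length(full$models))
    errors <- c(errors, "no models selected")
  bad_m <- setdiff(full$models, c("lmm", "binary", "haplotype", "wls"))
  if (length(bad_m))
    errors <- c(errors, paste0("unknown model: ", paste(bad_m, collapse = ", ")))
  for (f in c("vcf", "phenotype", "meta")) {
    if (is.null(full[[f]])) errors <- c(errors, paste0("missing input: ", f))
    else if (!file.exists(full[[f]]))
      errors <- c(errors, paste0("file not found: ", full[[f]]))
  }
  if (!is.null(full$genes) && !file.exists(full$genes))
    errors <- c(errors, paste0("file not found: ", full$genes))
  if (is.null(full$disease)) errors <- c(errors, "missing disease column name")
  if (full$low_cut >= full$high_cut)
    errors <- c(errors, "low_cut must be below high_cut")
  list(config = full, errors = errors)
}

#' Run the full across-breed GWAS workflow
#'
#' Stages run in order: QC summaries, optional breed verification, site
#' quality filtering, genotype-level QC, relatedness/eigenvectors, the
#' selected scans, and summarisation (diagnostics, region collapsing,
#' annotation). Each stage failure halts with a stage-named error. A run
#' manifest (thresholds, seed, per-stage counts, output checksums) is
#' written alongside the result tables when `out_dir` is set.
#'
#' @param cfg a configuration list; validated via [validate_config()].
#' @return list with `ledgers`, `scans`, `diagnostics`, `regions`,
#'   `manifest` (and `flags` when breed verification ran).
#' @export
run_study <- function(cfg) {
  val <- validate_config(cfg)
  if (length(val$errors))
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "))
  cfg <- val$config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  meta <- stage("read_meta", utils::read.table(cfg$meta, header = TRUE,
                                               sep = "\t",
                                               stringsAsFactors = FALSE))
  panel <- stage("read_phenotype", read_breed_panel(cfg$phenotype))
  gm <- stage("read_vcf", read_vcf(cfg$vcf, meta = meta))
  qc <- stage("qc_summaries", qc_summaries(gm))

  flags <- NULL
  if (isTRUE(cfg$do_breed_verify)) {
    vb <- stage("breed_verify",
                verify_breeds(gm, n_boot = cfg$n_boot, seed = cfg$seed))
    flags <- vb$flags
    if (nrow(flags))
      gm <- gm_subset(gm, samples = !(gm$samples$sample_id %in% flags$sample_id))
  }

  sq <- stage("filter_site_quality", filter_site_quality(gm, cfg$min_qual))
  gq <- stage("filter_genotype_qc",
              filter_genotype_qc(sq$gm,
                                 min_sample_call_rate = cfg$min_sample_call_rate,
                                 min_site_call_rate = cfg$min_site_call_rate,
                                 min_maf = cfg$min_maf))
  gmf <- gq$gm

  grm <- stage("grm", centered_grm(gmf))
  eig <- stage("eigen", grm_eigen(grm))

  y <- stage("phenotype_broadcast",
             broadcast_phenotype(panel, gmf$samples, cfg$disease))
  keep <- !is.na(y)
  if (!all(keep)) {
    gmf <- gm_subset(gmf, samples = keep)
    grm <- centered_grm(gmf)
    eig <- grm_eigen(grm)
    y <- y[keep]
  }

  scans <- list()
  if ("lmm" %in% cfg$models)
    scans$lmm <- stage("scan_lmm",
                       lmm_scan(gmf, y, K = grm, eig = eig,
                                per_snp_r = cfg$per_snp_r))
  if ("binary" %in% cfg$models) {
    bp <- stage("binary_phenotype",
                assign_binary_phenotype(panel, cfg$disease, cfg$low_cut,
                                        cfg$high_cut, gmf$samples))
    scans$binary <- stage("scan_binary",
                          binary_casecontrol_scan(gmf, bp$labels, K = grm,
                                                  per_snp_r = cfg$per_snp_r))
  }
  if ("haplotype" %in% cfg$models) {
    k <- cfg$n_eigenvectors
    if (is.null(k)) k <- scree_select(eig$values)$k
    scans$haplotype <- stage("scan_haplotype",
                             haplotype_scan(gmf, y,
                                            pcs = eig$vectors[, seq_len(k),
                                                              drop = FALSE],
                                            window_size = cfg$window))
  }
  if ("wls" %in% cfg$models) {
    inputs <- stage("breed_average_dosage",
                    breed_average_dosage(gmf, panel, n_pcs = cfg$n_pcs))
    yb <- inputs$panel[[cfg$disease]][match(inputs$breeds, inputs$panel$breed)]
    ok <- !is.na(yb)
    if (!all(ok)) stop("stage 'scan_wls' failed: breeds without prevalence")
    scans$wls <- stage("scan_wls", wls_scan(inputs, yb, n_pcs = cfg$n_pcs))
  }

  diag_of <- function(s) {
    tab <- if (inherits(s, "hap_scan")) s$windows else s
    scan_diagnostics(tab, alpha = cfg$alpha)
  }
  diagnostics <- lapply(scans, diag_of)
  regions <- lapply(names(scans), function(m) {
    tab <- if (inherits(scans[[m]], "hap_scan")) scans[[m]]$windows else scans[[m]]
    thr <- bonferroni_threshold(cfg$alpha, sum(tab$flag == ""))
    r <- collapse_regions(tab, thr, max_gap = cfg$max_gap)
    if (!is.null(cfg$genes) && nrow(r)) r <- annotate_regions(r, cfg$genes)
    r
  })
  names(regions) <- names(scans)

  manifest <- list(
    package_version = as.character(utils::packageVersion("breedscan")),
    seed = cfg$seed,
    thresholds = cfg[c("min_qual", "min_maf", "min_sample_call_rate",
                       "min_site_call_rate", "window", "n_pcs", "alpha",
                       "max_gap", "low_cut", "high_cut")],
    models = cfg$models,
    counts = list(samples_in = nrow(meta),
                  variants_in = ledger_retained(sq$ledger) +
                    sum(sq$ledger$count[sq$ledger$type == "removed"]),
                  variants_after_quality = ledger_retained(sq$ledger),
                  variants_final = ledger_retained(gq$ledger),
                  samples_final = n_samples(gmf),
                  breed_flags = if (is.null(flags)) 0L else nrow(flags))
  )

  out <- list(qc = qc,
              ledgers = list(site_quality = sq$ledger,
                             genotype_qc = gq$ledger,
                             samples = gq$sample_ledger),
              scans = scans, diagnostics = diagnostics, regions = regions,
              flags = flags, manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ledger(sq$ledger, file.path(cfg$out_dir, "ledger_site_quality.tsv"))
    write_ledger(gq$ledger, file.path(cfg$out_dir, "ledger_genotype_qc.tsv"))
    for (m in names(scans)) {
      tab <- if (inherits(scans[[m]], "hap_scan")) scans[[m]]$windows else scans[[m]]
      write_scan(tab, file.path(cfg$out_dir, paste0("scan_", m, ".tsv")))
      utils::write.table(regions[[m]],
                         file.path(cfg$out_dir, paste0("regions_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    files <- list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
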
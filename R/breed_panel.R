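#' Breed phenotype panel
#'
#' One row per breed: per-disease prevalence and the number of genotyped
#' dogs. Prevalences supplied as percentages (any value above 1) are
#' normalised to fractions column-wise. Weights are the breed's share of the
#' whole sample population and always sum to one.
#'
#' @param breed character vector of breed names.
#' @param n integer vector of per-breed sample counts.
#' @param prevalence data.frame (or named list) of per-disease prevalences,
#'   one column per disease, rows aligned with `breed`.
#' @return data.frame of class `breed_panel` with columns `breed`, `n`,
#'   `weight` and one column per disease.
#' @export
breed_panel <- function(breed, n, prevalence) {
  prevalence <- as.data.frame(prevalence)
  stopifnot(length(breed) == length(n), nrow(prevalence) == length(breed))
  if (anyDuplicated(breed)) stop("duplicated breed names")
  if (any(n < 0)) stop("negative sample counts")
  for (j in seq_along(prevalence)) {
    x <- prevalence[[j]]
    if (any(x < 0 | x > 100, na.rm = TRUE))
      stop("prevalence outside [0, 100]% in column ", names(prevalence)[j])
    if (any(x > 1, na.rm = TRUE)) x <- x / 100
    prevalence[[j]] <- x
  }
  df <- data.frame(breed = as.character(breed), n = as.integer(n),
                   weight = n / sum(n), stringsAsFactors = FALSE)
  df <- cbind(df, prevalence)
  class(df) <- c("breed_panel", "data.frame")
  df
}

#' @export
print.breed_panel <- function(x, ...) {
  cat("breed_panel: ", nrow(x), " breeds, ", sum(x$n), " dogs, diseases: ",
      paste(setdiff(names(x), c("breed", "n", "weight")), collapse = ", "),
      "\n", sep = "")
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more breeds\n", sep = "")
  invisible(x)
}

#' Read a breed panel from TSV
#'
#' Expects columns `breed`, `n`, and one column per disease prevalence.
#'
#' @param path TSV path.
#' @return a [breed_panel()].
#' @export
read_breed_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("breed", "n") %in% names(df)))
    stop("breed panel needs 'breed' and 'n' columns")
  dis <- setdiff(names(df), c("breed", "n", "weight"))
  breed_panel(df$breed, df$n, df[, dis, drop = FALSE])
}

#' Broadcast a breed prevalence to individual samples
#'
#' Every dog carries its breed's prevalence as a quantitative phenotype (the
#' categorical-phenotype device at the heart of the across-breed scans).
#'
#' @param panel a [breed_panel()].
#' @param meta data.frame with `sample_id` and `breed`.
#' @param disease name of the prevalence column to broadcast.
#' @return named numeric vector of per-sample phenotype values (NA for breeds
#'   without a reported prevalence).
#' @export
broadcast_phenotype <- function(panel, meta, disease) {
  if (!disease %in% names(panel)) stop("unknown disease column: ", disease)
  y <- panel[[disease]][match(meta$breed, panel$breed)]
  names(y) <- meta$sample_id
  y
}
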
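#' Construct a genotype matrix
#'
#' The central genotype container: an additive dosage matrix (samples in rows,
#' variants in columns, values in \[0, 2\] or `NA`) plus per-variant metadata.
#' Dosages count copies of the variant's `a1` allele.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data.frame with one row per variant and at least columns
#'   `id`, `chrom`, `pos`, `a1` (the counted allele), `a2`. Optional columns
#'   `maf`, `call_rate`, `hwe_p`, `info` are filled with computed values or
#'   `NA` when absent.
#' @param dosages numeric matrix, `length(sample_ids)` rows by
#'   `nrow(variants)` columns; entries in \[0, 2\] or `NA`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `variants`, `dosages` (dimnames set to sample/variant ids).
#' @export
genotype_matrix <- function(sample_ids, variants, dosages) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(variants))
    stop("dosage matrix must be n_samples x n_variants")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in [0, 2] or be missing")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  dimnames(dosages) <- list(sample_ids, variants$id)
  for (col in c("maf", "call_rate", "hwe_p", "info"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  variants$call_rate <- colMeans(!is.na(dosages))
  af <- colMeans(dosages, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  rownames(variants) <- NULL
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants;",
      sum(is.na(x$dosages)), "missing dosages\n")
  invisible(x)
}

#' Subset a genotype matrix by sample and/or variant ids
#'
#' @param g a `genotype_matrix`.
#' @param samples,variants character vectors of ids to keep (default: all).
#' @return A `genotype_matrix` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_genotypes <- function(g, samples = g$sample_ids,
                             variants = g$variants$id) {
  si <- match(samples, g$sample_ids)
  vi <- match(variants, g$variants$id)
  if (anyNA(si)) stop("unknown sample ids: ",
                      paste(samples[is.na(si)], collapse = ", "))
  if (anyNA(vi)) stop("unknown variant ids: ",
                      paste(variants[is.na(vi)], collapse = ", "))
  genotype_matrix(g$sample_ids[si], g$variants[vi, , drop = FALSE],
                  g$dosages[si, vi, drop = FALSE])
}

# Hard-call dosages by rounding to the nearest integer copy number.
hard_calls <- function(dosages) {
  hc <- round(dosages)
  hc[hc < 0] <- 0
  hc[hc > 2] <- 2
  hc
}
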
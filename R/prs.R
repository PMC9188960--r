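.complement <- c(A = "T", C = "G", G = "C", T = "A")

comp_allele <- function(x) {
  out <- unname(.complement[x])
  out[is.na(out)] <- x[is.na(out)]  # symbolic alleles pass through
  out
}

#' Harmonise GWAS summary statistics with genotype alleles
#'
#' Matches variants by id and aligns the GWAS effect to the genotype's
#' counted allele: identical orientation keeps `beta`; swapped alleles flip
#' its sign; strand-complemented orientations are resolved by complementing
#' first. Palindromic variants (A/T, C/G) are excluded as strand-ambiguous,
#' as are id mismatches and allele mismatches.
#'
#' @param variants variant metadata data.frame (columns `id`, `a1`, `a2`)
#'   or a [genotype_matrix()].
#' @param stats summary-statistics data.frame from [read_summary_stats()].
#' @return data.frame of class `weight_table`: `id`, `counted_allele`,
#'   `weight` (log-odds per copy of the counted allele), `sign_flipped`, `p`;
#'   attribute `exclusions` itemises palindromic / unmatched / mismatched
#'   counts.
#' @export
harmonize_alleles <- function(variants, stats) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$variants
  v <- variants[, c("id", "a1", "a2")]
  idx <- match(v$id, stats$id)
  unmatched <- sum(is.na(idx))
  v <- v[!is.na(idx), , drop = FALSE]
  s <- stats[idx[!is.na(idx)], , drop = FALSE]

  pal <- toupper(v$a2) == comp_allele(toupper(v$a1))
  n_pal <- sum(pal)
  v <- v[!pal, , drop = FALSE]; s <- s[!pal, , drop = FALSE]

  a1 <- toupper(v$a1); a2 <- toupper(v$a2)
  ea <- toupper(s$effect_allele); oa <- toupper(s$other_allele)
  same <- a1 == ea & a2 == oa
  flip <- a1 == oa & a2 == ea
  c_same <- !same & !flip & a1 == comp_allele(ea) & a2 == comp_allele(oa)
  c_flip <- !same & !flip & a1 == comp_allele(oa) & a2 == comp_allele(ea)
  matched <- same | flip | c_same | c_flip
  n_mismatch <- sum(!matched)

  keep_same <- same | c_same
  keep_flip <- flip | c_flip
  out <- data.frame(
    id = v$id[matched],
    counted_allele = v$a1[matched],
    weight = ifelse(keep_same[matched], s$beta[matched], -s$beta[matched]),
    sign_flipped = keep_flip[matched],
    p = s$p[matched],
    stringsAsFactors = FALSE)
  if (nrow(out) == 0)
    stop("no variants could be harmonised between genotypes and summary ",
         "statistics")
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(unmatched_id = unmatched,
                               palindromic = n_pal,
                               allele_mismatch = n_mismatch,
                               strand_flipped = sum(c_same | c_flip),
                               matched = nrow(out))
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Select SNPs by GWAS p-value threshold
#'
#' Retains weights whose discovery p-value is at or below `p_max`
#' (boundary inclusive).
#'
#' @param weights a [harmonize_alleles()] weight table.
#' @param p_max inclusion threshold (default 0.5).
#' @return the filtered weight table.
#' @export
select_snps <- function(weights, p_max = 0.5) {
  out <- weights[weights$p <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy p-value clumping against a genotype reference
#'
#' Variants are visited in ascending p-value order; a variant is accepted
#' unless an already-accepted variant on the same chromosome within
#' `window_kb` has squared dosage correlation above `r2_max` with it.
#'
#' @param stats summary-statistics data.frame (needs `id`, `p`).
#' @param reference a [genotype_matrix()] containing the stats variants.
#' @param r2_max,window_kb clumping parameters.
#' @return character vector of retained (index) variant ids.
#' @export
clump <- function(stats, reference, r2_max = 0.1, window_kb = 250) {
  if (nrow(stats) == 0) return(character(0))
  vi <- match(stats$id, reference$variants$id)
  if (anyNA(vi))
    stop("reference lacks variant(s): ",
         paste(stats$id[is.na(vi)], collapse = ", "))
  v <- reference$variants[vi, , drop = FALSE]
  ord <- order(stats$p)
  accepted <- integer(0)
  for (i in ord) {
    near <- accepted[v$chrom[accepted] == v$chrom[i] &
                       abs(v$pos[accepted] - v$pos[i]) <= window_kb * 1000]
    ok <- TRUE
    for (j in near) {
      r <- suppressWarnings(cor(reference$dosages[, vi[i]],
                                reference$dosages[, vi[j]],
                                use = "pairwise.complete.obs"))
      if (is.finite(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  stats$id[sort(accepted)]
}

#' Compute raw polygenic risk scores
#'
#' `raw_i = sum_j w_j d_ij` over the weight-table variants, with missing
#' dosages replaced by the variant's mean observed dosage.
#'
#' @param g a [genotype_matrix()]; must contain every weight-table variant.
#' @param weights a weight table ([harmonize_alleles()] then
#'   [select_snps()]).
#' @return data.frame of class `prs_vector`: `id`, `raw`.
#' @export
prs_score <- function(g, weights) {
  vi <- match(weights$id, g$variants$id)
  if (anyNA(vi))
    stop("weights refer to variant(s) absent from genotypes: ",
         paste(weights$id[is.na(vi)], collapse = ", "),
         " (harmonise against these genotypes first)")
  mism <- g$variants$a1[vi] != weights$counted_allele
  if (any(mism))
    stop("counted-allele mismatch for variant(s): ",
         paste(weights$id[mism], collapse = ", "))
  d <- g$dosages[, vi, drop = FALSE]
  if (anyNA(d))
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      if (any(miss)) d[miss, j] <- mean(d[, j], na.rm = TRUE)
    }
  structure(data.frame(id = g$sample_ids,
                       raw = as.vector(d %*% weights$weight),
                       stringsAsFactors = FALSE),
            class = c("prs_vector", "data.frame"))
}

#' Normalise polygenic scores to mean 0, SD 1
#'
#' The mean and SD are computed over `normalisation_set` (default: all scored
#' samples, i.e. cases and controls jointly) and the affine map is applied to
#' every sample.
#'
#' @param prs a [prs_score()] result.
#' @param normalisation_set sample ids defining the normalisation statistics.
#' @return the input with a `z` column added.
#' @export
normalize_prs <- function(prs, normalisation_set = prs$id) {
  idx <- match(normalisation_set, prs$id)
  if (anyNA(idx))
    stop("normalisation set contains unscored sample(s): ",
         paste(normalisation_set[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stop("need at least 2 samples to normalise")
  mu <- mean(prs$raw[idx])
  s <- sd(prs$raw[idx])
  if (!is.finite(s) || s == 0)
    stop("degenerate score: zero standard deviation over normalisation set")
  prs$z <- (prs$raw - mu) / s
  prs
}
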
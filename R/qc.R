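#' QC threshold set
#'
#' Defaults mirror a standard pre-/post-imputation microarray QC cascade:
#' SNP call rate >= 98%, MAF >= 1%, HWE exact p >= 1e-5, sample call rate
#' >= 98%, heterozygosity within mean +/- 3 SD, imputation INFO >= 0.9, LD
#' pruning with a 1000-SNP window advanced by 100 SNPs at r2 0.1, and 4 PCs.
#'
#' @param snp_call_rate_min,maf_min,hwe_p_min,sample_call_rate_min,het_sd_limit,info_min,prune_window_snps,prune_step,prune_r2,n_pcs
#'   see description.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.98, maf_min = 0.01,
                          hwe_p_min = 1e-5, sample_call_rate_min = 0.98,
                          het_sd_limit = 3, info_min = 0.9,
                          prune_window_snps = 1000, prune_step = 100,
                          prune_r2 = 0.1, n_pcs = 4) {
  stopifnot(snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            prune_window_snps >= prune_step, prune_step >= 1)
  structure(list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 sample_call_rate_min = sample_call_rate_min,
                 het_sd_limit = het_sd_limit, info_min = info_min,
                 prune_window_snps = as.integer(prune_window_snps),
                 prune_step = as.integer(prune_step), prune_r2 = prune_r2,
                 n_pcs = as.integer(n_pcs)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of HWE for a biallelic genotype table. Conditional on
#' the observed allele counts, the probability of each possible heterozygote
#' count (same parity as the minor-allele count) is computed by the standard
#' recurrence; the p-value sums the probabilities of all configurations no
#' more probable than the observed one. Monomorphic sites return 1 by
#' convention.
#'
#' @param n_hom_a,n_het,n_hom_b genotype counts (homozygous A1A1,
#'   heterozygous, homozygous A2A2).
#' @param midp use the mid-p correction (half weight on configurations
#'   exactly as probable as the observed one). The plain exact p-value is
#'   conservative and discrete; the mid-p variant is close to uniform under
#'   the null and is the usual choice for calibration diagnostics. The QC
#'   filter uses the plain exact p.
#' @return exact p-value; plain version in (0, 1\].
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b, midp = FALSE) {
  stopifnot(n_hom_a >= 0, n_het >= 0, n_hom_b >= 0)
  n <- n_hom_a + n_het + n_hom_b
  if (n == 0) stop("empty genotype table")
  n_a <- 2 * n_hom_a + n_het
  n_b <- 2 * n_hom_b + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)

  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised probabilities via the recurrence
  #   P(h+2)/P(h) = 4 * n_ra(h) * n_rb(h) / ((h+2) * (h+1))
  # where n_ra, n_rb are the homozygote counts implied by h.
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_r <- (rare - h) / 2
    hom_c <- n - (rare + h) / 2  # common-allele homozygotes
    lp[i] <- lp[i - 1] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  lo <- pr[obs] * (1 - 1e-10)
  hi <- pr[obs] * (1 + 1e-10)
  if (midp)
    return(sum(pr[pr < lo]) + 0.5 * sum(pr[pr >= lo & pr <= hi]))
  min(1, sum(pr[pr <= hi]))
}

# Per-variant genotype counts from hard calls.
.geno_counts <- function(dosages) {
  hc <- hard_calls(dosages)
  t(apply(hc, 2, function(col) c(sum(col == 0, na.rm = TRUE),
                                 sum(col == 1, na.rm = TRUE),
                                 sum(col == 2, na.rm = TRUE))))
}

#' Filter variants by call rate, MAF, HWE and imputation quality
#'
#' Rules are applied in fixed order — call rate, then MAF, then HWE exact-test
#' p-value, then INFO (skipped when no variant carries an INFO value) — and
#' each removed variant is attributed to the first rule it fails. MAF is
#' computed from non-missing dosages; HWE counts use hard calls.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (retained variants) and `report`
#'   (data.frame `rule`, `n_removed`, `removed_ids`; attribute
#'   `retained_ids`).
#' @export
filter_variants <- function(g, thresholds = qc_thresholds()) {
  stopifnot(nrow(g$variants) > 0)
  v <- g$variants
  counts <- .geno_counts(g$dosages)
  hwe_p <- vapply(seq_len(nrow(v)), function(j)
    hwe_exact_test(counts[j, 1], counts[j, 2], counts[j, 3]), numeric(1))
  v$hwe_p <- hwe_p

  alive <- rep(TRUE, nrow(v))
  removed <- list()
  apply_rule <- function(rule, fails) {
    hit <- alive & fails
    removed[[rule]] <<- v$id[hit]
    alive[hit] <<- FALSE
  }
  apply_rule("call_rate", v$call_rate < thresholds$snp_call_rate_min)
  apply_rule("maf", v$maf < thresholds$maf_min)
  apply_rule("hwe", hwe_p < thresholds$hwe_p_min)
  if (!all(is.na(v$info)))
    apply_rule("info", !is.na(v$info) & v$info < thresholds$info_min)
  else removed[["info"]] <- character(0)

  if (!any(alive)) warning("all variants removed by QC filters")
  kept <- genotype_matrix(g$sample_ids, v[alive, , drop = FALSE],
                          g$dosages[, alive, drop = FALSE])
  kept$variants$hwe_p <- v$hwe_p[alive]
  report <- data.frame(rule = names(removed),
                       n_removed = vapply(removed, length, integer(1)),
                       removed_ids = vapply(removed, paste,
                                            character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "retained_ids") <- v$id[alive]
  list(genotypes = kept, report = report)
}

#' Filter samples by call rate and heterozygosity
#'
#' Removes samples whose genotype call rate falls below threshold, then
#' computes each remaining sample's heterozygosity rate (fraction of
#' non-missing hard calls that are heterozygous) and removes samples beyond
#' `het_sd_limit` standard deviations from the mean. The heterozygosity step
#' is skipped (with a warning) when fewer than 3 samples remain or the SD is
#' zero.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` and `report` as in [filter_variants()].
#' @export
filter_samples <- function(g, thresholds = qc_thresholds()) {
  stopifnot(length(g$sample_ids) > 0)
  call_rate <- rowMeans(!is.na(g$dosages))
  removed <- list()
  alive <- call_rate >= thresholds$sample_call_rate_min
  removed[["call_rate"]] <- g$sample_ids[!alive]

  ids <- g$sample_ids[alive]
  if (length(ids) < 3) {
    warning("fewer than 3 samples; heterozygosity filter skipped")
    removed[["heterozygosity"]] <- character(0)
  } else {
    hc <- hard_calls(g$dosages[alive, , drop = FALSE])
    het <- rowMeans(hc == 1, na.rm = TRUE)
    s <- sd(het)
    if (!is.finite(s) || s == 0) {
      removed[["heterozygosity"]] <- character(0)
    } else {
      out <- abs(het - mean(het)) > thresholds$het_sd_limit * s
      removed[["heterozygosity"]] <- ids[out]
    }
  }
  keep <- setdiff(g$sample_ids, unlist(removed))
  kept <- subset_genotypes(g, samples = keep)
  report <- data.frame(rule = names(removed),
                       n_removed = vapply(removed, length, integer(1)),
                       removed_ids = vapply(removed, paste,
                                            character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  attr(report, "retained_ids") <- keep
  list(genotypes = kept, report = report)
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window_snps` variants (advanced by `step`,
#' per chromosome in position order), while any retained pair has squared
#' Pearson dosage correlation above `r2_max`, the member with the lower MAF is
#' removed (ties broken against the later position). Deterministic.
#'
#' @param g a [genotype_matrix()].
#' @param window_snps,step,r2_max pruning parameters (PLINK-style SNP-count
#'   window).
#' @return character vector of retained variant ids, in input order.
#' @export
ld_prune <- function(g, window_snps = 1000, step = 100, r2_max = 0.1) {
  v <- g$variants
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    starts <- seq(1, max(1, length(idx)), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      d <- g$dosages[, win, drop = FALSE]
      r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      while (any(r2 > r2_max)) {
        pair <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        cand <- win[c(pair[1], pair[2])]
        mafs <- v$maf[cand]
        drop_i <- if (mafs[1] < mafs[2]) 1
          else if (mafs[2] < mafs[1]) 2
          else which.max(v$pos[cand])
        keep[cand[drop_i]] <- FALSE
        wi <- which(win == cand[drop_i])
        r2[wi, ] <- 0
        r2[, wi] <- 0
      }
      if (s + window_snps - 1 >= length(idx)) break
    }
  }
  v$id[keep]
}

#' Principal components from the variance-standardised relationship matrix
#'
#' Missing dosages are mean-imputed per variant; each variant column is then
#' standardised to mean 0, variance 1 (zero-variance columns dropped). The
#' genetic relationship matrix is `X X' / m`; the returned PCs are its leading
#' eigenvectors scaled by the square root of their eigenvalues. Sign
#' convention: the largest-magnitude loading of each PC is positive.
#'
#' @param g a [genotype_matrix()].
#' @param n_pcs number of components requested; truncated to the matrix rank
#'   with a warning when larger.
#' @return numeric matrix (samples x PCs) with rownames = sample ids and
#'   columns `PC1`, `PC2`, ...; attribute `eigenvalues`.
#' @export
compute_pcs <- function(g, n_pcs = 4) {
  stopifnot(length(g$sample_ids) >= 2, nrow(g$variants) >= 2)
  d <- g$dosages
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- mean(d[, j], na.rm = TRUE)
  }
  sds <- apply(d, 2, sd)
  ok <- sds > 0
  x <- scale(d[, ok, drop = FALSE])
  m <- ncol(x)
  if (m == 0) {
    warning("no polymorphic variants; returning 0 PCs")
    out <- matrix(numeric(0), nrow(d), 0,
                  dimnames = list(g$sample_ids, NULL))
    attr(out, "eigenvalues") <- numeric(0)
    return(out)
  }
  grm <- tcrossprod(x) / m
  eg <- eigen(grm, symmetric = TRUE)
  tol <- max(eg$values, 0) * length(g$sample_ids) * .Machine$double.eps
  rank <- sum(eg$values > max(tol, 1e-12))
  k <- min(n_pcs, rank)
  if (k < n_pcs)
    warning("requested ", n_pcs, " PCs but rank is ", rank,
            "; returning ", k)
  if (k == 0) {
    out <- matrix(numeric(0), nrow(d), 0,
                  dimnames = list(g$sample_ids, NULL))
    attr(out, "eigenvalues") <- numeric(0)
    return(out)
  }
  pcs <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pcs[, j]))
    if (pcs[i_max, j] < 0) pcs[, j] <- -pcs[, j]
  }
  pcs <- sweep(pcs, 2, sqrt(eg$values[seq_len(k)]), `*`)
  dimnames(pcs) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  attr(pcs, "eigenvalues") <- eg$values[seq_len(k)]
  pcs
}

#' Flag PCA outlier samples
#'
#' Flags samples whose PC1 or PC2 coordinate lies beyond the median plus or
#' minus `sd_limit` robust standard deviations (1.4826 MAD). A zero MAD on a
#' component flags no one on that component.
#'
#' @param pcs matrix from [compute_pcs()] (uses the first two columns).
#' @param sd_limit robust-SD multiplier.
#' @return character vector of flagged sample ids.
#' @export
flag_pc_outliers <- function(pcs, sd_limit = 6) {
  stopifnot(nrow(pcs) >= 3)
  out <- rep(FALSE, nrow(pcs))
  for (j in seq_len(min(2, ncol(pcs)))) {
    x <- pcs[, j]
    s <- mad(x)  # 1.4826 * MAD by default
    if (s > 0) out <- out | abs(x - median(x)) > sd_limit * s
  }
  rownames(pcs)[out]
}
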
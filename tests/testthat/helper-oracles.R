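# Independent oracles and tiny fixture builders shared across the suite.

# HWE exact p by direct enumeration: multinomial probability of every
# heterozygote configuration compatible with the allele counts, summed over
# configurations no more probable than the observed one.
enum_hwe_p <- function(n_hom_a, n_het, n_hom_b, midp = FALSE) {
  n <- n_hom_a + n_het + n_hom_b
  na <- 2 * n_hom_a + n_het
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  lo <- pr[obs] * (1 - 1e-10); hi <- pr[obs] * (1 + 1e-10)
  if (midp) sum(pr[pr < lo]) + 0.5 * sum(pr[pr >= lo & pr <= hi])
  else min(1, sum(pr[pr <= hi]))
}

# Per-sample loop PRS oracle.
loop_prs <- function(g, weights) {
  vi <- match(weights$id, g$variants$id)
  sapply(seq_along(g$sample_ids), function(i) {
    tot <- 0
    for (k in seq_along(vi)) {
      d <- g$dosages[i, vi[k]]
      if (is.na(d)) d <- mean(g$dosages[, vi[k]], na.rm = TRUE)
      tot <- tot + weights$weight[k] * d
    }
    tot
  })
}

# Brute-force maximum-likelihood logistic oracle via general-purpose
# optimisation of the exact negative log-likelihood.
optim_logistic <- function(y, x_mat) {
  x_mat <- cbind(1, x_mat)
  nll <- function(b) {
    eta <- as.vector(x_mat %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  fit <- optim(rep(0, ncol(x_mat)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# Small genotype matrix with the given dosage matrix (samples x variants).
toy_genotypes <- function(dosages, chrom = NULL, pos = NULL,
                          a1 = NULL, a2 = NULL) {
  m <- ncol(dosages)
  genotype_matrix(
    sprintf("s%03d", seq_len(nrow(dosages))),
    data.frame(id = sprintf("v%03d", seq_len(m)),
               chrom = if (is.null(chrom)) rep("1", m) else chrom,
               pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
               a1 = if (is.null(a1)) rep("A", m) else a1,
               a2 = if (is.null(a2)) rep("G", m) else a2,
               stringsAsFactors = FALSE),
    dosages)
}

# Weight table bypassing harmonisation, for direct scoring tests.
toy_weights <- function(ids, weights, p = NULL, counted = "A") {
  structure(data.frame(id = ids, counted_allele = counted, weight = weights,
                       sign_flipped = FALSE,
                       p = if (is.null(p)) rep(0.01, length(ids)) else p,
                       stringsAsFactors = FALSE),
            class = c("weight_table", "data.frame"))
}

# A fast-running simulation configuration for downstream tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(m_snps = 150, n_cases = 120, n_controls = 120,
                   n_trios = 30, n_discovery = 5000, seed = 101)
  do.call(sim_config, utils::modifyList(defaults, args))
}
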
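# Seeded simulation studies used for operating-characteristic checks:
# type-I error, parameter recovery, power, and the three-group pattern.

#' Type-I error of the PRS association under a flat polygenic background
#'
#' Repeatedly simulates cohorts with `h2 = 0` and no major-effect variant —
#' so case status is independent of genotype — scores them with
#' noise-only GWAS weights, and fits the sex-adjusted logistic association.
#' Reports the fraction of replicates rejecting at `alpha`.
#'
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `i` uses `seed * 100 + i` internally.
#' @param n_cases,n_controls,m_snps per-replicate cohort dimensions.
#' @param alpha nominal test level.
#' @return list: `rate`, `n_reps`, `alpha`.
#' @export
assoc_type1_study <- function(n_reps = 2000, seed = 1, n_cases = 250,
                              n_controls = 250, m_snps = 100,
                              alpha = 0.05) {
  reject <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(m_snps = m_snps, h2_liability = 0, gamma_major = 0,
                      carrier_freq = 0, n_discovery = 5000,
                      n_cases = n_cases, n_controls = n_controls,
                      seed = (seed %% 10000) * 100000 + i)
    eff <- simulate_true_effects(cfg)
    ss <- simulate_summary_stats(eff, cfg)
    co <- simulate_cohort(eff, cfg)
    w <- select_snps(harmonize_alleles(co$genotypes, ss), 0.5)
    prs <- normalize_prs(prs_score(co$genotypes, w))
    z <- prs$z[match(co$samples$id, prs$id)]
    fit <- fit_logistic(co$samples$phenotype == "case", z,
                        data.frame(sex = code_sex(co$samples$sex)))
    reject[i] <- fit$p < alpha
  }
  list(rate = mean(reject), n_reps = n_reps, alpha = alpha)
}

#' Type-I error of the pTDT under unascertained transmission
#'
#' Simulates trios without affected-proband ascertainment — transmission is
#' symmetric, so the pTDT null holds regardless of heritability — and
#' reports the fraction of replicates rejecting at `alpha`.
#'
#' @inheritParams assoc_type1_study
#' @param n_trios trios per replicate.
#' @param h2 liability heritability of the generating model.
#' @return list: `rate`, `n_reps`, `alpha`.
#' @export
ptdt_type1_study <- function(n_reps = 2000, seed = 1, n_trios = 30,
                             m_snps = 100, h2 = 0.3, alpha = 0.05) {
  reject <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(m_snps = m_snps, h2_liability = h2, gamma_major = 0,
                      carrier_freq = 0, n_discovery = 5000,
                      n_trios = n_trios, ascertain_trios = FALSE,
                      seed = (seed %% 10000) * 100000 + i)
    eff <- simulate_true_effects(cfg)
    ss <- simulate_summary_stats(eff, cfg)
    tr <- simulate_trios(eff, cfg)
    w <- select_snps(harmonize_alleles(tr$genotypes, ss), 0.5)
    prs <- normalize_prs(prs_score(tr$genotypes, w))
    reject[i] <- ptdt_test(tr$trios, prs)$p < alpha
  }
  list(rate = mean(reject), n_reps = n_reps, alpha = alpha)
}

#' Recovery of the heritability ordering by the PRS association
#'
#' For each run, simulates one cohort per heritability value (same seed
#' offset, shared dimensions), fits the sex-adjusted PRS association, and
#' checks that the estimated log-odds per SD increases strictly along the
#' grid. Returns the fraction of runs with the correct ordering and the
#' per-run estimates.
#'
#' @param n_runs number of independent runs.
#' @param seed base seed.
#' @param h2_grid increasing heritability values.
#' @param n_cases,n_controls,m_snps,n_discovery cohort dimensions.
#' @return list: `fraction_ordered`, `betas` (matrix runs x grid),
#'   `h2_grid`, `n_runs`.
#' @export
h2_recovery_study <- function(n_runs = 10, seed = 1,
                              h2_grid = c(0, 0.1, 0.3),
                              n_cases = 2000, n_controls = 2000,
                              m_snps = 300, n_discovery = 10000) {
  betas <- matrix(NA_real_, n_runs, length(h2_grid),
                  dimnames = list(NULL, paste0("h2_", h2_grid)))
  for (r in seq_len(n_runs)) {
    for (j in seq_along(h2_grid)) {
      cfg <- sim_config(m_snps = m_snps, h2_liability = h2_grid[j],
                        gamma_major = 0, carrier_freq = 0,
                        n_discovery = n_discovery, n_cases = n_cases,
                        n_controls = n_controls,
                        seed = (seed %% 10000) * 100000 + r * 10 + j)
      eff <- simulate_true_effects(cfg)
      ss <- simulate_summary_stats(eff, cfg)
      co <- simulate_cohort(eff, cfg)
      w <- select_snps(harmonize_alleles(co$genotypes, ss), 0.5)
      prs <- normalize_prs(prs_score(co$genotypes, w))
      z <- prs$z[match(co$samples$id, prs$id)]
      fit <- fit_logistic(co$samples$phenotype == "case", z,
                          data.frame(sex = code_sex(co$samples$sex)))
      betas[r, j] <- fit$beta
    }
  }
  ordered <- apply(betas, 1, function(b) all(diff(b) > 0))
  list(fraction_ordered = mean(ordered), betas = betas,
       h2_grid = h2_grid, n_runs = n_runs)
}

#' Power of the pTDT in affected-proband trios
#'
#' Simulates ascertained trio cohorts under a heritable liability and
#' reports the fraction of replicates in which the pTDT rejects at `alpha`,
#' along with the mean of the per-replicate mean deviations.
#'
#' @inheritParams assoc_type1_study
#' @param n_trios trios per replicate.
#' @param h2 liability heritability.
#' @param n_discovery discovery GWAS size for the weights.
#' @return list: `power`, `mean_deviation`, `n_reps`, `n_trios`.
#' @export
ptdt_power_study <- function(n_reps = 25, seed = 1, n_trios = 171,
                             h2 = 0.3, m_snps = 300, n_discovery = 10000,
                             alpha = 0.05) {
  reject <- logical(n_reps)
  devs <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(m_snps = m_snps, h2_liability = h2, gamma_major = 0,
                      carrier_freq = 0, n_discovery = n_discovery,
                      n_trios = n_trios, ascertain_trios = TRUE,
                      seed = (seed %% 10000) * 100000 + i)
    eff <- simulate_true_effects(cfg)
    ss <- simulate_summary_stats(eff, cfg)
    tr <- simulate_trios(eff, cfg)
    w <- select_snps(harmonize_alleles(tr$genotypes, ss), 0.5)
    prs <- normalize_prs(prs_score(tr$genotypes, w))
    res <- ptdt_test(tr$trios, prs)
    reject[i] <- res$p < alpha
    devs[i] <- res$mean_deviation
  }
  list(power = mean(reject), mean_deviation = mean(devs),
       n_reps = n_reps, n_trios = n_trios)
}
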
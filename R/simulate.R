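#' Simulation configuration for liability-threshold cohorts
#'
#' Defines the generating model used throughout the package's tests and
#' analyses: `m_snps` unlinked biallelic SNPs in Hardy-Weinberg equilibrium
#' whose additive effects explain a liability-scale heritability `h2_liability`
#' (h2); a rare dominant variant of major effect carried with frequency
#' `carrier_freq` (f) that shifts liability by `gamma_major` (gamma); and a
#' disease threshold set by prevalence `prevalence_k` (K). Residual variance
#' is `1 - h2` so the non-major liability has unit variance.
#'
#' @param m_snps number of SNPs.
#' @param maf_range allele-frequency range (low, high) within (0, 0.5].
#' @param h2_liability SNP heritability of liability, in \[0, 1).
#' @param prevalence_k disease prevalence K, in (0, 1).
#' @param gamma_major liability shift per major-effect carrier (>= 0).
#' @param carrier_freq population frequency of major-effect carriers, \[0, 1).
#' @param n_discovery discovery GWAS sample size for summary statistics.
#' @param n_cases,n_controls,n_trios cohort sizes to ascertain.
#' @param ascertain_trios keep only trios whose child is affected.
#' @param seed integer seed; all `simulate_*` functions derive their random
#'   streams from it, so identical config implies identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 1000, maf_range = c(0.05, 0.5),
                       h2_liability = 0.3, prevalence_k = 0.01,
                       gamma_major = 3, carrier_freq = 0.003,
                       n_discovery = 30000, n_cases = 500, n_controls = 500,
                       n_trios = 100, ascertain_trios = TRUE, seed = 1) {
  stopifnot(m_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2_liability >= 0, h2_liability < 1,
            prevalence_k > 0, prevalence_k < 1,
            gamma_major >= 0, carrier_freq >= 0, carrier_freq < 1,
            n_discovery > 0)
  structure(list(m_snps = as.integer(m_snps), maf_range = maf_range,
                 h2_liability = h2_liability, prevalence_k = prevalence_k,
                 gamma_major = gamma_major, carrier_freq = carrier_freq,
                 n_discovery = as.integer(n_discovery),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_trios = as.integer(n_trios),
                 ascertain_trios = isTRUE(ascertain_trios),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Distinct random streams per generator stage, derived from the config seed.
.sim_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}

#' Draw per-SNP allele frequencies and true liability effects
#'
#' Allele frequencies are uniform on `maf_range`; raw effects are Gaussian and
#' rescaled so the additive variance sums exactly to the target heritability:
#' sum_j 2 p_j (1 - p_j) a_j^2 = h2. With `h2_liability = 0` all effects are 0.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `true_effects`: `id`, `chrom`, `pos`, `a1`,
#'   `a2`, `maf` (p_j), `effect` (a_j).
#' @export
simulate_true_effects <- function(config) {
  set.seed(.sim_seed(config, 1L))
  m <- config$m_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  if (config$h2_liability == 0) {
    a <- numeric(m)
  } else {
    a <- rnorm(m)
    a <- a * sqrt(config$h2_liability / sum(2 * p * (1 - p) * a^2))
  }
  structure(data.frame(id = sprintf("snp%05d", seq_len(m)),
                       chrom = as.character(1 + (seq_len(m) - 1) %% 22),
                       pos = 10000L + 5000L * ((seq_len(m) - 1) %/% 22),
                       a1 = "A", a2 = "G",
                       maf = p, effect = a, stringsAsFactors = FALSE),
            class = c("true_effects", "data.frame"))
}

#' Simulate noisy discovery-GWAS summary statistics
#'
#' Per SNP, the reported effect is the true liability effect plus Gaussian
#' estimation noise with standard error `1 / sqrt(2 p (1 - p) n_discovery)`;
#' p-values are two-sided Wald. The effect allele is the counted allele `a1`.
#'
#' @param effects a [simulate_true_effects()] table.
#' @param config a [sim_config()] (supplies `n_discovery` and seed).
#' @return summary-statistics data.frame (`id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`).
#' @export
simulate_summary_stats <- function(effects, config) {
  set.seed(.sim_seed(config, 2L))
  se <- 1 / sqrt(2 * effects$maf * (1 - effects$maf) * config$n_discovery)
  beta <- effects$effect + rnorm(nrow(effects), 0, se)
  p <- 2 * pnorm(-abs(beta / se))
  p <- pmax(p, 1e-300)
  data.frame(id = effects$id, chrom = effects$chrom, pos = effects$pos,
             effect_allele = effects$a1, other_allele = effects$a2,
             beta = beta, se = se, p = p, stringsAsFactors = FALSE)
}

# Genotypes for a block of n individuals at the effect SNPs: HWE binomials.
.draw_genotypes <- function(n, maf) {
  matrix(rbinom(n * length(maf), 2L, rep(maf, each = n)), nrow = n)
}

#' Simulate an ascertained case/control cohort
#'
#' Individuals are drawn from the population model — unlinked HWE genotypes,
#' polygenic liability `G = sum a_j (g_j - 2 p_j)` (mean-centred so the
#' threshold sits at the prevalence quantile), a dominant major-effect carrier flag
#' `C ~ Bernoulli(f)` shifting liability by gamma, residual
#' `N(0, 1 - h2)` — and kept by rejection sampling until `n_cases` affected
#' (liability above the prevalence threshold) and `n_controls` unaffected
#' individuals are collected. Cases carrying the major-effect variant are
#' labelled `screen_status = "positive"`, other cases `"negative"` (ground
#' truth); controls get `NA`.
#'
#' @param effects a [simulate_true_effects()] table.
#' @param config a [sim_config()].
#' @param cohort cohort label written into the sample table.
#' @param max_draws cap on total individuals drawn before declaring the
#'   ascertainment infeasible.
#' @return list with `genotypes` (a [genotype_matrix()]) and `samples`
#'   (data.frame: `id`, `phenotype`, `sex`, `cohort`, `screen_status`,
#'   `carrier`, `liability`, `polygenic` — the true polygenic score).
#' @export
simulate_cohort <- function(effects, config, cohort = "sim",
                            max_draws = NULL) {
  set.seed(.sim_seed(config, 3L))
  k_thresh <- qnorm(1 - config$prevalence_k)
  if (is.null(max_draws))
    max_draws <- ceiling(50 * config$n_cases / config$prevalence_k +
                           50 * config$n_controls)
  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  resid_sd <- sqrt(1 - config$h2_liability)

  if (all(effects$effect == 0)) {
    # Exact shortcut: liability is independent of genotypes, so draw status
    # first and genotypes only for the retained samples.
    status <- .ascertain_status(n_case, n_ctrl, config, k_thresh, resid_sd,
                                max_draws)
    geno <- .draw_genotypes(n_case + n_ctrl, effects$maf)
    keep <- list(g = geno, carrier = status$carrier,
                 liability = status$liability, case = status$case)
  } else {
    keep <- .ascertain_full(effects, config, k_thresh, resid_sd,
                            n_case, n_ctrl, max_draws)
  }

  ord <- order(!keep$case)  # cases first
  g <- keep$g[ord, , drop = FALSE]
  carrier <- keep$carrier[ord]
  liability <- keep$liability[ord]
  is_case <- keep$case[ord]
  n <- length(is_case)
  ids <- sprintf("%s_%s%04d", cohort,
                 ifelse(is_case, "case", "ctrl"),
                 c(seq_len(n_case), seq_len(n_ctrl)))
  samples <- data.frame(
    id = ids,
    phenotype = ifelse(is_case, "case", "control"),
    sex = rbinom(n, 1L, 0.5) + 1L,
    cohort = cohort,
    screen_status = ifelse(is_case, ifelse(carrier == 1L, "positive",
                                           "negative"), NA_character_),
    carrier = carrier == 1L,
    liability = liability,
    polygenic = as.vector(g %*% effects$effect) -
      sum(2 * effects$maf * effects$effect),
    stringsAsFactors = FALSE)
  variants <- effects[, c("id", "chrom", "pos", "a1", "a2")]
  list(genotypes = genotype_matrix(ids, variants, g), samples = samples)
}

# Case/control status without genotypes (used when all SNP effects are 0).
.ascertain_status <- function(n_case, n_ctrl, config, k_thresh, resid_sd,
                              max_draws) {
  carrier <- integer(0); liability <- numeric(0); case <- logical(0)
  drawn <- 0L
  need <- function() sum(case) < n_case || sum(!case) < n_ctrl
  while (need()) {
    if (drawn >= max_draws)
      stop("ascertainment infeasible: ", max_draws,
           " draws did not yield the requested cases/controls")
    chunk <- min(max_draws - drawn,
                 max(1000L, ceiling(2 * n_case / config$prevalence_k)))
    cc <- rbinom(chunk, 1L, config$carrier_freq)
    ll <- config$gamma_major * cc + rnorm(chunk, 0, resid_sd)
    is_case <- ll > k_thresh
    drawn <- drawn + chunk
    take <- (is_case & cumsum(is_case) + sum(case) <= n_case) |
      (!is_case & cumsum(!is_case) + sum(!case) <= n_ctrl)
    carrier <- c(carrier, cc[take])
    liability <- c(liability, ll[take])
    case <- c(case, is_case[take])
  }
  list(carrier = carrier, liability = liability, case = case)
}

# Full rejection sampling with genotypes.
.ascertain_full <- function(effects, config, k_thresh, resid_sd,
                            n_case, n_ctrl, max_draws) {
  m <- nrow(effects)
  chunk_size <- max(1000L, min(50000L, ceiling(2e6 / m)))
  g_keep <- NULL; carrier <- integer(0); liability <- numeric(0)
  case <- logical(0); drawn <- 0L
  while (sum(case) < n_case || sum(!case) < n_ctrl) {
    if (drawn >= max_draws)
      stop("ascertainment infeasible: ", max_draws,
           " draws did not yield the requested cases/controls")
    chunk <- min(chunk_size, max_draws - drawn)
    gg <- .draw_genotypes(chunk, effects$maf)
    cc <- rbinom(chunk, 1L, config$carrier_freq)
    ll <- as.vector(gg %*% effects$effect) -
      sum(2 * effects$maf * effects$effect) +
      config$gamma_major * cc + rnorm(chunk, 0, resid_sd)
    is_case <- ll > k_thresh
    drawn <- drawn + chunk
    take <- (is_case & cumsum(is_case) + sum(case) <= n_case) |
      (!is_case & cumsum(!is_case) + sum(!case) <= n_ctrl)
    if (any(take)) {
      g_keep <- rbind(g_keep, gg[take, , drop = FALSE])
      carrier <- c(carrier, cc[take])
      liability <- c(liability, ll[take])
      case <- c(case, is_case[take])
    }
  }
  list(g = g_keep, carrier = carrier, liability = liability, case = case)
}

#' Simulate parent-offspring trios with Mendelian transmission
#'
#' Parents are drawn from the population model; each parent transmits one of
#' its two alleles uniformly at random per SNP, so the child dosage is the sum
#' of two transmitted alleles. The major-effect variant arises de novo in the
#' child with probability `carrier_freq` (parents are never carriers),
#' matching the de novo dominant aetiology of severe epilepsies. With
#' `ascertain_trios = TRUE`, only trios whose child is affected under the
#' liability rule are kept.
#'
#' @param effects a [simulate_true_effects()] table.
#' @param config a [sim_config()].
#' @return list with `genotypes` (fathers, mothers and children),
#'   `samples` (children carry case status and ground-truth screen status),
#'   `trios` (data.frame `father_id`, `mother_id`, `child_id`) and
#'   `pedigree` (FAM-dialect table).
#' @export
simulate_trios <- function(effects, config) {
  set.seed(.sim_seed(config, 4L))
  m <- nrow(effects)
  k_thresh <- qnorm(1 - config$prevalence_k)
  resid_sd <- sqrt(1 - config$h2_liability)
  n_want <- config$n_trios
  max_draws <- if (config$ascertain_trios)
    ceiling(50 * n_want / config$prevalence_k) else n_want
  chunk_size <- max(500L, min(20000L, ceiling(1e6 / m)))

  gf <- gm <- gc <- NULL
  carrier <- integer(0); liability <- numeric(0)
  drawn <- 0L
  while (NROW(gc) < n_want) {
    if (drawn >= max_draws)
      stop("trio ascertainment infeasible: ", max_draws,
           " draws did not yield ", n_want, " qualifying trios")
    chunk <- min(chunk_size, max_draws - drawn)
    f <- .draw_genotypes(chunk, effects$maf)
    mo <- .draw_genotypes(chunk, effects$maf)
    # transmitted allele ~ Bernoulli(g/2) per parent per SNP
    tf <- matrix(rbinom(chunk * m, 1L, f / 2), nrow = chunk)
    tm <- matrix(rbinom(chunk * m, 1L, mo / 2), nrow = chunk)
    ch <- tf + tm
    cc <- rbinom(chunk, 1L, config$carrier_freq)
    ll <- as.vector(ch %*% effects$effect) -
      sum(2 * effects$maf * effects$effect) +
      config$gamma_major * cc + rnorm(chunk, 0, resid_sd)
    keep <- if (config$ascertain_trios) ll > k_thresh else rep(TRUE, chunk)
    drawn <- drawn + chunk
    if (any(keep)) {
      keep <- keep & cumsum(keep) + NROW(gc) <= n_want
      gf <- rbind(gf, f[keep, , drop = FALSE])
      gm <- rbind(gm, mo[keep, , drop = FALSE])
      gc <- rbind(gc, ch[keep, , drop = FALSE])
      carrier <- c(carrier, cc[keep])
      liability <- c(liability, ll[keep])
    }
  }

  n <- n_want
  fid <- sprintf("fam%04d", seq_len(n))
  f_id <- paste0(fid, "_fa"); m_id <- paste0(fid, "_mo")
  c_id <- paste0(fid, "_ch")
  all_ids <- c(f_id, m_id, c_id)
  g_all <- rbind(gf, gm, gc)
  variants <- effects[, c("id", "chrom", "pos", "a1", "a2")]
  child_case <- if (config$ascertain_trios) rep(TRUE, n) else
    liability > k_thresh
  samples <- data.frame(
    id = all_ids,
    phenotype = c(rep("control", 2 * n),
                  ifelse(child_case, "case", "control")),
    sex = c(rep(1L, n), rep(2L, n), rbinom(n, 1L, 0.5) + 1L),
    cohort = "trio",
    screen_status = c(rep(NA_character_, 2 * n),
                      ifelse(child_case,
                             ifelse(carrier == 1L, "positive", "negative"),
                             NA_character_)),
    carrier = c(rep(FALSE, 2 * n), carrier == 1L),
    liability = c(rep(NA_real_, 2 * n), liability),
    stringsAsFactors = FALSE)
  trios <- data.frame(father_id = f_id, mother_id = m_id, child_id = c_id,
                      stringsAsFactors = FALSE)
  pedigree <- data.frame(
    family_id = c(fid, fid, fid),
    id = all_ids,
    father_id = c(rep("0", 2 * n), f_id),
    mother_id = c(rep("0", 2 * n), m_id),
    sex = samples$sex,
    phenotype = ifelse(samples$phenotype == "case", 2L, 1L),
    stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(all_ids, variants, g_all),
       samples = samples, trios = trios, pedigree = pedigree)
}

#' Simulate annotated rare-variant and CNV tables with ground truth
#'
#' For every screen-positive case (true carrier) one qualifying record is
#' generated — either an SNV satisfying the qualifying rules (dominant-panel
#' gene, LoF or missense with MPC > 2, absent from population databases, seen
#' at most 3 times in the dataset) or a CNV satisfying one of the CNV clauses
#' (> 2 Mb, epilepsy gene/hotspot overlap, or pLI > 0.9 gene overlap). Every
#' case additionally receives decoy records, each violating exactly one rule,
#' so screen-negative cases have variant data but no qualifying record.
#'
#' @param samples a sample table from [simulate_cohort()] (uses `phenotype`
#'   and ground-truth `screen_status`).
#' @param config a [sim_config()] (seed only).
#' @return list with `snv` and `cnv` annotation data.frames (each carrying
#'   `truth_qualifying` and `decoy_class` label columns) and `truth`
#'   (data.frame `case_id`, `status` — the generator's screen labels).
#' @export
simulate_annotations <- function(samples, config) {
  stopifnot(nrow(samples) > 0)
  set.seed(.sim_seed(config, 5L))
  cases <- samples[samples$phenotype == "case", , drop = FALSE]
  pos <- cases$id[cases$screen_status %in% "positive"]
  neg <- cases$id[cases$screen_status %in% "negative"]

  qual_snv <- function(case_id, i) {
    lof <- runif(1) < 0.5
    data.frame(case_id = case_id, variant_id = sprintf("qv_%s", case_id),
               gene = sprintf("PANEL_GENE%02d", 1 + i %% 20),
               consequence = if (lof) "lof" else "missense",
               mpc = if (lof) NA_real_ else runif(1, 2.2, 4),
               in_population_db = FALSE,
               dataset_count = sample(1:3, 1),
               gene_in_dominant_panel = TRUE,
               truth_qualifying = TRUE, decoy_class = NA_character_,
               stringsAsFactors = FALSE)
  }
  decoy_snv <- function(case_id, class) {
    rec <- data.frame(case_id = case_id,
                      variant_id = sprintf("dv_%s_%s", class, case_id),
                      gene = "PANEL_GENE01", consequence = "missense",
                      mpc = 3, in_population_db = FALSE, dataset_count = 1L,
                      gene_in_dominant_panel = TRUE,
                      truth_qualifying = FALSE, decoy_class = class,
                      stringsAsFactors = FALSE)
    switch(class,
           low_mpc = {rec$mpc <- runif(1, 0, 1.99)},
           off_panel = {rec$gene <- "OFFPANEL_GENE"
                        rec$gene_in_dominant_panel <- FALSE},
           in_db = {rec$in_population_db <- TRUE},
           recurrent = {rec$dataset_count <- sample(4:8, 1)},
           benign_csq = {rec$consequence <- "synonymous"})
    rec
  }
  qual_cnv <- function(case_id) {
    clause <- sample(c("length", "hotspot", "pli"), 1)
    data.frame(case_id = case_id, cnv_id = sprintf("qc_%s", case_id),
               length_bp = if (clause == "length")
                 round(runif(1, 2.1e6, 8e6)) else round(runif(1, 1e5, 1.9e6)),
               overlaps_epilepsy_gene_or_hotspot = clause == "hotspot",
               overlaps_pli_gt_0_9_gene = clause == "pli",
               truth_qualifying = TRUE, decoy_class = NA_character_,
               stringsAsFactors = FALSE)
  }
  decoy_cnv <- function(case_id) {
    data.frame(case_id = case_id, cnv_id = sprintf("dc_%s", case_id),
               length_bp = round(runif(1, 1e5, 1.9e6)),
               overlaps_epilepsy_gene_or_hotspot = FALSE,
               overlaps_pli_gt_0_9_gene = FALSE,
               truth_qualifying = FALSE, decoy_class = "small_no_overlap",
               stringsAsFactors = FALSE)
  }

  snv <- list(); cnv <- list()
  for (i in seq_along(pos)) {
    if (runif(1) < 0.7) snv[[length(snv) + 1]] <- qual_snv(pos[i], i)
    else cnv[[length(cnv) + 1]] <- qual_cnv(pos[i])
  }
  classes <- c("low_mpc", "off_panel", "in_db", "recurrent", "benign_csq")
  for (i in seq_along(neg)) {
    snv[[length(snv) + 1]] <- decoy_snv(neg[i], classes[1 + i %% 5])
    if (i %% 3 == 0) cnv[[length(cnv) + 1]] <- decoy_cnv(neg[i])
  }
  for (i in seq_along(pos))  # positives also carry decoys
    if (i %% 2 == 0)
      snv[[length(snv) + 1]] <- decoy_snv(pos[i], classes[1 + i %% 5])

  empty_snv <- data.frame(case_id = character(0), variant_id = character(0),
                          gene = character(0), consequence = character(0),
                          mpc = numeric(0), in_population_db = logical(0),
                          dataset_count = integer(0),
                          gene_in_dominant_panel = logical(0),
                          truth_qualifying = logical(0),
                          decoy_class = character(0))
  empty_cnv <- data.frame(case_id = character(0), cnv_id = character(0),
                          length_bp = numeric(0),
                          overlaps_epilepsy_gene_or_hotspot = logical(0),
                          overlaps_pli_gt_0_9_gene = logical(0),
                          truth_qualifying = logical(0),
                          decoy_class = character(0))
  list(snv = if (length(snv)) do.call(rbind, snv) else empty_snv,
       cnv = if (length(cnv)) do.call(rbind, cnv) else empty_cnv,
       truth = data.frame(case_id = cases$id,
                          status = ifelse(is.na(cases$screen_status),
                                          "unknown", cases$screen_status),
                          stringsAsFactors = FALSE))
}

#' Inject QC-violating artifacts into a genotype matrix
#'
#' Degrades a clean matrix so that flagged variants/samples violate exactly
#' one QC filter each: per-genotype missingness on selected variants (call
#' rate), rare-allele replacement (MAF), engineered heterozygote excess
#' verified to fail the HWE exact test, whole-sample missingness (sample call
#' rate), and heterozygosity-outlier samples.
#'
#' @param g a [genotype_matrix()].
#' @param variant_missing_rate fraction of variants given ~5% missing calls.
#' @param low_maf_rate fraction of variants rewritten at MAF 0.005.
#' @param hwe_violation_rate fraction of variants rewritten with het excess.
#' @param sample_missing_rate fraction of samples given ~5% missing calls.
#' @param het_outlier_rate fraction of samples rewritten as heterozygous at
#'   80% of variants.
#' @param seed integer seed.
#' @return list with `genotypes` (degraded matrix) and `flags` — ground-truth
#'   id vectors `variants_missing`, `variants_low_maf`, `variants_hwe`,
#'   `samples_missing`, `samples_het`.
#' @export
inject_qc_artifacts <- function(g, variant_missing_rate = 0,
                                low_maf_rate = 0, hwe_violation_rate = 0,
                                sample_missing_rate = 0,
                                het_outlier_rate = 0, seed = 1) {
  rates <- c(variant_missing_rate, low_maf_rate, hwe_violation_rate,
             sample_missing_rate, het_outlier_rate)
  stopifnot(all(rates >= 0), all(rates <= 1))
  set.seed(seed)
  d <- g$dosages
  n <- nrow(d); m <- ncol(d)
  vid <- g$variants$id; sid <- g$sample_ids

  pick <- function(k, pool) if (k >= 1) sample(pool, min(k, length(pool)))
    else character(0)
  avail_v <- vid
  v_miss <- pick(round(variant_missing_rate * m), avail_v)
  avail_v <- setdiff(avail_v, v_miss)
  v_maf <- pick(round(low_maf_rate * m), avail_v)
  avail_v <- setdiff(avail_v, v_maf)
  v_hwe <- pick(round(hwe_violation_rate * m), avail_v)
  s_miss <- pick(round(sample_missing_rate * n), sid)
  s_het <- pick(round(het_outlier_rate * n), setdiff(sid, s_miss))

  # missingness first, so the MAF/HWE constructions below are validated
  # against the cells that stay observed
  for (v in v_miss) {
    idx <- sample(n, max(1L, round(0.05 * n)))
    d[idx, v] <- NA_real_
  }
  for (s in s_miss) {
    idx <- sample(m, max(1L, round(0.05 * m)))
    d[s, idx] <- NA_real_
  }
  for (v in v_maf) {
    obs <- !is.na(d[, v])
    # redraw until the realised MAF is below the 1% filter line
    repeat {
      d[obs, v] <- rbinom(sum(obs), 2L, 0.005)
      if (mean(d[obs, v]) / 2 < 0.01) break
    }
  }
  for (v in v_hwe) {
    obs <- !is.na(d[, v])
    # heterozygote excess: ~95% hets at a common allele frequency
    repeat {
      d[obs, v] <- ifelse(runif(sum(obs)) < 0.95, 1L,
                          sample(c(0L, 2L), sum(obs), TRUE))
      hc <- d[obs, v]
      if (hwe_exact_test(sum(hc == 0), sum(hc == 1), sum(hc == 2)) < 1e-5)
        break
    }
  }
  # heterozygosity outliers avoid the engineered variant columns so those
  # artifacts stay exactly as constructed
  het_cols <- setdiff(vid, c(v_maf, v_hwe))
  for (s in s_het) {
    idx <- sample(het_cols, round(0.8 * length(het_cols)))
    d[s, idx] <- 1
  }
  list(genotypes = genotype_matrix(sid, g$variants, d),
       flags = list(variants_missing = v_miss, variants_low_maf = v_maf,
                    variants_hwe = v_hwe, samples_missing = s_miss,
                    samples_het = s_het))
}
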
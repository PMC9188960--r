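#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> genotype QC -> PRS scoring -> case/control
#' association -> three-group comparison -> pTDT -> rare-variant screen on
#' one simulated cohort, writing each stage's tables and a provenance YAML
#' (config, seed, package version, per-stage row counts) into `out_dir`.
#' A stage failure aborts later stages with a diagnostic naming the stage.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param thresholds a [qc_thresholds()].
#' @param p_max PRS inclusion p-value threshold.
#' @return invisible list of the in-memory stage results (`cohort`, `qc`,
#'   `prs`, `assoc`, `comparison`, `ptdt`, `screen`, `provenance`).
#' @export
run_pipeline <- function(config, out_dir, thresholds = qc_thresholds(),
                         p_max = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate", {
    effects <- simulate_true_effects(config)
    stats <- simulate_summary_stats(effects, config)
    cohort <- simulate_cohort(effects, config)
    trios <- simulate_trios(effects, config)
    ann <- simulate_annotations(cohort$samples, config)
    write_results_tsv(stats, file.path(out_dir, "summary_stats.tsv"))
    write_results_tsv(cohort$samples, file.path(out_dir, "samples.tsv"))
    write_genotypes_vcf(cohort$genotypes,
                        file.path(out_dir, "genotypes.vcf"))
    write_trios_fam(trios$pedigree, file.path(out_dir, "trios.fam"))
    write_results_tsv(ann$snv, file.path(out_dir, "annotations_snv.tsv"))
    write_results_tsv(ann$cnv, file.path(out_dir, "annotations_cnv.tsv"))
    list(effects = effects, stats = stats, cohort = cohort, trios = trios,
         ann = ann)
  })
  counts$simulate <- c(n_snps = nrow(sim$effects),
                       n_samples = nrow(sim$cohort$samples),
                       n_trios = nrow(sim$trios$trios))

  qc <- stage("qc", {
    fv <- filter_variants(sim$cohort$genotypes, thresholds)
    fs <- filter_samples(fv$genotypes, thresholds)
    kept <- ld_prune(fs$genotypes, thresholds$prune_window_snps,
                     thresholds$prune_step, thresholds$prune_r2)
    pruned <- subset_genotypes(fs$genotypes, variants = kept)
    pcs <- compute_pcs(pruned, thresholds$n_pcs)
    write_results_tsv(rbind(fv$report, fs$report),
                      file.path(out_dir, "qc_report.tsv"))
    list(genotypes = fs$genotypes, pcs = pcs,
         report = rbind(fv$report, fs$report))
  })
  counts$qc <- c(n_variants_kept = nrow(qc$genotypes$variants),
                 n_samples_kept = length(qc$genotypes$sample_ids))

  prs <- stage("score", {
    w <- harmonize_alleles(qc$genotypes, sim$stats)
    w <- select_snps(w, p_max)
    raw <- prs_score(qc$genotypes, w)
    z <- normalize_prs(raw)
    write_results_tsv(z, file.path(out_dir, "prs.tsv"))
    z
  })
  counts$score <- c(n_scored = nrow(prs))

  samp <- sim$cohort$samples
  samp <- samp[match(qc$genotypes$sample_ids, samp$id), , drop = FALSE]
  covars <- stage("covariates", {
    pcs <- qc$pcs[match(samp$id, rownames(qc$pcs)), , drop = FALSE]
    cbind(data.frame(sex = code_sex(samp$sex)), as.data.frame(pcs))
  })

  assoc <- stage("assoc", {
    z <- prs$z[match(samp$id, prs$id)]
    res <- fit_logistic(samp$phenotype == "case", z, covars)
    write_results_tsv(
      data.frame(beta = res$beta, se = res$se, z = res$z, p = res$p,
                 r2_nagelkerke = res$r2_nagelkerke,
                 n_cases = res$n_cases, n_controls = res$n_controls),
      file.path(out_dir, "association.tsv"))
    res
  })

  comparison <- stage("compare-groups", {
    groups <- ifelse(samp$phenotype == "control", "control",
                     ifelse(samp$screen_status == "positive",
                            "screen_pos", "screen_neg"))
    z <- prs$z[match(samp$id, prs$id)]
    cmp <- pairwise_group_comparison(z, groups, covars)
    write_results_tsv(cmp, file.path(out_dir, "group_comparison.tsv"))
    cmp
  })

  ptdt_res <- stage("ptdt", {
    tw <- harmonize_alleles(sim$trios$genotypes, sim$stats)
    tw <- select_snps(tw, p_max)
    tz <- normalize_prs(prs_score(sim$trios$genotypes, tw))
    res <- ptdt_stratified(sim$trios$trios, tz, sim$trios$samples)
    tab <- do.call(rbind, lapply(res, function(r)
      if (isTRUE(r$skipped))
        data.frame(stratum = r$stratum, n_trios = r$n_trios,
                   mean_deviation = NA_real_, t_stat = NA_real_,
                   p = NA_real_, skipped = TRUE)
      else data.frame(stratum = r$stratum, n_trios = r$n_trios,
                      mean_deviation = r$mean_deviation, t_stat = r$t_stat,
                      p = r$p, skipped = FALSE)))
    write_results_tsv(tab, file.path(out_dir, "ptdt.tsv"))
    res
  })

  screen <- stage("screen", {
    # screen all simulated cases: variant data exists independent of array QC
    cases <- sim$cohort$samples$id[sim$cohort$samples$phenotype == "case"]
    asg <- assign_screen_status(cases, sim$ann$snv, sim$ann$cnv)
    write_results_tsv(asg, file.path(out_dir, "screen_assignments.tsv"))
    asg
  })
  counts$screen <- c(n_positive = sum(screen$status == "positive"),
                     n_negative = sum(screen$status == "negative"),
                     n_unknown = sum(screen$status == "unknown"))

  provenance <- list(
    package = "epiprs",
    version = as.character(packageVersion("epiprs")),
    seed = config$seed,
    config = unclass(config),
    stage_counts = lapply(counts, as.list))
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))

  invisible(list(cohort = sim$cohort, qc = qc, prs = prs, assoc = assoc,
                 comparison = comparison, ptdt = ptdt_res, screen = screen,
                 provenance = provenance))
}

#' Replicate the multi-cohort study pattern on synthetic data
#'
#' Simulates several cohorts under a shared generating model (per-cohort
#' seeds derived from the base config), runs the case/control association
#' and the three-group comparison in each, and pools them by fixed-effects
#' meta-analysis — the per-cohort + pooled layout of a forest plot, and the
#' control / screen-positive / screen-negative contrast pattern.
#'
#' @param config a [sim_config()]; cohort `i` uses `seed + i`.
#' @param n_cohorts number of synthetic cohorts.
#' @param p_max PRS inclusion threshold.
#' @return list with `per_cohort` (data.frame of per-cohort association
#'   results), `meta` (fixed-effects `meta_result` for case vs control),
#'   `forest` (forest table), `contrasts` (data.frame of per-cohort pairwise
#'   results) and `contrast_meta` (named list of `meta_result` per contrast).
#' @export
replicate_study_pattern <- function(config, n_cohorts = 3, p_max = 0.5) {
  stopifnot(n_cohorts >= 2)
  per <- list(); cmp <- list()
  for (i in seq_len(n_cohorts)) {
    cfg <- config
    cfg$seed <- config$seed + i
    label <- sprintf("cohort%02d", i)
    effects <- simulate_true_effects(cfg)
    stats <- simulate_summary_stats(effects, cfg)
    cohort <- simulate_cohort(effects, cfg, cohort = label)
    w <- select_snps(harmonize_alleles(cohort$genotypes, stats), p_max)
    prs <- normalize_prs(prs_score(cohort$genotypes, w))
    z <- prs$z[match(cohort$samples$id, prs$id)]
    covars <- data.frame(sex = code_sex(cohort$samples$sex))
    res <- fit_logistic(cohort$samples$phenotype == "case", z, covars)
    per[[label]] <- res
    groups <- ifelse(cohort$samples$phenotype == "control", "control",
                     ifelse(cohort$samples$screen_status == "positive",
                            "screen_pos", "screen_neg"))
    pc <- pairwise_group_comparison(z, groups, covars)
    pc$cohort <- label
    cmp[[label]] <- pc
  }
  betas <- vapply(per, `[[`, numeric(1), "beta")
  ses <- vapply(per, `[[`, numeric(1), "se")
  meta <- meta_fixed(betas, ses)
  contrasts <- do.call(rbind, cmp)
  rownames(contrasts) <- NULL
  contrast_meta <- lapply(
    setNames(nm = unique(contrasts$contrast)),
    function(ct) {
      sub <- contrasts[contrasts$contrast == ct & !is.na(contrasts$beta), ]
      if (nrow(sub) == 0) return(NULL)
      meta_fixed(sub$beta, sub$se)
    })
  per_tab <- data.frame(
    cohort = names(per),
    beta = betas, se = ses,
    p = vapply(per, `[[`, numeric(1), "p"),
    r2_nagelkerke = vapply(per, `[[`, numeric(1), "r2_nagelkerke"),
    stringsAsFactors = FALSE)
  rownames(per_tab) <- NULL
  list(per_cohort = per_tab, meta = meta,
       forest = forest_table(per, meta),
       contrasts = contrasts, contrast_meta = contrast_meta)
}
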
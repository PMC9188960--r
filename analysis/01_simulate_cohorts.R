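#!/usr/bin/env Rscript
# Simulate the synthetic study: three DEE-like case/control cohorts under a
# shared liability-threshold model (polygenic background h2 = 0.3, prevalence
# 1%, rare dominant major-effect variant gamma = 3 carried by 0.3% of the
# population), plus an affected-proband trio cohort and annotated
# rare-variant tables with ground-truth screen labels.

library(epiprs)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

base <- sim_config(m_snps = 500, n_cases = 400, n_controls = 400,
                   n_trios = 171, n_discovery = 30000, seed = 20260921)

cat("== Simulating discovery GWAS summary statistics\n")
effects <- simulate_true_effects(base)
stats <- simulate_summary_stats(effects, base)
write_results_tsv(stats, file.path(out, "summary_stats.tsv"))
cat(sprintf("   %d SNPs; realised h2 = %.4f\n", nrow(effects),
            sum(2 * effects$maf * (1 - effects$maf) * effects$effect^2)))

for (i in 1:3) {
  cfg <- base
  cfg$seed <- base$seed + i
  label <- sprintf("cohort%02d", i)
  cat("== Simulating", label, "\n")
  co <- simulate_cohort(effects, cfg, cohort = label)
  ann <- simulate_annotations(co$samples, cfg)
  write_genotypes_vcf(co$genotypes,
                      file.path(out, paste0(label, "_genotypes.vcf")))
  write_results_tsv(co$samples, file.path(out, paste0(label, "_samples.tsv")))
  write_results_tsv(ann$snv, file.path(out, paste0(label, "_snv.tsv")))
  write_results_tsv(ann$cnv, file.path(out, paste0(label, "_cnv.tsv")))
  cat(sprintf("   %d cases (%d screen-positive), %d controls\n",
              cfg$n_cases, sum(co$samples$screen_status %in% "positive"),
              cfg$n_controls))
}

cat("== Simulating affected-proband trios (CENet-scale, n = 171)\n")
tr <- simulate_trios(effects, base)
write_genotypes_vcf(tr$genotypes, file.path(out, "trio_genotypes.vcf"))
write_trios_fam(tr$pedigree, file.path(out, "trios.fam"))
write_results_tsv(tr$samples, file.path(out, "trio_samples.tsv"))
cat(sprintf("   %d trios; %d screen-positive children\n",
            nrow(tr$trios), sum(tr$samples$screen_status %in% "positive")))

cat("Done: inputs written under", out, "\n")
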
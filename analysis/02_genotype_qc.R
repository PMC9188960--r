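#!/usr/bin/env Rscript
# Genotype QC on the first simulated cohort, after injecting known
# artifacts: low-call-rate and rare variants, HWE-violating variants,
# low-call-rate samples and heterozygosity outliers. Verifies that the
# filter cascade removes exactly the injected problems, then LD-prunes and
# computes ancestry PCs.

library(epiprs)

geno <- read_genotypes_vcf("results/sim/cohort01_genotypes.vcf")
cat("Input:", length(geno$sample_ids), "samples x", nrow(geno$variants),
    "variants\n")

art <- inject_qc_artifacts(geno, variant_missing_rate = 0.03,
                           low_maf_rate = 0.02, hwe_violation_rate = 0.01,
                           sample_missing_rate = 0.01,
                           het_outlier_rate = 0.005, seed = 4)

fv <- filter_variants(art$genotypes)
fs <- filter_samples(fv$genotypes)
report <- rbind(fv$report, fs$report)
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_results_tsv(report[, c("rule", "n_removed")], "results/qc/qc_report.tsv")
cat("QC removals by rule:\n")
print(report[, c("rule", "n_removed")], row.names = FALSE)

flagged <- unlist(art$flags)
removed <- setdiff(c(geno$variants$id, geno$sample_ids),
                   c(fs$genotypes$variants$id, fs$genotypes$sample_ids))
cat(sprintf("Injected artifacts recovered: %d / %d\n",
            sum(flagged %in% removed), length(flagged)))

kept <- ld_prune(fs$genotypes)
cat(sprintf("LD pruning on unlinked SNPs: %d / %d retained\n",
            length(kept), nrow(fs$genotypes$variants)))

pcs <- compute_pcs(fs$genotypes, 4)
outliers <- flag_pc_outliers(pcs)
cat(sprintf("PCA: %d components; %d outlier samples flagged\n",
            ncol(pcs), length(outliers)))
write_results_tsv(data.frame(id = rownames(pcs), pcs),
                  "results/qc/pcs.tsv")
cat("Done: QC report and PCs under results/qc\n")
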
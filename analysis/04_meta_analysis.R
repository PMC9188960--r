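#!/usr/bin/env Rscript
# Pool the per-cohort PRS log-odds by inverse-variance fixed effects,
# report heterogeneity (Q, I2), compare with the DerSimonian-Laird
# random-effects model, and emit forest-plot tables.

library(epiprs)

tab <- read.delim("results/assoc/association_per_cohort.tsv")
dir.create("results/meta", showWarnings = FALSE, recursive = TRUE)

fe <- meta_fixed(tab$beta, tab$se)
re <- meta_random_dl(tab$beta, tab$se)
cat("Fixed-effects model:\n"); print(fe)
cat("Random-effects (DerSimonian-Laird) model:\n"); print(re)

ft <- forest_table(tab, fe)
write_results_tsv(ft, "results/meta/forest_fixed.tsv")
write_results_tsv(forest_table(tab, re), "results/meta/forest_random.tsv")
write_results_tsv(
  data.frame(model = c("fixed", "random"),
             pooled_beta = c(fe$pooled_beta, re$pooled_beta),
             pooled_se = c(fe$pooled_se, re$pooled_se),
             p = c(fe$p, re$p), q = c(fe$q_stat, re$q_stat),
             i2 = c(fe$i2, re$i2), tau2 = c(fe$tau2, re$tau2)),
  "results/meta/meta_summary.tsv")
cat("Done: pooled estimates and forest tables under results/meta\n")
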
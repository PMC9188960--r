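# The liability-threshold generator: effects, summary stats, cohorts,
# trios, annotations, and QC artifact injection.

test_that("true effects hit the target heritability exactly and are seeded", {
  cfg <- small_config(m_snps = 1000, h2_liability = 0.3)
  eff <- simulate_true_effects(cfg)
  expect_equal(sum(2 * eff$maf * (1 - eff$maf) * eff$effect^2), 0.3,
               tolerance = 1e-6)
  expect_true(all(eff$maf >= cfg$maf_range[1] & eff$maf <= cfg$maf_range[2]))
  # h2 = 0 means a flat generator
  expect_true(all(simulate_true_effects(
    small_config(h2_liability = 0))$effect == 0))
  # determinism
  expect_identical(eff, simulate_true_effects(cfg))
})

test_that("summary statistics carry Wald-consistent noise", {
  cfg <- small_config(m_snps = 400)
  eff <- simulate_true_effects(cfg)
  ss <- simulate_summary_stats(eff, cfg)
  expect_equal(ss$p, 2 * pnorm(-abs(ss$beta / ss$se)), tolerance = 1e-12)
  # rarer SNP => larger se
  expect_true(all(diff(ss$se[order(eff$maf)]) <= 1e-12))
  # null calibration: under h2 = 0 about 5% of SNPs reach p < 0.05
  cfg0 <- small_config(m_snps = 10000, h2_liability = 0, seed = 300)
  ss0 <- simulate_summary_stats(simulate_true_effects(cfg0), cfg0)
  frac <- mean(ss0$p < 0.05)
  ci <- qbinom(c(0.0005, 0.9995), 10000, 0.05) / 10000
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("large discovery samples recover the true effects", {
  cfg_small <- small_config(m_snps = 200, n_discovery = 2000)
  cfg_big <- small_config(m_snps = 200, n_discovery = 2e7)
  eff <- simulate_true_effects(cfg_big)
  err_small <- simulate_summary_stats(eff, cfg_small)$beta - eff$effect
  err_big <- simulate_summary_stats(eff, cfg_big)$beta - eff$effect
  expect_lt(sd(err_big), sd(err_small) / 10)
  expect_equal(simulate_summary_stats(eff, cfg_big)$beta, eff$effect,
               tolerance = 1e-2)
})

test_that("cohort ascertainment yields the requested strata", {
  cfg <- small_config()
  co <- simulate_cohort(simulate_true_effects(cfg), cfg)
  s <- co$samples
  expect_equal(sum(s$phenotype == "case"), cfg$n_cases)
  expect_equal(sum(s$phenotype == "control"), cfg$n_controls)
  # screen status is the carrier flag among cases, NA for controls
  expect_true(all(is.na(s$screen_status[s$phenotype == "control"])))
  expect_equal(s$screen_status[s$phenotype == "case"] == "positive",
               s$carrier[s$phenotype == "case"])
  # cases lie above the liability threshold, controls below
  thr <- qnorm(1 - cfg$prevalence_k)
  expect_true(all(s$liability[s$phenotype == "case"] > thr))
  expect_true(all(s$liability[s$phenotype == "control"] <= thr))
  # no major-effect variant, no carriers, no screen-positives
  cfg0 <- small_config(gamma_major = 0, carrier_freq = 0)
  co0 <- simulate_cohort(simulate_true_effects(cfg0), cfg0)
  expect_false(any(co0$samples$screen_status %in% "positive"))
  # infeasible ascertainment reports its cap
  expect_error(
    simulate_cohort(simulate_true_effects(cfg), cfg, max_draws = 50),
    "50 draws")
})

test_that("unascertained draws match prevalence and liability variance", {
  # unascertained children double as population draws
  cfg <- sim_config(m_snps = 60, n_trios = 20000, ascertain_trios = FALSE,
                    prevalence_k = 0.05, gamma_major = 2, carrier_freq = 0.05,
                    h2_liability = 0.3, seed = 77)
  tr <- simulate_trios(simulate_true_effects(cfg), cfg)
  child <- tr$samples[!is.na(tr$samples$liability), ]
  frac <- mean(child$phenotype == "case")
  # P(case) = (1-f) K + f (1 - Phi(thr - gamma))
  thr <- qnorm(0.95)
  expected <- 0.95 * 0.05 + 0.05 * (1 - pnorm(thr - 2))
  ci <- qbinom(c(0.0005, 0.9995), nrow(child), expected) / nrow(child)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  # Var(L) = 1 + gamma^2 f (1 - f)
  expect_equal(var(child$liability), 1 + 4 * 0.05 * 0.95, tolerance = 0.05)
})

test_that("trio transmission is Mendelian and symmetric when unascertained", {
  cfg <- small_config(n_trios = 400, ascertain_trios = FALSE, seed = 9)
  eff <- simulate_true_effects(cfg)
  tr <- simulate_trios(eff, cfg)
  d <- tr$genotypes$dosages
  fa <- d[tr$trios$father_id, ]; mo <- d[tr$trios$mother_id, ]
  ch <- d[tr$trios$child_id, ]
  expect_true(all(ch %in% 0:2))
  # each child allele must come from the corresponding parent
  expect_true(all(ch[fa == 0 & mo == 0] == 0))
  expect_true(all(ch[fa == 2 & mo == 2] == 2))
  expect_true(all(ch[fa == 2 & mo == 0] == 1))
  expect_true(all(abs(ch - (fa + mo) / 2) <= 1))
  # transmission symmetry: mean child-minus-midparent PRS ~ 0
  w <- toy_weights(eff$id, eff$effect)
  prs <- prs_score(tr$genotypes, w)
  mp <- midparent_prs(tr$trios, prs, scale = "raw")
  dev <- prs$raw[match(tr$trios$child_id, prs$id)] - mp
  expect_lt(abs(mean(dev)) / (sd(dev) / sqrt(length(dev))), 4)
})

test_that("affected ascertainment shifts transmitted polygenic risk upward", {
  cfg <- small_config(m_snps = 200, n_trios = 500, n_discovery = 200,
                      ascertain_trios = TRUE, seed = 13)
  eff <- simulate_true_effects(cfg)
  tr <- simulate_trios(eff, cfg)
  expect_true(all(tr$samples$phenotype[match(tr$trios$child_id,
                                             tr$samples$id)] == "case"))
  w <- toy_weights(eff$id, eff$effect)
  prs <- prs_score(tr$genotypes, w)
  mp <- midparent_prs(tr$trios, prs, scale = "raw")
  dev <- prs$raw[match(tr$trios$child_id, prs$id)] - mp
  expect_gt(mean(dev) / (sd(dev) / sqrt(length(dev))), 3)
})

test_that("generator output is deterministic given seed and config", {
  cfg <- small_config(seed = 42)
  eff <- simulate_true_effects(cfg)
  a <- simulate_cohort(eff, cfg); b <- simulate_cohort(eff, cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$samples, b$samples)
  ta <- simulate_trios(eff, cfg); tb <- simulate_trios(eff, cfg)
  expect_identical(ta$genotypes$dosages, tb$genotypes$dosages)
  aa <- simulate_annotations(a$samples, cfg)
  ab <- simulate_annotations(b$samples, cfg)
  expect_identical(aa$snv, ab$snv)
})

test_that("annotations give each carrier one qualifying record and decoys fail", {
  cfg <- small_config(carrier_freq = 0.15, gamma_major = 2, seed = 21)
  co <- simulate_cohort(simulate_true_effects(cfg), cfg)
  ann <- simulate_annotations(co$samples, cfg)
  pos <- ann$truth$case_id[ann$truth$status == "positive"]
  expect_gt(length(pos), 0)
  qual <- rbind(
    data.frame(case_id = ann$snv$case_id, q = ann$snv$truth_qualifying),
    data.frame(case_id = ann$cnv$case_id, q = ann$cnv$truth_qualifying))
  n_qual <- tapply(qual$q, qual$case_id, sum)
  expect_true(all(n_qual[pos] == 1))
  expect_true(all(n_qual[setdiff(names(n_qual), pos)] == 0))
  # labelled decoys actually fail classification
  dec <- ann$snv[!is.na(ann$snv$decoy_class), ]
  expect_true(all(!classify_snv(dec)))
  # and qualifying records pass it
  expect_true(all(classify_snv(ann$snv[ann$snv$truth_qualifying, ])))
  if (any(ann$cnv$truth_qualifying))
    expect_true(all(classify_cnv(ann$cnv[ann$cnv$truth_qualifying, ])))
})

test_that("QC artifact injection produces exactly the targeted violations", {
  cfg <- small_config(m_snps = 100, n_cases = 200, n_controls = 200)
  g <- simulate_cohort(simulate_true_effects(cfg), cfg)$genotypes
  art <- inject_qc_artifacts(g, variant_missing_rate = 0.05,
                             low_maf_rate = 0.05, hwe_violation_rate = 0.03,
                             sample_missing_rate = 0.02,
                             het_outlier_rate = 0.01, seed = 3)
  gd <- art$genotypes
  fl <- art$flags
  # call rate dropped to ~95% on flagged variants
  cr <- gd$variants$call_rate[match(fl$variants_missing, gd$variants$id)]
  expect_true(all(cr < 0.98))
  expect_true(all(gd$variants$maf[match(fl$variants_low_maf,
                                        gd$variants$id)] < 0.01))
  for (v in fl$variants_hwe) {
    hc <- gd$dosages[, v]  # may carry NAs from sample-level missingness
    expect_lt(hwe_exact_test(sum(hc == 0, na.rm = TRUE),
                             sum(hc == 1, na.rm = TRUE),
                             sum(hc == 2, na.rm = TRUE)), 1e-5)
  }
  expect_true(all(rowMeans(!is.na(gd$dosages[fl$samples_missing, ,
                                             drop = FALSE])) < 0.98))
  # zero rates leave the matrix untouched
  clean <- inject_qc_artifacts(g, seed = 3)
  expect_identical(clean$genotypes$dosages, g$dosages)
})
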
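# Genotype QC: HWE exact test, variant/sample filters, LD pruning, PCA.

test_that("HWE exact test matches full enumeration on small tables", {
  expect_equal(hwe_exact_test(57, 14, 50), enum_hwe_p(57, 14, 50),
               tolerance = 1e-12)
  # modal heterozygote configuration gives p = 1
  expect_equal(hwe_exact_test(10, 20, 10), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)  # monomorphic convention
  # sweep of assorted configurations
  set.seed(1)
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(5:120, 1), c(0.3, 0.45, 0.25))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 enum_hwe_p(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3], midp = TRUE),
                 enum_hwe_p(cnt[1], cnt[2], cnt[3], midp = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("HWE p-values are calibrated on clean simulated genotypes", {
  set.seed(202)
  n <- 1000
  pv_mid <- pv_plain <- numeric(1200)
  for (i in 1:1200) {
    p <- runif(1, 0.05, 0.5)
    gcounts <- tabulate(rbinom(n, 2, p) + 1L, 3L)
    pv_plain[i] <- hwe_exact_test(gcounts[1], gcounts[2], gcounts[3])
    pv_mid[i] <- hwe_exact_test(gcounts[1], gcounts[2], gcounts[3],
                                midp = TRUE)
  }
  # mid-p is uniform under the null
  expect_gt(suppressWarnings(ks.test(pv_mid, "punif"))$p.value, 0.01)
  # the plain exact p is conservative, never anti-conservative
  expect_gt(suppressWarnings(
    ks.test(pv_plain, "punif", alternative = "greater"))$p.value, 0.01)
})

test_that("variant filters remove exactly the offending variants, in order", {
  set.seed(11)
  n <- 300
  d <- cbind(rbinom(n, 2, 0.3),          # clean
             rbinom(n, 2, 0.005),        # MAF 0.005
             rbinom(n, 2, 0.25),         # will get missingness
             rep(c(0, 1), n / 2))        # gross het excess
  d[1:12, 3] <- NA                       # call rate 0.96
  g <- toy_genotypes(d)
  res <- filter_variants(g)
  rep <- res$report
  expect_equal(rep$n_removed[rep$rule == "call_rate"], 1)
  expect_equal(rep$removed_ids[rep$rule == "call_rate"], "v003")
  expect_equal(rep$removed_ids[rep$rule == "maf"], "v002")
  expect_equal(rep$removed_ids[rep$rule == "hwe"], "v004")
  expect_equal(res$genotypes$variants$id, "v001")
  # conservation: removed + retained = input
  expect_equal(sum(rep$n_removed) + nrow(res$genotypes$variants), ncol(d))
  # idempotence
  res2 <- filter_variants(res$genotypes)
  expect_equal(sum(res2$report$n_removed), 0)
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
  # INFO rule applies only when INFO values exist
  g$variants$info <- c(0.95, 0.95, 0.95, 0.85)
  res3 <- filter_variants(g)
  expect_equal(res3$report$removed_ids[res3$report$rule == "info"], "")
  g$variants$info <- c(0.85, 0.95, 0.95, 0.95)
  # every variant now violates some rule
  expect_warning(res4 <- filter_variants(g), "all variants removed")
  expect_equal(res4$report$removed_ids[res4$report$rule == "info"], "v001")
})

test_that("clean simulated cohorts pass the variant filters untouched", {
  cfg <- small_config(n_cases = 300, n_controls = 300, maf_range = c(0.1, 0.5))
  g <- simulate_cohort(simulate_true_effects(cfg), cfg)$genotypes
  res <- filter_variants(g, qc_thresholds(hwe_p_min = 1e-7))
  expect_equal(sum(res$report$n_removed), 0)
})

test_that("sample filters catch injected low-call-rate and het outliers", {
  cfg <- small_config(m_snps = 200, n_cases = 150, n_controls = 150)
  g <- simulate_cohort(simulate_true_effects(cfg), cfg)$genotypes
  art <- inject_qc_artifacts(g, sample_missing_rate = 0.02,
                             het_outlier_rate = 0.01, seed = 8)
  res <- filter_samples(art$genotypes)
  rep <- res$report
  removed_cr <- strsplit(rep$removed_ids[rep$rule == "call_rate"], ",")[[1]]
  removed_het <- strsplit(rep$removed_ids[rep$rule == "heterozygosity"],
                          ",")[[1]]
  expect_setequal(removed_cr, art$flags$samples_missing)
  expect_true(all(art$flags$samples_het %in% removed_het))
  expect_equal(length(res$genotypes$sample_ids) + sum(rep$n_removed),
               length(g$sample_ids))
})

test_that("degenerate sample sets skip the heterozygosity rule", {
  d <- matrix(1, 5, 4)  # identical samples: SD of het = 0
  res <- filter_samples(toy_genotypes(d))
  expect_equal(sum(res$report$n_removed), 0)
  expect_warning(filter_samples(toy_genotypes(matrix(1, 2, 4))),
                 "fewer than 3")
})

test_that("LD pruning keeps unlinked variants and breaks correlated sets", {
  cfg <- small_config(m_snps = 120, n_cases = 250, n_controls = 250)
  g <- simulate_cohort(simulate_true_effects(cfg), cfg)$genotypes
  kept <- ld_prune(g, window_snps = 1000, step = 100, r2_max = 0.1)
  expect_gt(length(kept), 110)  # independent SNPs: r2 ~ 1/n, almost all kept
  # duplicated column: exactly one of the pair survives
  d <- g$dosages[, 1:10]
  d <- cbind(d, d[, 3])
  g2 <- toy_genotypes(d)
  kept2 <- ld_prune(g2, 1000, 100, 0.1)
  expect_equal(length(setdiff(g2$variants$id, kept2)), 1)
  expect_length(intersect(c("v003", "v011"), kept2), 1)
  # three mutually correlated variants leave one: verify by brute force
  base <- rbinom(400, 2, 0.4)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 2 - x[i]; x }
  set.seed(2)
  trio <- cbind(base, flip(base, 5), flip(base, 5))
  r2 <- cor(trio)^2
  expect_true(all(r2[upper.tri(r2)] > 0.5))
  kept3 <- ld_prune(toy_genotypes(trio), 1000, 100, 0.1)
  expect_length(kept3, 1)
})

test_that("PCA separates divergent populations and is orthogonal", {
  set.seed(33)
  m <- 150
  p1 <- runif(m, 0.1, 0.9); p2 <- pmin(0.95, pmax(0.05, p1 + runif(m, -0.4, 0.4)))
  d <- rbind(t(replicate(60, rbinom(m, 2, p1))),
             t(replicate(60, rbinom(m, 2, p2))))
  g <- toy_genotypes(d)
  pcs <- compute_pcs(g, 4)
  expect_equal(dim(pcs), c(120, 4))
  grp <- rep(c(1, 2), each = 60)
  between <- abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1]))
  within <- sd(c(pcs[grp == 1, 1] - mean(pcs[grp == 1, 1]),
                 pcs[grp == 2, 1] - mean(pcs[grp == 2, 1])))
  expect_gt(between, 3 * within)
  # orthogonality of the eigencomponents
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # requesting past the rank truncates with a warning
  tiny <- toy_genotypes(matrix(c(0, 1, 2, 0, 1, 2), 3, 2))
  expect_warning(p2c <- compute_pcs(tiny, 3), "rank")
  expect_lte(ncol(p2c), 2)
  # identical samples have rank 0
  expect_warning(p0 <- compute_pcs(toy_genotypes(matrix(1, 4, 3)), 2),
                 "0 PCs|rank")
  expect_equal(ncol(p0), 0)
})

test_that("PC outlier flagging is robust and nested across thresholds", {
  set.seed(4)
  pcs <- cbind(PC1 = rnorm(50), PC2 = rnorm(50))
  rownames(pcs) <- sprintf("s%02d", 1:50)
  expect_length(flag_pc_outliers(pcs, 6), 0)
  pcs2 <- pcs
  pcs2[7, 1] <- median(pcs[, 1]) + 10 * mad(pcs[, 1])
  expect_equal(flag_pc_outliers(pcs2, 6), "s07")
  # nesting: stricter limit flags a superset
  out8 <- flag_pc_outliers(pcs2, 8)
  out6 <- flag_pc_outliers(pcs2, 6)
  expect_true(all(out8 %in% out6))
  # zero MAD flags nothing
  flat <- cbind(PC1 = rep(0, 10), PC2 = rep(0, 10))
  rownames(flat) <- sprintf("s%02d", 1:10)
  expect_length(flag_pc_outliers(flat), 0)
})
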
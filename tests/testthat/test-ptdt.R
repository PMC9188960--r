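# Polygenic transmission disequilibrium test.

toy_trio_prs <- function(fa, mo, ch) {
  n <- length(fa)
  trios <- data.frame(father_id = sprintf("f%02d", 1:n),
                      mother_id = sprintf("m%02d", 1:n),
                      child_id = sprintf("c%02d", 1:n),
                      stringsAsFactors = FALSE)
  prs <- data.frame(id = c(trios$father_id, trios$mother_id, trios$child_id),
                    raw = c(fa, mo, ch), z = c(fa, mo, ch),
                    stringsAsFactors = FALSE)
  list(trios = trios, prs = prs)
}

test_that("mid-parent scores average the parents", {
  tp <- toy_trio_prs(c(1, 2, 0.5), c(-1, 2, 0.7), c(0, 0, 0))
  mp <- midparent_prs(tp$trios, tp$prs)
  expect_equal(unname(mp), c(0, 2, 0.6))
  # random fixture against direct arithmetic
  set.seed(9)
  fa <- rnorm(30); mo <- rnorm(30)
  tp2 <- toy_trio_prs(fa, mo, rnorm(30))
  expect_equal(unname(midparent_prs(tp2$trios, tp2$prs)), (fa + mo) / 2)
  # missing member is named
  tp$prs <- tp$prs[tp$prs$id != "m02", ]
  expect_error(midparent_prs(tp$trios, tp$prs), "c02")
})

test_that("pTDT t statistic follows the hand formula", {
  # children equal to mid-parents: no signal
  fa <- c(0.2, 0.9, -0.4, 1.1); mo <- c(-0.3, 0.1, 0.8, 0.2)
  tp <- toy_trio_prs(fa, mo, (fa + mo) / 2)
  res <- ptdt_test(tp$trios, tp$prs)
  expect_equal(res$mean_deviation, 0)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p, 1)
  # constant positive deviation: t = mean / (sd / sqrt(n)) on the
  # standardized deviations
  fa <- c(1, 0, -1); mo <- c(0.5, -0.5, 0)
  mp <- (fa + mo) / 2
  dev_raw <- c(0.2, 0.25, 0.15)
  tp2 <- toy_trio_prs(fa, mo, mp + dev_raw)
  res2 <- ptdt_test(tp2$trios, tp2$prs)
  dev <- dev_raw / sd(mp)
  expect_equal(res2$n_trios, 3)
  expect_equal(res2$df, 2)
  expect_equal(res2$mean_deviation, mean(dev), tolerance = 1e-12)
  expect_equal(res2$t_stat, mean(dev) / (sd(dev) / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(res2$p, 2 * pt(-abs(res2$t_stat), 2), tolerance = 1e-12)
  # degenerate inputs
  expect_error(ptdt_test(tp2$trios[1, ], tp2$prs), "at least 2")
  tp3 <- toy_trio_prs(c(1, 1), c(1, 1), c(2, 0))
  expect_error(ptdt_test(tp3$trios, tp3$prs), "zero variance")
})

test_that("pTDT is invariant to location and scale of the scores", {
  set.seed(18)
  fa <- rnorm(40); mo <- rnorm(40); ch <- (fa + mo) / 2 + rnorm(40, 0.1, 0.3)
  tp <- toy_trio_prs(fa, mo, ch)
  base <- ptdt_test(tp$trios, tp$prs)
  shift <- toy_trio_prs(fa + 5, mo + 5, ch + 5)
  expect_equal(ptdt_test(shift$trios, shift$prs)$t_stat, base$t_stat,
               tolerance = 1e-10)
  scaled <- toy_trio_prs(2.7 * fa, 2.7 * mo, 2.7 * ch)
  sres <- ptdt_test(scaled$trios, scaled$prs)
  expect_equal(sres$t_stat, base$t_stat, tolerance = 1e-10)
  expect_equal(sres$p, base$p, tolerance = 1e-10)
})

test_that("stratified pTDT partitions trios and skips small strata", {
  set.seed(25)
  fa <- rnorm(30); mo <- rnorm(30); ch <- (fa + mo) / 2 + rnorm(30, 0.2, 0.3)
  tp <- toy_trio_prs(fa, mo, ch)
  samples <- data.frame(id = tp$trios$child_id,
                        screen_status = rep(c("positive", "negative"),
                                            c(10, 20)),
                        stringsAsFactors = FALSE)
  res <- ptdt_stratified(tp$trios, tp$prs, samples)
  expect_equal(res$all$n_trios, 30)
  expect_equal(res$screen_pos$n_trios, 10)
  expect_equal(res$screen_neg$n_trios, 20)
  expect_equal(res$screen_pos$n_trios + res$screen_neg$n_trios,
               res$all$n_trios)
  # all-negative children: positive stratum skipped
  samples$screen_status <- "negative"
  res2 <- ptdt_stratified(tp$trios, tp$prs, samples)
  expect_true(isTRUE(res2$screen_pos$skipped))
  expect_equal(res2$screen_neg$n_trios, 30)
})

test_that("ascertained simulation shows over-transmission in both strata", {
  cfg <- sim_config(m_snps = 200, n_trios = 250, n_discovery = 200,
                    h2_liability = 0.3, gamma_major = 0, carrier_freq = 0.35,
                    ascertain_trios = TRUE, seed = 61)
  eff <- simulate_true_effects(cfg)
  ss <- simulate_summary_stats(eff, cfg)
  tr <- simulate_trios(eff, cfg)
  w <- select_snps(harmonize_alleles(tr$genotypes, ss), 0.5)
  prs <- normalize_prs(prs_score(tr$genotypes, w))
  res <- ptdt_stratified(tr$trios, prs, tr$samples)
  expect_gt(res$all$mean_deviation, 0)
  expect_gt(res$screen_pos$mean_deviation, 0)
  expect_gt(res$screen_neg$mean_deviation, 0)
  expect_lt(res$all$p, 0.01)
})
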
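# Allele harmonisation, SNP selection, clumping, scoring, normalisation.

test_that("allele harmonisation aligns, flips, complements and excludes", {
  v <- data.frame(id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
                  a1 = c("A", "C", "A", "A", "C", "A"),
                  a2 = c("G", "T", "C", "T", "G", "G"),
                  stringsAsFactors = FALSE)
  st <- data.frame(id = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs9"),
                   effect_allele = c("A", "T", "T", "A", "C", "A"),
                   other_allele = c("G", "C", "G", "T", "G", "G"),
                   beta = c(0.3, 0.2, 0.15, 0.1, 0.1, 0.1),
                   se = rep(0.05, 6), p = rep(0.01, 6),
                   stringsAsFactors = FALSE)
  w <- harmonize_alleles(v, st)
  # rs1 exact match; rs2 swapped (weight flipped); rs3 strand complement
  # (A/C vs T/G, same orientation); rs4 palindromic A/T; rs5 palindromic C/G;
  # rs6 unmatched id
  expect_equal(w$id, c("rs1", "rs2", "rs3"))
  expect_equal(w$weight, c(0.3, -0.2, 0.15))
  expect_equal(w$sign_flipped, c(FALSE, TRUE, FALSE))
  ex <- attr(w, "exclusions")
  expect_equal(unname(ex["palindromic"]), 2)
  expect_equal(unname(ex["unmatched_id"]), 1)
  expect_error(harmonize_alleles(v[4:5, ], st), "no variants")
})

test_that("flipping the counted allele negates the weight, preserving z", {
  set.seed(14)
  d <- matrix(rbinom(200, 2, 0.4), 20, 10)
  g <- toy_genotypes(d)
  w <- toy_weights(g$variants$id, rnorm(10))
  z1 <- normalize_prs(prs_score(g, w))$z
  # recode every variant to count the other allele
  g2 <- toy_genotypes(2 - d, a1 = rep("G", 10), a2 = rep("A", 10))
  w2 <- w; w2$counted_allele <- "G"; w2$weight <- -w$weight
  z2 <- normalize_prs(prs_score(g2, w2))$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("p-value thresholding is boundary-inclusive", {
  w <- toy_weights(c("a", "b", "c"), c(1, 2, 3), p = c(0.5, 0.51, 0.001))
  sel <- select_snps(w, 0.5)
  expect_setequal(sel$id, c("a", "c"))
  expect_equal(nrow(select_snps(w[0, ], 0.5)), 0)
})

test_that("clumping retains the lower-p member of correlated pairs", {
  set.seed(6)
  base <- rbinom(300, 2, 0.4)
  d <- cbind(base, base, rbinom(300, 2, 0.4))
  g <- toy_genotypes(d, pos = c(1000L, 2000L, 3000L))
  st <- data.frame(id = g$variants$id, p = c(0.2, 0.01, 0.5))
  kept <- clump(st, g, r2_max = 0.1, window_kb = 250)
  expect_setequal(kept, c("v002", "v003"))
  # unlinked SNPs all retained
  cfg <- small_config(m_snps = 60, n_cases = 200, n_controls = 200)
  gg <- simulate_cohort(simulate_true_effects(cfg), cfg)$genotypes
  ss <- simulate_summary_stats(simulate_true_effects(cfg), cfg)
  expect_length(clump(ss, gg), 60)
  expect_length(clump(ss[0, ], gg), 0)
})

test_that("scoring matches hand computation and the per-sample loop oracle", {
  g <- toy_genotypes(matrix(c(2, 1), 1, 2))
  w <- toy_weights(c("v001", "v002"), c(0.2, -0.1))
  expect_equal(prs_score(g, w)$raw, 0.3)
  expect_equal(prs_score(g, toy_weights(c("v001", "v002"), c(0, 0)))$raw, 0)
  # random 50 x 20 fixture with missingness against the loop oracle
  set.seed(77)
  d <- matrix(rbinom(1000, 2, runif(20, 0.1, 0.5)[rep(1:20, each = 50)]),
              50, 20)
  d[sample(1000, 30)] <- NA
  gr <- toy_genotypes(d)
  wr <- toy_weights(gr$variants$id, rnorm(20, 0, 0.2))
  expect_lt(max(abs(prs_score(gr, wr)$raw - loop_prs(gr, wr))), 1e-10)
  expect_error(prs_score(g, toy_weights("nope", 1)), "absent")
})

test_that("normalisation is exact, affine-invariant and set-dependent", {
  set.seed(15)
  raw <- data.frame(id = sprintf("s%02d", 1:40), raw = rnorm(40, 5, 3))
  z <- normalize_prs(raw)
  expect_equal(mean(z$z), 0, tolerance = 1e-8)
  expect_equal(sd(z$z), 1, tolerance = 1e-8)
  # affine transforms of the raw score leave z unchanged
  raw2 <- raw; raw2$raw <- 3 * raw$raw + 7
  expect_equal(normalize_prs(raw2)$z, z$z, tolerance = 1e-10)
  # normalising over a subset is an affine remap of the full-set z
  sub <- raw$id[1:15]
  zs <- normalize_prs(raw, normalisation_set = sub)$z
  fitcoef <- coef(lm(zs ~ z$z))
  expect_equal(unname(fitcoef[2] * z$z + fitcoef[1]), zs, tolerance = 1e-8)
  expect_error(normalize_prs(data.frame(id = c("a", "b"), raw = c(1, 1))),
               "degenerate")
})

test_that("PRS tracks true polygenic liability, more tightly with larger GWAS", {
  run_cor <- function(n_disc) {
    cfg <- small_config(m_snps = 200, n_cases = 250, n_controls = 250,
                        n_discovery = n_disc, seed = 55)
    eff <- simulate_true_effects(cfg)
    ss <- simulate_summary_stats(eff, cfg)
    co <- simulate_cohort(eff, cfg)
    w <- select_snps(harmonize_alleles(co$genotypes, ss), 0.5)
    prs <- normalize_prs(prs_score(co$genotypes, w))
    cor(prs$z[match(co$samples$id, prs$id)], co$samples$polygenic)
  }
  c_small <- run_cor(500)
  c_big <- run_cor(50000)
  expect_gt(c_small, 0)
  expect_gt(c_big, c_small)
})
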
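---
title: "Polygenic risk in presumed monogenic epilepsies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk in presumed monogenic epilepsies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprs)
```

## The scientific question

Developmental and epileptic encephalopathies (DEEs) and related epilepsies
with intellectual disability are usually treated as monogenic: a de novo
dominant variant of large effect explains the phenotype in up to half of
patients. `epiprs` implements the analysis chain used to ask whether common
genetic variation *also* contributes — whether polygenic risk scores (PRS)
built from common-epilepsy GWAS weights are elevated in such cases relative
to population controls, whether that elevation is present both in cases with
an identified damaging variant ("screen-positive") and without
("screen-negative"), and whether risk alleles are over-transmitted from
unaffected parents to affected children (pTDT).

The real cohorts behind those questions are access-controlled, so the
package pairs every analysis step with a generator that simulates cohorts
with the statistical structure the analysis assumes, carrying ground-truth
labels that make each step testable end to end.

## The generating model

Disease liability for individual $i$ is

$$L_i = \sum_j a_j (g_{ij} - 2p_j) \;+\; \gamma C_i \;+\; \varepsilon_i,
\qquad \varepsilon_i \sim N(0,\, 1-h^2),$$

with unlinked biallelic SNP dosages $g_{ij} \sim \mathrm{Bin}(2, p_j)$ in
Hardy–Weinberg equilibrium, per-allele effects $a_j$ rescaled so
$\sum_j 2p_j(1-p_j)a_j^2 = h^2$ exactly, a rare dominant major-effect
carrier flag $C_i \sim \mathrm{Bernoulli}(f)$, and disease when
$L_i > \Phi^{-1}(1-K)$. The polygenic term is mean-centred so the threshold
sits at the prevalence quantile. Among cases, carriers are labelled
screen-positive and non-carriers screen-negative; controls have no screen
label. The marginal liability variance is $1 + \gamma^2 f(1-f)$, a
generator invariant the tests check.

Discovery GWAS summary statistics are emulated per SNP as
$\hat\beta_j = a_j + N(0, se_j^2)$ with
$se_j = 1/\sqrt{2p_j(1-p_j)\,n_\mathrm{disc}}$ and two-sided Wald p-values.
Trios draw parents from the population model; each parent transmits one of
its two alleles uniformly per SNP, and the major-effect variant arises *de
novo* in the child with probability $f$ (parents are never carriers),
matching the de novo dominant aetiology of DEEs. Affected-proband
ascertainment keeps trios whose child crosses the liability threshold.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `h2_liability` | 0.3 | SNP-heritability scale reported for common epilepsies; the tests also sweep \{0, 0.1, 0.3\} |
| `prevalence_k` | 0.01 | ~1% lifetime epilepsy risk; DEEs are far rarer, but smaller $K$ only deepens the rejection sampling without changing the mechanics |
| `gamma_major` | 3 | carrier penetrance $1-\Phi(\Phi^{-1}(0.99)-3) \approx 0.75$, a highly penetrant dominant variant |
| `carrier_freq` | 0.003 | yields a screen-positive fraction among cases near 0.18, matching the observed 460/2,569 |
| `maf_range` | [0.05, 0.5] | common variants, the PRS regime |
| `n_discovery` | 30,000 | discovery scale; per-SNP signal-to-noise is governed by $m/n_\mathrm{disc}$, see below |

The realised PRS strength is controlled by the ratio of SNP count to
discovery sample size: the squared correlation between the score and the
true polygenic liability is approximately $h^2 / (h^2 + m/n_\mathrm{disc})$.
A real epilepsy PRS spreads its signal over ~10^6 SNPs estimated from a
~4×10^4-sample GWAS; at desk scale we use hundreds-to-thousands of SNPs, so
the default configuration yields a much stronger score than the published
Nagelkerke $R^2$ of 0.08–3.3%. Tests that probe ordering and power use this
strong-score regime deliberately; nothing downstream depends on matching
the absolute published effect sizes, which derive from access-controlled
data.

## Ascertainment and the screen-positive stratum

One genuinely subtle property of the liability-threshold model: under
case ascertainment with a strongly penetrant major variant
($\gamma \gg 0$), carrier cases need far less polygenic liability to cross
the threshold than non-carrier cases, so the model *predicts lower* mean
polygenic scores in screen-positive than screen-negative cases — a collider
effect of conditioning on case status. The default generator shows exactly
that (the `analysis/03` driver prints it).

The published pattern — both strata elevated against controls and no
significant difference between them — corresponds to a regime where screen
status is effectively independent of the polygenic background (weak scores,
moderate penetrance, heterogeneous screens). The package reproduces that
pattern with the *shared-background* generator: $\gamma = 0$ with carrier
labels drawn at `carrier_freq = 0.18`, so both case strata literally share
one polygenic distribution. The three-group comparison then yields positive
log-odds for both strata against controls and a null pos-vs-neg contrast at
the Bonferroni-adjusted level — the inference level the three-way
comparison reports, since a raw p for an exactly null contrast is uniform.

## The analysis chain

**Genotype QC** applies, in fixed order, call rate < 98%, MAF < 1%,
HWE exact-test $p < 10^{-5}$, and imputation INFO < 0.9 (when INFO values
are present); each removed variant is attributed to the first rule it
fails, so reports are deterministic. Sample QC removes call rate < 98% then
heterozygosity beyond mean ± 3 SD. Dosages are hard-called by rounding for
HWE and heterozygosity; no ambiguity zone is used because array/imputed
dosages concentrate near integers and the synthetic data are hard calls.
HWE is computed on all samples (configurable in principle, but the cascade
here follows the single-filter design). LD pruning is the PLINK-style
unit-less window (1000 SNPs, step 100, $r^2 > 0.1$, lower-MAF member
removed); on the generator's unlinked SNPs it is an identity operation,
which makes the PRS oracle exact. PCs come from the eigendecomposition of
the variance-standardised relationship matrix $XX^\top/m$, scaled by
$\sqrt{\lambda}$, with the largest-magnitude loading forced positive.
PCA outlier removal — a visual step in practice — is automated as
median ± 6 robust SDs (1.4826·MAD) on PC1/PC2.

The exact HWE test enumerates heterozygote configurations conditional on
the allele counts via the standard recurrence. Its p-values are discrete
and conservative by construction, so they are *not* uniform under the null;
the calibration tests therefore check uniformity of the **mid-p** variant
(half weight on equally probable configurations, as in PLINK's midp mode)
and check one-sidedly that the plain p-value is never anti-conservative.
The filter itself uses the plain exact p at $10^{-5}$.

**PRS scoring** harmonises GWAS weights to the genotype's counted allele:
identical orientation keeps $\beta$, swapped alleles flip its sign, strand
complements are resolved before matching, and palindromic (A/T, C/G)
variants are dropped — without allele-frequency matching their strand is
unresolvable, and frequency matching is out of scope. SNPs with discovery
$p \le 0.5$ (boundary inclusive) enter the score
$\mathrm{raw}_i = \sum_j w_j d_{ij}$, with missing dosages mean-imputed per
variant (the standard scoring-tool default, and what keeps the loop oracle
simple). Scores are normalised to mean 0, SD 1 over cases and controls
jointly within each cohort. Clumping is available (greedy by ascending p
against a genotype reference) but off by default: the synthetic SNPs are
unlinked and real scores inherit clumping from the source GWAS.

**Association** is a maximum-likelihood logistic regression of case status
on the normalised score with sex and the top four PCs as covariates
(sex 1/2 numeric, pedigree convention; unknown sex mean-coded with a
warning). Wald p-values match standard GLM summaries. Nagelkerke pseudo-R²
rescales Cox–Snell against its maximum and is clipped to [0, 1].
Rank-deficient designs and quasi-complete separation raise errors rather
than returning divergent estimates. The three-group analysis is implemented
as three pairwise binomial fits with Bonferroni adjustment, oriented so a
positive log-odds always means "elevated PRS in the later-listed group"
(cases vs controls; screen-positive vs screen-negative). A single
simultaneous multinomial model with a max-t adjustment is a noted
alternative; the pairwise form was chosen because its contrast matrix is
fully specified and each fit is independently testable against oracles.

**Meta-analysis** pools per-cohort log-odds by inverse variance:
$w_i = 1/se_i^2$, Cochran's Q, $I^2 = \max(0, (Q-df)/Q) \cdot 100$ (zero
for one study or $Q = 0$). The random-effects comparison uses
DerSimonian–Laird $\tau^2$ — a deliberate, documented divergence from
REML defaults in standard software, chosen for its closed form, which the
tests verify by hand and cross-check against `metafor::rma.uni(method =
"DL")`.

**pTDT** standardises each trio's child-minus-mid-parent score by the SD of
the mid-parent scores within the analysed stratum and applies a two-sided
one-sample t-test. Per-stratum (rather than global) SD is used when
stratifying; location and scale invariance of the statistic make the
raw-vs-z-scale choice immaterial. Strata with fewer than two trios are
reported as skipped. When all deviations are identical the statistic is 0
(null) or signed infinity, not NaN.

**The qualifying screen** classifies SNVs as qualifying iff the gene is in
the dominant-acting epilepsy/ID panel AND the consequence is
loss-of-function or missense with MPC > 2 AND the variant is absent from
population databases AND seen at most 3 times in the dataset; missense
without an MPC score never qualifies. CNVs qualify by the literal OR:
length > 2 Mb (strict), epilepsy-gene/hotspot overlap, or overlap with a
pLI > 0.9 gene — the length-only clause is permissive, and the audit log
records which clause fired. Cases with variant data but no qualifying
record are screen-negative; cases absent from both tables are unknown,
mirroring the 190 unassignable cases in the published accounting. Panel
membership and database presence are boolean inputs: live database queries
are version-dependent and unreproducible.

## Numerical choices and problem sizes

Logistic fits run to a score tolerance of 1e-10 with a 100-iteration cap.
The HWE recurrence works on normalised probabilities with a 1e-10 relative
tie tolerance. PCs below a rank tolerance of
$\lambda_{\max} \cdot n \cdot \epsilon$ are dropped.

The seeded operating-characteristic studies use: type-I error of the
association, 2,000 replicates of 250+250 samples × 100 SNPs under
$h^2 = 0$ (sex as the only covariate — no stratification is simulated, so
PCs would model pure noise); type-I error of the pTDT, 2,000 replicates of
30 unascertained trios; heritability-ordering recovery, 10 runs of
2,000+2,000 samples × 300 SNPs over $h^2 \in \{0, 0.1, 0.3\}$; pTDT power,
25 replicates of 171 ascertained trios (the scale of the trio cohort in
the published accounting) at $h^2 = 0.3$. Both null rejection rates are
required to fall in [0.03, 0.07].

## What the generator does and does not emulate

It emulates: HWE genotypes, a polygenic liability with exact target
heritability, prevalence-threshold case status, a rare dominant
major-effect stratum, noisy discovery GWAS estimates, Mendelian
transmission with proband ascertainment, and annotation tables that
exercise every screening rule, including decoys violating exactly one rule
each.

It does not emulate: linkage disequilibrium (so pruning/clumping are
near-identity operations and PRS oracles are exact); population structure
beyond two-population PCA fixtures (so PC covariates absorb noise, not
confounding); X-linked or recessive inheritance; CNV coordinates;
annotation error or cohort-specific screen heterogeneity (the published
screens ranged from full ACMG review to purely bioinformatic rules). A
green suite therefore demonstrates correctness of the machinery on data
satisfying the model's assumptions, not robustness to the violations real
cohorts bring.

## Known limitations

The published cohort effect sizes are not reproducible here — they derive
from access-controlled data — so quantitative agreement is limited to the
cohort-accounting arithmetic; everything else is validated against oracles
and operating characteristics. The multinomial comparison and the
random-effects estimator intentionally differ from the original tooling as
documented above. Imputation, phasing, relatedness pruning, ACMG curation
and annotation are out of scope: their outputs are inputs here.
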
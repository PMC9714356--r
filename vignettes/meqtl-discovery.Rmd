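---
title: "meQTL discovery from methylation-array SNP probes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meQTL discovery from methylation-array SNP probes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlscan)
library(dplyr)
```

## The problem

Illumina HumanMethylation450 arrays carry, besides ~485,000 CpG probes, a
set of 65 SNP control probes intended for sample tracking; 62 of them target
biallelic variants. The beta signal of such a probe is the fraction of the
"methylated" channel, which for a SNP probe is really the fraction of one
allele: homozygotes sit near 0 or 1 and heterozygotes near 0.5, so the
signal forms three peaks and encodes a genotype. `meqtlscan` turns this
by-product into a small genotyping panel and asks, for every SNP-CpG
combination, whether methylation depends on genotype — a methylation
quantitative trait locus (meQTL) scan — with a case/control comparison to
find regulatory relationships present in only one group.

## Models and procedures

**Genotype calling.** Each probe's signal is clustered in one dimension by
k-means with centers initialized at 0.1, 0.5 and 0.9 and refined by Lloyd
iteration (convergence when the largest center shift is below 1e-6, cap 100
iterations). The fixed, peak-anchored initialization makes the caller fully
deterministic; a Gaussian mixture would model peak widths but adds nothing
at the separation these probes show, and its EM fit is initialization
sensitive. Empty clusters are legitimate (monomorphic or two-genotype
SNPs), which is why we iterate Lloyd by hand rather than calling a k-means
routine that treats them as failure. A sample further than
`max_cluster_distance` (default 0.2, half the inter-peak spacing) from its
nearest converged center is left uncalled. The homozygote cluster carrying
the rarer allele is designated minor and samples are coded by minor-allele
dosage: minor homozygote 2, heterozygote 1, other homozygote 0. At an
allele frequency of exactly 0.5 the high-signal cluster is kept minor — an
arbitrary but documented and deterministic tie-break.

**SNP quality control.** Three per-SNP filters, all strict inequalities, so
boundary values fail: MAF > 0.01, missing rate < 0.01, and Hardy-Weinberg
equilibrium exact-test p > 0.001. The HWE test is the exact conditional
test: given the observed allele counts, every compatible heterozygote count
is enumerated and the p-value sums the probabilities of tables at most as
probable as the one observed. The exact test (rather than chi-square) is
preferred because a 62-SNP panel gives no asymptotic comfort at rare
genotypes and the enumeration admits an independent brute-force oracle in
the tests. Missing codes are excluded from both MAF and HWE counts
(complete-case); HWE can optionally be restricted to control samples
(`hwe_samples`), with all-sample testing as the default.

**Association scan.** For a SNP $s$ and CpG $c$ in a sample stratum, we fit
ordinary least squares on the beta scale:

$$ \mathrm{beta}_{c,i} = \mu + \beta \, d_{s,i} + \gamma\,\mathrm{age}_i + \varepsilon_i $$

where $d \in \{0,1,2\}$ is minor-allele dosage. $\beta$ is the change in
methylation beta per minor-allele copy; significance is two-sided from a
t-distribution with $n-3$ degrees of freedom. Methylation is regressed
untransformed (no M-value logit), matching how the effect is interpreted —
"methylation decreased by 0.0x per allele" is a beta-scale statement. Age
enters untransformed as a single linear covariate. Missingness is handled
pairwise per SNP-CpG pair. Pairs with fewer than 4 complete cases, constant
dosage in the stratum, dosage collinear with age, or residuals at
rounding-noise scale are flagged (`status` column) rather than tested.

The scan is vectorized by the Frisch-Waugh decomposition: per SNP, dosage
and all complete-case CpG vectors are residualized against (intercept, age),
after which every slope, standard error and p-value is a column operation.
A per-pair reference path (`fit_pair()`) exists and the tests require the
two routes to agree to 1e-10.

**Multiple testing.** The family is *per SNP*: each SNP's set of testable
CpGs is adjusted by Benjamini-Hochberg step-up on its own, and a pair is
significant when its adjusted value satisfies q < alpha (strict; default
alpha 0.05). This per-feature family is a deliberate design: the scan asks
"which CpGs does this SNP regulate" 62 times, not one global question.
`fdr_scope = "global"` is available for the single-family alternative.
Flagged pairs carry no test and are excluded from the family size $m$. BH
(not BY, not q-value estimation) is the default reading of "FDR" and is
delegated to `stats::p.adjust`; a by-definition step-up oracle checks it in
the tests.

**Genomic classification.** A significant pair on the same chromosome
(labels compared after stripping a `chr` prefix, case-insensitively) is
*cis* when the SNP-CpG distance is strictly below the 1 Mb window and
*long-distance cis* otherwise; different chromosomes give *trans*. "Less
than 1 Mb" and "greater than 1 Mb" leave the exact boundary undefined; we
classify a distance of exactly 1 Mb as long-distance cis (cis requires
strict <), and the window is configurable. CpGs and SNPs are points (the
probe coordinate and the variant coordinate); no gene-body expansion is
attempted, and the two BED inputs must share a genome build — the package
is build-agnostic.

**Case/control comparison.** The scan is run separately in case and control
strata; the union of significant pairs is labeled `case_only`,
`control_only`, or `both` by which strata reached significance. No formal
interaction test is attempted — stratum-unique calls conflate effect
heterogeneity with power, which is inherent to the separate-scan design and
is why the calibration test below tolerates up to 10% spurious unique calls
for strong shared effects. Shared pairs with opposite effect signs are
flagged `opposite_direction`. Methylation differences between groups at
implicated CpGs use Welch's unequal-variance t-test ("t-test" alone is
underspecified; Welch is the safer default). When both groups are constant,
p is 1 for equal means by convention.

## The synthetic-data generator

`simulate_meqtl_dataset()` produces the whole input bundle with known
truth. Its defaults mirror the geometry of a blood-methylation case/control
cohort: 689 samples at case fraction 354/689, 62 SNP probes, minor-allele
frequencies uniform on an interval within (0, 0.5], uniform ages on
18–70 years.

- **Genotypes** are Hardy-Weinberg by construction (dosage ~ Binomial(2, f)).
- **Probe signal** is dosage/2 plus Gaussian noise (SD 0.03 by default —
  tight, well-separated peaks; the real noise model of these probes is not
  documented anywhere we know of, so peak-centered Gaussian is an explicit
  assumption), clipped to [0, 1], with a configurable missing rate.
- **Methylation** at CpG $c$ has a Beta(a, b) baseline (default rule: mean
  uniform on (0.1, 0.9), precision a+b uniform on (20, 100), i.e. residual
  SDs roughly 0.05–0.10, typical of array beta values away from the
  boundaries). The linear predictor adds planted per-allele effects
  (optionally only in case or only in control samples) and a per-CpG age
  slope (SD `age_effect_sd` per standardized age). Residual noise is
  Beta-distributed by moment matching — the linear predictor becomes the
  Beta mean at the baseline precision — so draws respect [0, 1] without a
  clipping step distorting effects; the expected value stays linear in
  dosage, so fitted slopes are unbiased for the planted deltas. A
  configuration whose linear predictor leaves [0, 1] on more than 1% of
  entries is refused at generation time.
- **Determinism**: one seed drives everything; identical configurations are
  bit-identical.

What the generator does *not* emulate: Infinium I/II chemistry and raw
IDAT intensities, probe cross-reactivity, batch effects, cell-type
composition, genotype-methylation confounding through ancestry, and the
bimodal near-boundary concentration of real 450K beta distributions.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to those artifacts — on
real data the usual EWAS covariates (cell counts, batch) would belong in
the regression, and the package deliberately keeps the covariate set to age
to match its analytic contract.

## Numerical choices

- Lloyd iteration tolerance 1e-6 on center shift; distance cutoff 0.2.
- OLS via QR; zero-residual detection at `rss <= 1e-24 * sum(y^2)`, flagged
  as `zero_residual_variance` instead of reporting an unstable t.
- HWE enumeration in log-space, shifted by the maximum before
  exponentiating; the "as probable as observed" comparison uses a 1e-12
  relative tolerance so ties are counted as ties.
- The attempted-pair count is kept as a double (62 x 485,512 = 30,101,744
  fits in an integer, but larger panels need not).
- The pipeline's run log contains versions, thresholds and stage counts but
  no timestamps, so reruns on identical inputs are byte-identical.

## Test problem sizes

The suite checks calibration and recovery at sizes a laptop handles in
seconds while keeping Monte-Carlo error far from the asserted margins: null
calibration at 20 SNPs x 500 CpGs, n = 300, 50 replicates (the expected
per-SNP family-wise discovery rate under BH at 0.05 is about 5%, asserted
below 10%); effect recovery at n = 2,000 and MAF 0.3 over 50 replicates
(per-replicate slope SE ~0.0024, so the mean over replicates is asserted
within ±0.005 of the planted −0.05); the HWE implementation is compared to
the enumeration oracle exhaustively for all genotype tables with n ≤ 50.

## Known limitations

- One covariate (age); no kinship, ancestry, cell-type or batch adjustment.
- Biallelic SNPs only; X/Y dosage is out of scope.
- Per-SNP BH controls FDR within each SNP's family, not study-wide.
- The stratified design cannot distinguish a group-specific effect from a
  power difference between strata; `case_only`/`control_only` labels are
  operational, not causal claims.
```{r pvals, fig.width = 5, fig.height = 3}
sim <- simulate_meqtl_dataset(meqtl_sim_config(
  n_samples = 300, n_snps = 6, n_cpgs = 200, seed = 1,
  effect_table = data.frame(snp_index = 1, cpg_index = 1,
                            delta_per_allele = -0.08, stratum = "all")))
scan <- meqtl_scan(sim$methylation, sim$genotype_truth, sim$samples, "all")
autoplot(scan)
```
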
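test_that("config validation rejects bad fields by name", {
  expect_error(meqtl_sim_config(n_samples = 5), "n_samples")
  expect_error(meqtl_sim_config(case_fraction = 1.2), "case_fraction")
  expect_error(meqtl_sim_config(allele_freq_range = c(0.6, 0.7)),
               "allele_freq_range")
  expect_error(meqtl_sim_config(missing_probe_rate = 1), "missing_probe_rate")
  expect_error(
    meqtl_sim_config(n_snps = 2, n_cpgs = 5, effect_table = data.frame(
      snp_index = 3, cpg_index = 1, delta_per_allele = 0.1, stratum = "all")),
    "effect_table")
  expect_error(
    meqtl_sim_config(n_snps = 2, n_cpgs = 5, effect_table = data.frame(
      snp_index = c(1, 1), cpg_index = c(2, 2),
      delta_per_allele = 0.1, stratum = "all")),
    "effect_table")
})

test_that("planted deltas that push expected beta out of range are refused", {
  cfg <- meqtl_sim_config(
    n_samples = 100, n_snps = 1, n_cpgs = 1,
    allele_freq_range = c(0.5, 0.5),
    baseline_beta_params = c(5, 45),   # baseline mean 0.1
    effect_table = data.frame(snp_index = 1, cpg_index = 1,
                              delta_per_allele = -0.4, stratum = "all"),
    seed = 3)
  expect_error(simulate_meqtl_dataset(cfg), "effect_table")
})

test_that("same seed and config give bit-identical datasets", {
  eff <- data.frame(snp_index = 1, cpg_index = 2,
                    delta_per_allele = -0.05, stratum = "case_only")
  a <- small_sim(seed = 11, effect_table = eff)
  b <- small_sim(seed = 11, effect_table = eff)
  expect_identical(a$snp_probes, b$snp_probes)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$genotype_truth$codes, b$genotype_truth$codes)
  expect_identical(a$samples, b$samples)
  c_ <- small_sim(seed = 12, effect_table = eff)
  expect_false(identical(a$methylation, c_$methylation))
})

test_that("all beta values are in range and masked probes are NA", {
  sim <- small_sim(seed = 2, missing_probe_rate = 0.2)
  expect_true(all(sim$methylation >= 0 & sim$methylation <= 1))
  pr <- sim$snp_probes
  expect_true(anyNA(pr))
  expect_true(all(pr[!is.na(pr)] >= 0 & pr[!is.na(pr)] <= 1))
})

test_that("truth table resolves ids in the generated matrices", {
  eff <- data.frame(snp_index = c(1, 3), cpg_index = c(2, 7),
                    delta_per_allele = c(-0.05, 0.04),
                    stratum = c("all", "control_only"))
  sim <- small_sim(seed = 5, effect_table = eff)
  expect_equal(nrow(sim$truth), 2)
  expect_true(all(sim$truth$snp_id %in% rownames(sim$genotype_truth$codes)))
  expect_true(all(sim$truth$cpg_id %in% rownames(sim$methylation)))
  null_sim <- small_sim(seed = 5)
  expect_equal(nrow(null_sim$truth), 0)
})

test_that("generated genotypes are Hardy-Weinberg distributed", {
  # 1,000 SNPs at n = 500: at least 99% should clear the HWE p > 0.001 gate
  sim <- simulate_meqtl_dataset(meqtl_sim_config(
    n_samples = 500, n_snps = 1000, n_cpgs = 1,
    missing_probe_rate = 0, seed = 17))
  p <- apply(sim$genotype_truth$codes, 1, function(x) {
    hwe_exact_p(sum(x == 2), sum(x == 1), sum(x == 0))
  })
  expect_gte(mean(p > 0.001), 0.99)
})

test_that("planted stratum effects shift methylation only in their stratum", {
  eff <- data.frame(snp_index = 1, cpg_index = 1,
                    delta_per_allele = -0.1, stratum = "case_only")
  sim <- simulate_meqtl_dataset(meqtl_sim_config(
    n_samples = 1200, n_snps = 2, n_cpgs = 4,
    allele_freq_range = c(0.4, 0.5), baseline_beta_params = c(25, 25),
    effect_table = eff, age_effect_sd = 0, missing_probe_rate = 0,
    seed = 23))
  d <- sim$genotype_truth$codes[1, ]
  y <- sim$methylation[1, ]
  case <- sim$samples$group == "case"
  slope_case <- coef(lm(y[case] ~ d[case]))[2]
  slope_ctrl <- coef(lm(y[!case] ~ d[!case]))[2]
  expect_lt(abs(slope_case - (-0.1)), 0.02)
  expect_lt(abs(slope_ctrl), 0.02)
})
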
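test_that("fit_pair reproduces an exact linear relationship", {
  fit <- fit_pair(c(0.10, 0.10, 0.20, 0.20, 0.30, 0.30),
                  c(0, 0, 1, 1, 2, 2), c(40, 50, 40, 50, 40, 50))
  expect_equal(fit$beta_hat, 0.1, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-12)  # residuals are zero
  expect_equal(fit$n_used, 6L)
})

test_that("fit_pair flags degenerate inputs instead of erroring", {
  # zero-variance response
  z <- fit_pair(rep(0.5, 8), rep(0:1, 4), seq(30, 65, 5))
  expect_equal(z$beta_hat, 0, tolerance = 1e-12)
  expect_false(z$status == "ok")
  # constant dosage
  cd <- fit_pair(runif(8), rep(1, 8), seq(30, 65, 5))
  expect_equal(cd$status, "degenerate_dosage")
  # dosage perfectly collinear with age
  co <- fit_pair(runif(8), rep(0:1, 4), 40 + 10 * rep(0:1, 4))
  expect_equal(co$status, "degenerate_dosage")
  # too few complete cases
  few <- fit_pair(c(0.1, 0.2, 0.3, NA, NA), c(0, 1, 2, 0, 1), rep(40, 5))
  expect_equal(few$status, "insufficient_data")
  expect_equal(few$n_used, 3L)
})

test_that("fit_pair matches the normal-equations oracle on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    d <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (var(d) == 0) next
    a <- runif(n, 20, 70)
    y <- runif(n)
    fit <- fit_pair(y, d, a)
    orc <- ols_oracle(y, d, a)
    expect_equal(fit$beta_hat, orc$beta_hat, tolerance = 1e-10)
    expect_equal(fit$se, orc$se, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-10)
  }
})

test_that("fit_pair drops missing samples pairwise", {
  set.seed(5)
  y <- runif(20); d <- rbinom(20, 2, 0.4); a <- runif(20, 20, 60)
  y[3] <- NA; d[7] <- NA
  keep <- !is.na(y) & !is.na(d)
  expect_equal(fit_pair(y, d, a),
               fit_pair(y[keep], d[keep], a[keep]))
})

test_that("vectorized scan equals per-pair fits to 1e-10", {
  sim <- small_sim(seed = 77, n_samples = 60, n_snps = 5, n_cpgs = 20,
                   missing_probe_rate = 0)
  sc <- meqtl_scan(sim$methylation, sim$genotype_truth, sim$samples, "all")
  rec <- tidy(sc)
  age <- sim$samples$age
  for (k in seq_len(nrow(rec))) {
    f <- fit_pair(sim$methylation[rec$cpg_id[k], ],
                  sim$genotype_truth$codes[rec$snp_id[k], ], age)
    expect_equal(rec$beta_hat[k], f$beta_hat, tolerance = 1e-10)
    expect_equal(rec$se[k], f$se, tolerance = 1e-10)
    expect_equal(rec$p_value[k], f$p_value, tolerance = 1e-10)
  }
})

test_that("scan attempts exactly n_snps x n_cpgs records", {
  sim <- small_sim(seed = 3, n_snps = 2, n_cpgs = 3)
  sc <- meqtl_scan(sim$methylation, sim$genotype_truth, sim$samples, "all")
  expect_equal(nrow(tidy(sc)), 6)
  expect_equal(glance(sc)$pairs_attempted, 6)
  expect_equal(scan_plan(62, 485512)$pairs_attempted, 30101744)
})

test_that("permuting sample order leaves every statistic unchanged", {
  sim <- small_sim(seed = 19, n_samples = 80, n_snps = 3, n_cpgs = 10)
  set.seed(1); perm <- sample(ncol(sim$methylation))
  g2 <- new_genotype_matrix(sim$genotype_truth$codes[, perm],
                            sim$genotype_truth$snp_meta)
  sc1 <- meqtl_scan(sim$methylation, sim$genotype_truth, sim$samples, "all")
  sc2 <- meqtl_scan(sim$methylation[, perm], g2,
                    sim$samples[perm, ], "all")
  expect_equal(tidy(sc1), tidy(sc2), tolerance = 1e-12)
})

test_that("scan errors when no samples are shared", {
  sim <- small_sim(seed = 4, n_snps = 2, n_cpgs = 3)
  meth2 <- sim$methylation
  colnames(meth2) <- paste0("X", colnames(meth2))
  expect_error(
    meqtl_scan(meth2, sim$genotype_truth, sim$samples, "all"),
    class = "meqtlscan_alignment_error")
})

test_that("per-SNP BH matches the step-up oracle", {
  rec <- tibble::tibble(
    snp_id = "s1", cpg_id = paste0("c", 1:4),
    p_value = c(0.001, 0.01, 0.02, 0.8), status = "ok")
  out <- per_snp_fdr(rec, alpha = 0.05)
  expect_equal(out$q_value, c(0.004, 0.02, 4 * 0.02 / 3, 0.8),
               tolerance = 1e-12)
  expect_equal(out$q_value, bh_oracle(rec$p_value), tolerance = 1e-12)
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))

  # m = 1: BH is the identity
  one <- per_snp_fdr(tibble::tibble(snp_id = "s", cpg_id = "c",
                                    p_value = 0.03, status = "ok"))
  expect_equal(one$q_value, 0.03)
  expect_true(one$significant)

  # all p = 1: nothing significant
  flat <- per_snp_fdr(tibble::tibble(snp_id = "s", cpg_id = paste0("c", 1:5),
                                     p_value = rep(1, 5), status = "ok"))
  expect_false(any(flat$significant))
})

test_that("BH families are per SNP and exclude flagged records", {
  set.seed(8)
  rec <- tibble::tibble(
    snp_id = rep(c("s1", "s2"), each = 6),
    cpg_id = rep(paste0("c", 1:6), 2),
    p_value = runif(12), status = "ok")
  rec$status[2] <- "degenerate_dosage"
  rec$p_value[2] <- NA
  out <- per_snp_fdr(rec)
  expect_true(is.na(out$q_value[2]))
  s1 <- rec$status == "ok" & rec$snp_id == "s1"
  expect_equal(out$q_value[s1], bh_oracle(rec$p_value[s1]), tolerance = 1e-12)
  s2 <- rec$snp_id == "s2"
  expect_equal(out$q_value[s2], bh_oracle(rec$p_value[s2]), tolerance = 1e-12)
  # q-values within a family are monotone in p after step-up
  ord <- order(out$p_value[s2])
  expect_true(all(diff(out$q_value[s2][ord]) >= -1e-15))

  glob <- per_snp_fdr(rec, fdr_scope = "global")
  ok <- rec$status == "ok"
  expect_equal(glob$q_value[ok], bh_oracle(rec$p_value[ok]), tolerance = 1e-12)
})

test_that("null pairs give uniform p-values", {
  # no planted effects: pool per-pair p-values over replicates
  p <- unlist(lapply(1:20, function(seed) {
    sim <- simulate_meqtl_dataset(meqtl_sim_config(
      n_samples = 100, n_snps = 2, n_cpgs = 25,
      baseline_beta_params = c(20, 20), missing_probe_rate = 0,
      seed = 1000 + seed))
    tidy(meqtl_scan(sim$methylation, sim$genotype_truth,
                    sim$samples, "all"))$p_value
  }))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
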
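test_that("Welch t-test matches the textbook formula", {
  out <- cpg_group_ttest(c(0.1, 0.2, 0.3, 0.4),
                         c("case", "case", "control", "control"))
  expect_equal(out$mean_diff, -0.2)
  # hand Welch: means 0.15 / 0.35, each var 0.005 with n = 2
  se <- sqrt(0.005 / 2 + 0.005 / 2)
  t_stat <- -0.2 / se
  df <- (0.005 / 2 + 0.005 / 2)^2 /
    ((0.005 / 2)^2 / 1 + (0.005 / 2)^2 / 1)
  expect_equal(out$ttest_p, 2 * pt(-abs(t_stat), df), tolerance = 1e-12)

  expect_equal(cpg_group_ttest(rep(c(0.2, 0.4), 4),
                               rep(c("case", "control"), each = 4))$mean_diff,
               0)
})

test_that("degenerate group inputs follow the stated conventions", {
  expect_error(cpg_group_ttest(c(0.1, 0.2, 0.3), c("case", "case", "control")),
               class = "meqtlscan_low_data_error")
  expect_equal(cpg_group_ttest(rep(0.4, 6),
                               rep(c("case", "control"), 3))$ttest_p, 1)
  zerovar <- cpg_group_ttest(rep(c(0.2, 0.6), each = 3),
                             rep(c("case", "control"), each = 3))
  expect_equal(zerovar$ttest_p, 0)
})

test_that("swapping group labels negates mean_diff, p unchanged", {
  set.seed(44)
  y <- runif(30)
  g <- sample(c("case", "control"), 30, replace = TRUE, prob = c(0.6, 0.4))
  a <- cpg_group_ttest(y, g)
  b <- cpg_group_ttest(y, ifelse(g == "case", "control", "case"))
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$ttest_p, b$ttest_p)
})

make_records <- function(q_by_pair, stratum) {
  tibble::tibble(
    snp_id = sub("-.*", "", names(q_by_pair)),
    cpg_id = sub(".*-", "", names(q_by_pair)),
    stratum = stratum,
    beta_hat = rep_len(c(-0.05, 0.04), length(q_by_pair)),
    q_value = unname(q_by_pair),
    significant = unname(q_by_pair) < 0.05,
    status = "ok")
}

test_that("categorize labels pairs by stratum-specific significance", {
  pairs <- c("s1-c1" = 0.001, "s1-c2" = 0.5, "s2-c1" = 0.01, "s2-c2" = 0.9)
  case <- make_records(pairs, "case")
  ctrl <- make_records(c("s1-c1" = 0.002, "s1-c2" = 0.01,
                         "s2-c1" = 0.6, "s2-c2" = 0.7), "control")
  out <- categorize_meqtls(case, ctrl)
  expect_equal(out$category[out$snp_id == "s1" & out$cpg_id == "c1"], "both")
  expect_equal(out$category[out$snp_id == "s1" & out$cpg_id == "c2"],
               "control_only")
  expect_equal(out$category[out$snp_id == "s2" & out$cpg_id == "c1"],
               "case_only")
  expect_equal(nrow(out), 3)  # s2-c2 significant nowhere
  # partition: categories tile the union of significant pairs
  expect_equal(sum(table(out$category)), nrow(out))
  # sorted output
  expect_equal(out, dplyr::arrange(out, snp_id, cpg_id))
})

test_that("opposite-direction shared pairs are flagged", {
  case <- make_records(c("s1-c1" = 0.001), "case")
  ctrl <- make_records(c("s1-c1" = 0.001), "control")
  ctrl$beta_hat <- -case$beta_hat
  out <- categorize_meqtls(case, ctrl)
  expect_equal(out$category, "both")
  expect_true(out$opposite_direction)
  same <- categorize_meqtls(case, case)
  expect_false(same$opposite_direction)
})

test_that("mismatched universes raise an alignment error", {
  case <- make_records(c("s1-c1" = 0.001), "case")
  ctrl <- make_records(c("s9-c9" = 0.001), "control")
  expect_error(categorize_meqtls(case, ctrl),
               class = "meqtlscan_alignment_error")
})

test_that("planted shared and case-only effects are recovered with labels", {
  eff <- dplyr::bind_rows(
    tibble::tibble(snp_index = 1:5, cpg_index = 1:5,
                   delta_per_allele = -0.08, stratum = "all"),
    tibble::tibble(snp_index = 6:8, cpg_index = 6:8,
                   delta_per_allele = -0.08, stratum = "case_only"))
  hits <- lapply(1:3, function(seed) {
    sim <- simulate_meqtl_dataset(meqtl_sim_config(
      n_samples = 2000, n_snps = 8, n_cpgs = 30,
      allele_freq_range = c(0.3, 0.5), baseline_beta_params = c(25, 25),
      effect_table = eff, missing_probe_rate = 0, seed = 500 + seed))
    case <- meqtl_scan(sim$methylation, sim$genotype_truth, sim$samples,
                       "case")
    ctrl <- meqtl_scan(sim$methylation, sim$genotype_truth, sim$samples,
                       "control")
    calls <- differential_meqtls(case, ctrl, sim$methylation, sim$samples)
    merged <- dplyr::inner_join(calls, sim$truth,
                                by = c("snp_id", "cpg_id"))
    ok_shared <- sum(merged$stratum == "all" & merged$category == "both")
    ok_case <- sum(merged$stratum == "case_only" &
                     merged$category == "case_only")
    c(ok_shared + ok_case, nrow(eff))
  })
  recovered <- vapply(hits, `[`, numeric(1), 1)
  expect_true(all(recovered >= 7))
})
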
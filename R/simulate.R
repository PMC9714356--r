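#' Simulate a synthetic methylation-array meQTL dataset
#'
#' Generates, with known planted truth, everything the pipeline consumes:
#' a SNP-probe signal matrix (three peaks at 0, 0.5 and 1 plus Gaussian
#' noise, clipped to [0, 1], with a configurable missing rate), the true
#' minor-allele dosage matrix behind it, a CpG methylation beta matrix with
#' Beta-distributed residual noise around a linear predictor (baseline +
#' planted dosage effects + age slope), a sample table with case/control
#' labels and ages, and a truth table of the planted effects.
#'
#' Genotypes are drawn per SNP under Hardy-Weinberg equilibrium: dosage ~
#' Binomial(2, f) with the minor-allele frequency f drawn uniformly from
#' `allele_freq_range`. Residual CpG noise is Beta-distributed via moment
#' matching — the linear predictor becomes the Beta mean and the baseline
#' precision (shape1 + shape2) is retained — so values stay in [0, 1]
#' without clipping dominating. Planted `case_only` / `control_only` effects
#' multiply the dosage term by the group indicator.
#'
#' @param config A [meqtl_sim_config()] object.
#' @return A list of class `meqtl_sim_data` with elements
#'   \describe{
#'     \item{snp_probes}{SNPs x samples matrix of probe beta signal, `NA`
#'       for masked entries.}
#'     \item{genotype_truth}{A `genotype_matrix`: the generating dosage codes
#'       and SNP metadata (id, chrom, pos, minor allele, call rate).}
#'     \item{methylation}{CpGs x samples matrix of methylation beta values.}
#'     \item{cpg_meta}{Tibble of CpG loci (`cpg_id`, `chrom`, `pos`).}
#'     \item{samples}{Tibble (`sample_id`, `group`, `age`).}
#'     \item{truth}{Tibble of planted effects
#'       (`snp_id`, `cpg_id`, `delta_per_allele`, `stratum`).}
#'   }
#'   Identical `config` (including seed) gives bit-identical output.
#' @export
#' @examples
#' sim <- simulate_meqtl_dataset(
#'   meqtl_sim_config(n_samples = 60, n_snps = 4, n_cpgs = 20, seed = 7)
#' )
#' dim(sim$methylation)
simulate_meqtl_dataset <- function(config) {
  if (!inherits(config, "meqtl_sim_config")) {
    config <- do.call(meqtl_sim_config, config)
  }
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  n <- config$n_samples
  n_snps <- config$n_snps
  n_cpgs <- config$n_cpgs

  sample_ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- sprintf("snp%03d", seq_len(n_snps))
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpgs))

  # sample metadata: Bernoulli group labels, uniform ages
  group <- ifelse(rbinom(n, 1, config$case_fraction) == 1, "case", "control")
  age <- runif(n, config$age_range[1], config$age_range[2])
  samples <- tibble::tibble(sample_id = sample_ids, group = group, age = age)

  # loci for annotation: features scattered over autosomes
  snp_meta <- tibble::tibble(
    snp_id = snp_ids,
    chrom = as.character(sample(1:22, n_snps, replace = TRUE)),
    pos = sample.int(2e8L, n_snps, replace = TRUE),
    minor_allele = "B",
    call_rate = NA_real_
  )
  cpg_meta <- tibble::tibble(
    cpg_id = cpg_ids,
    chrom = as.character(sample(1:22, n_cpgs, replace = TRUE)),
    pos = sample.int(2e8L, n_cpgs, replace = TRUE)
  )

  # HWE genotypes: minor-allele dosage ~ Binomial(2, f)
  maf <- runif(n_snps, config$allele_freq_range[1], config$allele_freq_range[2])
  codes <- t(vapply(maf, function(f) rbinom(n, 2L, f), integer(n)))
  dimnames(codes) <- list(snp_ids, sample_ids)

  # three-peaked probe signal with masking
  probes <- codes / 2 + rnorm(length(codes), sd = config$probe_noise_sd)
  probes <- pmin(pmax(probes, 0), 1)
  if (config$missing_probe_rate > 0) {
    mask <- runif(length(probes)) < config$missing_probe_rate
    probes[mask] <- NA_real_
  }
  dim(probes) <- dim(codes)
  dimnames(probes) <- dimnames(codes)
  snp_meta$call_rate <- 1 - rowMeans(is.na(probes))

  # baseline Beta parameters per CpG
  bp <- config$baseline_beta_params
  if (is.function(bp)) bp <- bp(n_cpgs)
  if (!is.matrix(bp) || nrow(bp) != n_cpgs || ncol(bp) != 2 || any(bp <= 0)) {
    validation_error("baseline_beta_params",
                     "sampling rule must return an n_cpgs x 2 positive matrix")
  }
  baseline_mean <- bp[, 1] / (bp[, 1] + bp[, 2])
  precision <- bp[, 1] + bp[, 2]

  # linear predictor on the beta scale
  z_age <- as.vector(scale(age))
  if (any(!is.finite(z_age))) z_age <- rep(0, n)  # constant-age degenerate
  age_slope <- rnorm(n_cpgs, 0, config$age_effect_sd)
  mu <- matrix(baseline_mean, n_cpgs, n) + outer(age_slope, z_age)

  eff <- config$effect_table
  if (nrow(eff) > 0) {
    ind_case <- as.numeric(group == "case")
    for (k in seq_len(nrow(eff))) {
      w <- switch(eff$stratum[k],
                  all = rep(1, n),
                  case_only = ind_case,
                  control_only = 1 - ind_case)
      mu[eff$cpg_index[k], ] <- mu[eff$cpg_index[k], ] +
        eff$delta_per_allele[k] * codes[eff$snp_index[k], ] * w
    }
  }

  clipped <- mean(mu < 0 | mu > 1)
  if (clipped > 0.01) {
    validation_error(
      "effect_table",
      sprintf("expected beta outside [0,1] for %.1f%% of entries (> 1%%); reduce planted deltas or age effect",
              100 * clipped)
    )
  }
  eps <- 1e-4
  mu <- pmin(pmax(mu, eps), 1 - eps)

  meth <- rbeta(length(mu), mu * precision, (1 - mu) * precision)
  dim(meth) <- dim(mu)
  dimnames(meth) <- list(cpg_ids, sample_ids)

  truth <- tibble::tibble(
    snp_id = snp_ids[eff$snp_index],
    cpg_id = cpg_ids[eff$cpg_index],
    delta_per_allele = eff$delta_per_allele,
    stratum = eff$stratum
  )

  structure(
    list(
      snp_probes = probes,
      genotype_truth = new_genotype_matrix(codes, snp_meta),
      methylation = meth,
      cpg_meta = cpg_meta,
      samples = samples,
      truth = truth,
      config = config
    ),
    class = "meqtl_sim_data"
  )
}

#' @export
print.meqtl_sim_data <- function(x, ...) {
  cat("<meqtl_sim_data>\n")
  cat(sprintf("  %d samples, %d SNP probes, %d CpGs, %d planted effects\n",
              nrow(x$samples), nrow(x$snp_probes), nrow(x$methylation),
              nrow(x$truth)))
  invisible(x)
}
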
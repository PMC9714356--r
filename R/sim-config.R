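#' Simulation configuration for synthetic meQTL datasets
#'
#' Describes a synthetic study emulating methylation-array meQTL data:
#' Hardy-Weinberg biallelic genotypes, a three-peaked SNP-probe beta signal,
#' Beta-distributed CpG methylation with additive per-minor-allele effects on
#' the beta scale (optionally restricted to the case or control stratum), a
#' linear age covariate effect, and case/control labels.
#'
#' Defaults mirror a blood-methylation case/control cohort on a 450K-style
#' array: 689 samples split 354 cases / 335 controls, 62 biallelic SNP probes,
#' allele frequencies spread over (0.05, 0.5], and probe noise tight enough
#' that the three genotype peaks stay visibly separated.
#'
#' @param n_samples Number of samples (>= 10).
#' @param case_fraction Proportion of case samples, in (0, 1).
#' @param n_snps Number of SNP probes.
#' @param n_cpgs Number of CpG sites.
#' @param allele_freq_range Length-2 range in (0, 0.5] from which each SNP's
#'   minor-allele frequency is drawn uniformly.
#' @param probe_noise_sd Beta-scale SD of the SNP-probe signal around its peak
#'   centers 0, 0.5 and 1.
#' @param baseline_beta_params Per-CpG Beta shape parameters for baseline
#'   methylation: a length-2 numeric `c(shape1, shape2)` used for every CpG, a
#'   two-column matrix with `n_cpgs` rows, or a function `function(n_cpgs)`
#'   returning such a matrix. The default rule draws a baseline mean uniformly
#'   in (0.1, 0.9) and a precision (shape1 + shape2) uniformly in (20, 100),
#'   giving residual beta-value SDs around 0.05-0.10.
#' @param effect_table Planted meQTL effects: a data frame with columns
#'   `snp_index`, `cpg_index`, `delta_per_allele` (change in methylation beta
#'   per minor-allele copy) and `stratum` (one of `"all"`, `"case_only"`,
#'   `"control_only"`). `NULL` means no planted effects.
#' @param age_range Length-2 positive range; ages are drawn uniformly.
#' @param age_effect_sd SD of the per-CpG age slope applied to standardized
#'   age, on the beta scale.
#' @param missing_probe_rate Proportion of SNP-probe entries masked as
#'   missing, in [0, 1).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   datasets.
#'
#' @return An object of class `meqtl_sim_config` (a validated list).
#' @seealso [simulate_meqtl_dataset()]
#' @export
#' @examples
#' cfg <- meqtl_sim_config(n_samples = 60, n_snps = 4, n_cpgs = 20, seed = 1)
meqtl_sim_config <- function(n_samples = 689,
                             case_fraction = 354 / 689,
                             n_snps = 62,
                             n_cpgs = 1000,
                             allele_freq_range = c(0.05, 0.5),
                             probe_noise_sd = 0.03,
                             baseline_beta_params = NULL,
                             effect_table = NULL,
                             age_range = c(18, 70),
                             age_effect_sd = 0.01,
                             missing_probe_rate = 0.005,
                             seed = 1L) {
  chk_count <- function(x, field, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != as.integer(x)) {
      validation_error(field, sprintf("must be a single integer >= %d", min))
    }
    as.integer(x)
  }
  n_samples <- chk_count(n_samples, "n_samples", min = 10)
  n_snps <- chk_count(n_snps, "n_snps")
  n_cpgs <- chk_count(n_cpgs, "n_cpgs")

  if (!is.numeric(case_fraction) || length(case_fraction) != 1 ||
      is.na(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    validation_error("case_fraction", "must be a proportion in (0, 1)")
  }
  if (!is.numeric(allele_freq_range) || length(allele_freq_range) != 2 ||
      any(is.na(allele_freq_range)) || allele_freq_range[1] <= 0 ||
      allele_freq_range[2] > 0.5 ||
      allele_freq_range[1] > allele_freq_range[2]) {
    validation_error("allele_freq_range",
                     "must be an increasing pair in (0, 0.5]")
  }
  if (!is.numeric(probe_noise_sd) || length(probe_noise_sd) != 1 ||
      is.na(probe_noise_sd) || probe_noise_sd < 0) {
    validation_error("probe_noise_sd", "must be a nonnegative number")
  }
  if (!is.numeric(age_range) || length(age_range) != 2 ||
      any(is.na(age_range)) || age_range[1] <= 0 ||
      age_range[1] > age_range[2]) {
    validation_error("age_range", "must be an increasing pair of positives")
  }
  if (!is.numeric(age_effect_sd) || length(age_effect_sd) != 1 ||
      is.na(age_effect_sd) || age_effect_sd < 0) {
    validation_error("age_effect_sd", "must be a nonnegative number")
  }
  if (!is.numeric(missing_probe_rate) || length(missing_probe_rate) != 1 ||
      is.na(missing_probe_rate) || missing_probe_rate < 0 ||
      missing_probe_rate >= 1) {
    validation_error("missing_probe_rate", "must be a proportion in [0, 1)")
  }
  seed <- chk_count(seed, "seed", min = 0)

  effect_table <- validate_effect_table(effect_table, n_snps, n_cpgs)
  baseline_beta_params <-
    validate_baseline_params(baseline_beta_params, n_cpgs)

  structure(
    list(
      n_samples = n_samples, case_fraction = case_fraction,
      n_snps = n_snps, n_cpgs = n_cpgs,
      allele_freq_range = allele_freq_range,
      probe_noise_sd = probe_noise_sd,
      baseline_beta_params = baseline_beta_params,
      effect_table = effect_table,
      age_range = age_range, age_effect_sd = age_effect_sd,
      missing_probe_rate = missing_probe_rate, seed = seed
    ),
    class = "meqtl_sim_config"
  )
}

validate_effect_table <- function(effect_table, n_snps, n_cpgs) {
  if (is.null(effect_table)) {
    return(tibble::tibble(
      snp_index = integer(), cpg_index = integer(),
      delta_per_allele = double(), stratum = character()
    ))
  }
  effect_table <- tibble::as_tibble(effect_table)
  needed <- c("snp_index", "cpg_index", "delta_per_allele", "stratum")
  if (!all(needed %in% names(effect_table))) {
    validation_error("effect_table",
                     paste("must have columns", paste(needed, collapse = ", ")))
  }
  if (nrow(effect_table) == 0) return(effect_table[needed])
  if (any(effect_table$snp_index < 1 | effect_table$snp_index > n_snps) ||
      any(effect_table$cpg_index < 1 | effect_table$cpg_index > n_cpgs)) {
    validation_error("effect_table", "planted indices out of bounds")
  }
  key <- paste(effect_table$snp_index, effect_table$cpg_index)
  if (anyDuplicated(key)) {
    validation_error("effect_table", "planted (snp, cpg) pairs must be unique")
  }
  if (!all(effect_table$stratum %in% c("all", "case_only", "control_only"))) {
    validation_error("effect_table",
                     "stratum must be one of all, case_only, control_only")
  }
  if (!is.numeric(effect_table$delta_per_allele) ||
      any(!is.finite(effect_table$delta_per_allele))) {
    validation_error("effect_table", "delta_per_allele must be finite numeric")
  }
  effect_table[needed]
}

validate_baseline_params <- function(x, n_cpgs) {
  if (is.null(x)) {
    return(function(n) {
      m <- runif(n, 0.1, 0.9)
      phi <- runif(n, 20, 100)
      cbind(shape1 = m * phi, shape2 = (1 - m) * phi)
    })
  }
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 2) {
    if (any(x <= 0)) {
      validation_error("baseline_beta_params", "shapes must be positive")
    }
    return(matrix(rep(x, each = n_cpgs), ncol = 2,
                  dimnames = list(NULL, c("shape1", "shape2"))))
  }
  if (is.matrix(x) && ncol(x) == 2 && nrow(x) == n_cpgs) {
    if (any(x <= 0)) {
      validation_error("baseline_beta_params", "shapes must be positive")
    }
    colnames(x) <- c("shape1", "shape2")
    return(x)
  }
  validation_error(
    "baseline_beta_params",
    "must be a length-2 numeric, an n_cpgs x 2 matrix, or a function(n)"
  )
}

#' @export
print.meqtl_sim_config <- function(x, ...) {
  cat("<meqtl_sim_config>\n")
  cat(sprintf("  samples: %d (case fraction %.3f)\n",
              x$n_samples, x$case_fraction))
  cat(sprintf("  SNPs: %d  CpGs: %d  planted effects: %d\n",
              x$n_snps, x$n_cpgs, nrow(x$effect_table)))
  cat(sprintf("  probe noise SD: %g  missing probe rate: %g  seed: %d\n",
              x$probe_noise_sd, x$missing_probe_rate, x$seed))
  invisible(x)
}
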
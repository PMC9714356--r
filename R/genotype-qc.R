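#' SNP quality-control thresholds
#'
#' The three SNP-level filters applied before association scanning, all
#' strict inequalities: minor allele frequency above `maf_min`, missing rate
#' below `missing_max`, and Hardy-Weinberg exact-test p-value above
#' `hwe_p_min`. Boundary values fail.
#'
#' @param maf_min Minimum (exclusive) minor allele frequency. Default 0.01.
#' @param missing_max Maximum (exclusive) missing rate. Default 0.01.
#' @param hwe_p_min Minimum (exclusive) HWE exact p-value. Default 0.001.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, missing_max = 0.01,
                          hwe_p_min = 0.001) {
  vals <- c(maf_min = maf_min, missing_max = missing_max,
            hwe_p_min = hwe_p_min)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1 ||
        is.na(vals[[nm]]) || vals[[nm]] < 0 || vals[[nm]] > 1) {
      validation_error(nm, "must be a single value in [0, 1]")
    }
  }
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Minor allele frequency from dosage codes
#'
#' Counts minor-allele copies over non-missing samples and folds the
#' frequency to `min(f, 1 - f)`, so the result is invariant under a 0/2 code
#' flip and never exceeds 0.5.
#'
#' @param codes Dosage vector with entries in `{0, 1, 2, NA}`.
#' @return Folded allele frequency in [0, 0.5].
#' @export
#' @examples
#' compute_maf(c(0, 0, 1, 2))  # 0.375
compute_maf <- function(codes) {
  ok <- !is.na(codes)
  if (!any(ok)) {
    abort("all genotype codes missing: MAF undefined",
          class = "meqtlscan_undefined_maf_error")
  }
  if (any(!codes[ok] %in% c(0, 1, 2))) {
    validation_error("codes", "non-missing codes must be 0, 1 or 2")
  }
  f <- sum(codes[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability under Hardy-Weinberg equilibrium is at most that
#' of the observed genotype table.
#'
#' @param n_hom_minor,n_het,n_hom_major Nonnegative genotype counts
#'   (total >= 1).
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(0, 0, 100)  # 1: monomorphic, only one table possible
#' hwe_exact_p(5, 25, 70)
hwe_exact_p <- function(n_hom_minor, n_het, n_hom_major) {
  counts <- c(n_hom_minor, n_het, n_hom_major)
  if (any(counts < 0) || any(counts != round(counts))) {
    validation_error("counts", "genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) validation_error("counts", "total count must be >= 1")

  n_a <- 2 * n_hom_minor + n_het   # copies of one allele
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)

  # all heterozygote counts compatible with the allele counts (same parity)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het | allele counts) up to a constant:
  #   P propto n! / (nAA! nAa! naa!) * 2^het, with
  #   nAA = (n_minor - het)/2, naa = n - het - nAA
  n_aa <- (n_minor - hets) / 2
  n_bb <- n - hets - n_aa
  logp <- hets * log(2) - lgamma(n_aa + 1) - lgamma(hets + 1) - lgamma(n_bb + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)

  obs <- which(hets == n_het)
  if (length(obs) != 1) {
    validation_error("counts", "heterozygote count incompatible with allele counts")
  }
  # numerically tolerant 'at most as probable as observed'
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

#' Per-SNP quality-control report
#'
#' Computes MAF, missing rate and the HWE exact p-value for every SNP and
#' marks the SNPs that pass all three strict filters.
#'
#' @param genotypes A [new_genotype_matrix()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @param hwe_samples Optional character vector of sample ids on which the
#'   HWE test is computed (e.g. controls only); default all samples.
#' @return Tibble with columns `snp_id`, `maf`, `missing_rate`, `hwe_p`,
#'   `pass`, `fail_reasons` (comma-joined subset of `maf`, `missing`, `hwe`;
#'   empty when passing).
#' @export
snp_qc <- function(genotypes, thresholds = qc_thresholds(),
                   hwe_samples = NULL) {
  codes <- genotypes$codes
  hwe_codes <- codes
  if (!is.null(hwe_samples)) {
    hwe_codes <- codes[, colnames(codes) %in% hwe_samples, drop = FALSE]
  }
  purrr::map_dfr(seq_len(nrow(codes)), function(i) {
    x <- codes[i, ]
    missing_rate <- mean(is.na(x))
    maf <- if (all(is.na(x))) NA_real_ else compute_maf(x)
    h <- hwe_codes[i, ]
    h <- h[!is.na(h)]
    hwe_p <- if (length(h) == 0) NA_real_ else {
      n2 <- sum(h == 2); n1 <- sum(h == 1); n0 <- sum(h == 0)
      hwe_exact_p(n2, n1, n0)
    }
    fails <- c(
      if (is.na(maf) || !(maf > thresholds$maf_min)) "maf",
      if (!(missing_rate < thresholds$missing_max)) "missing",
      if (is.na(hwe_p) || !(hwe_p > thresholds$hwe_p_min)) "hwe"
    )
    tibble::tibble(
      snp_id = genotypes$snp_meta$snp_id[i],
      maf = maf, missing_rate = missing_rate, hwe_p = hwe_p,
      pass = length(fails) == 0,
      fail_reasons = paste(fails, collapse = ",")
    )
  })
}

#' Filter SNPs by quality control
#'
#' @inheritParams snp_qc
#' @return A list: `report` (the [snp_qc()] tibble) and `genotypes` (a
#'   `genotype_matrix` restricted to passing SNPs, original order kept).
#' @export
filter_snps <- function(genotypes, thresholds = qc_thresholds(),
                        hwe_samples = NULL) {
  report <- snp_qc(genotypes, thresholds, hwe_samples)
  keep <- which(report$pass)
  filtered <- new_genotype_matrix(
    genotypes$codes[keep, , drop = FALSE],
    genotypes$snp_meta[keep, , drop = FALSE]
  )
  list(report = report, genotypes = filtered)
}
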
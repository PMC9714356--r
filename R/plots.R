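#' Diagnostic plot of a stratified scan
#'
#' Histogram of the scan's p-values. A well-calibrated null scan is flat;
#' a spike near zero reflects true (or planted) signal.
#'
#' @param object A `meqtl_scan` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meqtl_scan
#' @export
autoplot.meqtl_scan <- function(object, bins = 40, ...) {
  rec <- dplyr::filter(object$records, .data$status == "ok")
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "p-value",
      y = "SNP-CpG pairs",
      title = sprintf("meQTL scan p-values (stratum: %s)", object$stratum)
    ) +
    ggplot2::theme_minimal()
}

#' Genotype-stratified methylation boxplot for one SNP-CpG pair
#'
#' The standard meQTL display: methylation beta values at one CpG, grouped
#' by genotype dosage and faceted by case/control status.
#'
#' @param methylation CpGs x samples beta matrix.
#' @param genotypes A `genotype_matrix`.
#' @param samples Sample table with `sample_id`, `group`.
#' @param snp_id,cpg_id The pair to plot.
#' @return A ggplot object.
#' @export
plot_meqtl_pair <- function(methylation, genotypes, samples, snp_id, cpg_id) {
  if (!snp_id %in% rownames(genotypes$codes)) {
    validation_error("snp_id", sprintf("'%s' not in genotype matrix", snp_id))
  }
  if (!cpg_id %in% rownames(methylation)) {
    validation_error("cpg_id", sprintf("'%s' not in methylation matrix", cpg_id))
  }
  shared <- intersect(colnames(methylation), colnames(genotypes$codes))
  df <- tibble::tibble(
    sample_id = shared,
    beta = methylation[cpg_id, shared],
    dosage = factor(genotypes$codes[snp_id, shared], levels = 0:2),
    group = samples$group[match(shared, samples$sample_id)]
  )
  df <- tidyr::drop_na(df, "dosage", "beta")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dosage, y = .data$beta)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(
      x = sprintf("%s minor-allele dosage", snp_id),
      y = sprintf("%s methylation beta", cpg_id)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
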
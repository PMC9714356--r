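#' Pipeline configuration
#'
#' Paths and parameters for [run_meqtl_pipeline()]. Input files use the
#' package's interchange formats (see [read_matrix_tsv()],
#' [read_sample_table()], [read_locus_bed()]).
#'
#' @param probes Path to the SNP-probe signal TSV (or `NULL` if
#'   `genotypes` is given).
#' @param genotypes Path to a pre-called genotype dosage TSV (optional;
#'   when given, genotype calling is skipped).
#' @param methylation Path to the methylation beta TSV.
#' @param samples Path to the sample table TSV.
#' @param snp_bed,cpg_bed Paths to BED-like locus annotation.
#' @param out_dir Output directory.
#' @param thresholds A [qc_thresholds()] object.
#' @param alpha FDR significance level in (0, 1).
#' @param window cis/trans distance threshold in bp.
#' @param fdr_scope `"per_snp"` or `"global"`.
#' @param max_cluster_distance Genotype-calling distance cutoff.
#' @param hwe_group Samples used for the HWE test: `"all"` (default) or
#'   `"control"`.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `meqtl_pipeline_config` list.
#' @export
meqtl_pipeline_config <- function(probes = NULL, genotypes = NULL,
                                  methylation, samples, snp_bed, cpg_bed,
                                  out_dir,
                                  thresholds = qc_thresholds(),
                                  alpha = 0.05, window = 1e6,
                                  fdr_scope = c("per_snp", "global"),
                                  max_cluster_distance = 0.2,
                                  hwe_group = c("all", "control"),
                                  seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  hwe_group <- match.arg(hwe_group)
  if (is.null(probes) && is.null(genotypes)) {
    validation_error("probes", "either probes or genotypes must be given")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    validation_error("alpha", "must lie in [0, 1)")
  }
  for (p in c(probes, genotypes, methylation, samples, snp_bed, cpg_bed)) {
    if (!file.exists(p)) {
      validation_error("paths", sprintf("input file not found: %s", p))
    }
  }
  structure(
    list(probes = probes, genotypes = genotypes, methylation = methylation,
         samples = samples, snp_bed = snp_bed, cpg_bed = cpg_bed,
         out_dir = out_dir, thresholds = thresholds, alpha = alpha,
         window = window, fdr_scope = fdr_scope,
         max_cluster_distance = max_cluster_distance,
         hwe_group = hwe_group, seed = as.integer(seed)),
    class = "meqtl_pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "meqtlscan_stage_error", parent = e)
  })
}

#' Run the full meQTL discovery pipeline
#'
#' Chains every stage: read inputs, call genotypes from the SNP-probe signal
#' (unless pre-called genotypes are supplied), apply quality control, scan
#' case and control strata with the age-adjusted regression and per-SNP FDR,
#' annotate significant pairs as cis / long-distance cis / trans, and
#' compare the strata into differential calls. Writes `qc.tsv`,
#' `scan_case.tsv`, `scan_control.tsv`, `annotated.tsv`,
#' `differential.tsv` and `run_log.txt` to the output directory.
#' The run log carries no timestamps, so reruns on identical inputs are
#' byte-identical.
#'
#' @param config A [meqtl_pipeline_config()] object.
#' @return Invisibly, a list of class `meqtl_pipeline`: `qc`, `scan_case`,
#'   `scan_control`, `annotated`, `differential`, `counts`.
#' @export
run_meqtl_pipeline <- function(config) {
  stopifnot(inherits(config, "meqtl_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("meqtlscan %s", as.character(utils::packageVersion("meqtlscan"))),
    sprintf("alpha=%g window=%g fdr_scope=%s seed=%d",
            config$alpha, config$window, config$fdr_scope, config$seed),
    sprintf("qc: maf_min=%g missing_max=%g hwe_p_min=%g hwe_group=%s",
            config$thresholds$maf_min, config$thresholds$missing_max,
            config$thresholds$hwe_p_min, config$hwe_group)
  )

  samples <- stage("read_samples", read_sample_table(config$samples))
  meth <- stage("read_methylation",
                read_matrix_tsv(config$methylation, "methylation"))
  snp_loci <- stage("read_snp_bed", read_locus_bed(config$snp_bed, "snp_id"))
  cpg_loci <- stage("read_cpg_bed", read_locus_bed(config$cpg_bed, "cpg_id"))

  geno <- stage("genotypes", {
    if (!is.null(config$genotypes)) {
      codes <- read_matrix_tsv(config$genotypes, "genotypes")
      meta <- snp_loci[match(rownames(codes), snp_loci$snp_id), ]
      meta$snp_id <- rownames(codes)
      new_genotype_matrix(codes, tibble::tibble(
        snp_id = rownames(codes),
        chrom = meta$chrom, pos = meta$pos,
        minor_allele = NA_character_,
        call_rate = 1 - rowMeans(is.na(codes))
      ))
    } else {
      probes <- read_matrix_tsv(config$probes, "probes")
      meta <- snp_loci[match(rownames(probes), snp_loci$snp_id), ]
      call_genotype_matrix(
        probes,
        snp_meta = tibble::tibble(snp_id = rownames(probes),
                                  chrom = meta$chrom, pos = meta$pos),
        max_cluster_distance = config$max_cluster_distance
      )
    }
  })
  log_lines <- c(log_lines, sprintf("snps_in=%d", nrow(geno$codes)))

  qc <- stage("qc", {
    hwe_samples <- if (config$hwe_group == "control") {
      samples$sample_id[samples$group == "control"]
    }
    filter_snps(geno, config$thresholds, hwe_samples)
  })
  readr::write_tsv(qc$report, file.path(config$out_dir, "qc.tsv"),
                   na = "NA", progress = FALSE)
  log_lines <- c(log_lines, sprintf("snps_pass_qc=%d", sum(qc$report$pass)))

  plan <- scan_plan(qc$genotypes, meth)
  log_lines <- c(log_lines, sprintf(
    "pairs_attempted_per_stratum=%s (%d SNPs x %d CpGs)",
    format(plan$pairs_attempted, scientific = FALSE), plan$n_snps, plan$n_cpgs))

  scan_case <- stage("scan_case",
    meqtl_scan(meth, qc$genotypes, samples, stratum = "case",
               alpha = config$alpha, fdr_scope = config$fdr_scope))
  scan_control <- stage("scan_control",
    meqtl_scan(meth, qc$genotypes, samples, stratum = "control",
               alpha = config$alpha, fdr_scope = config$fdr_scope))
  write_scan_tsv(scan_case, file.path(config$out_dir, "scan_case.tsv"))
  write_scan_tsv(scan_control, file.path(config$out_dir, "scan_control.tsv"))
  for (s in list(scan_case, scan_control)) {
    g <- glance(s)
    log_lines <- c(log_lines, sprintf(
      "stratum=%s n_samples=%d pairs_tested=%d pairs_significant=%d",
      g$stratum, g$n_samples, g$pairs_tested, g$pairs_significant))
  }

  differential <- stage("differential",
    differential_meqtls(scan_case, scan_control, meth, samples))
  annotated <- stage("annotate", {
    sig <- differential[c("snp_id", "cpg_id", "category")]
    names(sig)[3] <- "stratum_category"
    annotate_meqtls(sig, snp_loci, cpg_loci, window = config$window)
  })
  differential <- dplyr::left_join(
    differential,
    dplyr::rename(annotated[c("snp_id", "cpg_id", "category", "distance_bp")],
                  genomic_category = "category"),
    by = c("snp_id", "cpg_id")
  )
  readr::write_tsv(annotated, file.path(config$out_dir, "annotated.tsv"),
                   na = "NA", progress = FALSE)
  readr::write_tsv(differential,
                   file.path(config$out_dir, "differential.tsv"),
                   na = "NA", progress = FALSE)

  tally <- table(factor(differential$category,
                        levels = c("case_only", "control_only", "both")))
  log_lines <- c(log_lines, sprintf(
    "categories: case_only=%d control_only=%d both=%d",
    tally[["case_only"]], tally[["control_only"]], tally[["both"]]))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(structure(
    list(qc = qc$report, scan_case = scan_case, scan_control = scan_control,
         annotated = annotated, differential = differential,
         counts = list(
           snps_in = nrow(geno$codes), snps_pass_qc = sum(qc$report$pass),
           pairs_attempted = plan$pairs_attempted,
           significant_case = sum(scan_case$records$significant),
           significant_control = sum(scan_control$records$significant),
           categories = as.list(tally)
         )),
    class = "meqtl_pipeline"
  ))
}

#' @export
print.meqtl_pipeline <- function(x, ...) {
  cat("<meqtl_pipeline>\n")
  cat(sprintf("  SNPs: %d in, %d passed QC; %s pairs attempted per stratum\n",
              x$counts$snps_in, x$counts$snps_pass_qc,
              format(x$counts$pairs_attempted, big.mark = ",")))
  cat(sprintf("  significant pairs: %d (case), %d (control)\n",
              x$counts$significant_case, x$counts$significant_control))
  cat(sprintf("  categories: %d case_only, %d control_only, %d both\n",
              x$counts$categories$case_only, x$counts$categories$control_only,
              x$counts$categories$both))
  invisible(x)
}
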
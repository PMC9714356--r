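#' Welch t-test of methylation between case and control samples
#'
#' Two-sided Welch (unequal-variance) two-sample t-test of a CpG's beta
#' values between groups. When both groups have zero variance the test
#' statistic is undefined; by convention the p-value is 1 when the group
#' means are equal and 0 otherwise.
#'
#' @param methylation Per-sample beta vector.
#' @param groups Per-sample labels, `"case"` / `"control"`.
#' @return One-row tibble: `mean_case`, `mean_control`, `mean_diff`
#'   (case minus control), `ttest_p`.
#' @export
#' @examples
#' cpg_group_ttest(c(0.1, 0.2, 0.3, 0.4),
#'                 c("case", "case", "control", "control"))
cpg_group_ttest <- function(methylation, groups) {
  if (length(methylation) != length(groups)) {
    validation_error("groups", "must be aligned with methylation by sample")
  }
  ok <- !is.na(methylation) & !is.na(groups)
  x <- methylation[ok & groups == "case"]
  y <- methylation[ok & groups == "control"]
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least 2 non-missing values per group for the t-test",
          class = "meqtlscan_low_data_error")
  }
  mean_case <- mean(x); mean_control <- mean(y)
  if (var(x) == 0 && var(y) == 0) {
    p <- if (mean_case == mean_control) 1 else 0
  } else {
    p <- t.test(x, y, var.equal = FALSE)$p.value
  }
  tibble::tibble(mean_case = mean_case, mean_control = mean_control,
                 mean_diff = mean_case - mean_control, ttest_p = p)
}

#' Categorize meQTLs across case and control scans
#'
#' Takes the union of pairs significant in either stratified scan and labels
#' each as `case_only` (significant in the case stratum only),
#' `control_only`, or `both`. Pairs significant in both strata with
#' opposite effect signs are flagged `opposite_direction`.
#'
#' @param case_scan,control_scan `meqtl_scan` objects (or their record
#'   tibbles) computed on the same SNP/CpG universe with the same alpha.
#' @return Tibble sorted by (`snp_id`, `cpg_id`): `snp_id`, `cpg_id`,
#'   `category`, `beta_case`, `q_case`, `beta_control`, `q_control`,
#'   `opposite_direction`.
#' @export
categorize_meqtls <- function(case_scan, control_scan) {
  case_rec <- if (inherits(case_scan, "meqtl_scan")) case_scan$records else
    tibble::as_tibble(case_scan)
  ctrl_rec <- if (inherits(control_scan, "meqtl_scan")) control_scan$records else
    tibble::as_tibble(control_scan)

  key <- function(r) paste(r$snp_id, r$cpg_id, sep = "\r")
  if (!setequal(key(case_rec), key(ctrl_rec))) {
    abort("case and control scans cover different SNP-CpG universes",
          class = "meqtlscan_alignment_error")
  }

  case_sig <- case_rec[case_rec$significant, ]
  ctrl_sig <- ctrl_rec[ctrl_rec$significant, ]
  union_keys <- union(key(case_sig), key(ctrl_sig))
  if (length(union_keys) == 0) {
    return(tibble::tibble(
      snp_id = character(), cpg_id = character(), category = character(),
      beta_case = double(), q_case = double(), beta_control = double(),
      q_control = double(), opposite_direction = logical()
    ))
  }

  case_idx <- match(union_keys, key(case_rec))
  ctrl_idx <- match(union_keys, key(ctrl_rec))
  in_case <- union_keys %in% key(case_sig)
  in_ctrl <- union_keys %in% key(ctrl_sig)

  out <- tibble::tibble(
    snp_id = case_rec$snp_id[case_idx],
    cpg_id = case_rec$cpg_id[case_idx],
    category = dplyr::case_when(
      in_case & in_ctrl ~ "both",
      in_case ~ "case_only",
      TRUE ~ "control_only"
    ),
    beta_case = case_rec$beta_hat[case_idx],
    q_case = case_rec$q_value[case_idx],
    beta_control = ctrl_rec$beta_hat[ctrl_idx],
    q_control = ctrl_rec$q_value[ctrl_idx],
    opposite_direction = in_case & in_ctrl &
      !is.na(case_rec$beta_hat[case_idx]) &
      !is.na(ctrl_rec$beta_hat[ctrl_idx]) &
      sign(case_rec$beta_hat[case_idx]) !=
        sign(ctrl_rec$beta_hat[ctrl_idx])
  )
  dplyr::arrange(out, .data$snp_id, .data$cpg_id)
}

#' Differential meQTL calls with group methylation tests
#'
#' Combines [categorize_meqtls()] with a per-CpG Welch t-test of methylation
#' between cases and controls ([cpg_group_ttest()]) for every pair in the
#' union of significant discoveries.
#'
#' @inheritParams categorize_meqtls
#' @param methylation CpGs x samples beta matrix.
#' @param samples Sample table with `sample_id`, `group`.
#' @return Tibble: the [categorize_meqtls()] columns plus `mean_case`,
#'   `mean_control`, `mean_diff`, `ttest_p`.
#' @export
differential_meqtls <- function(case_scan, control_scan, methylation,
                                samples) {
  calls <- categorize_meqtls(case_scan, control_scan)
  if (nrow(calls) == 0) {
    return(tibble::tibble(
      calls,
      mean_case = double(), mean_control = double(),
      mean_diff = double(), ttest_p = double()
    ))
  }
  groups <- samples$group[match(colnames(methylation), samples$sample_id)]
  tt <- purrr::map_dfr(calls$cpg_id, function(cg) {
    cpg_group_ttest(methylation[cg, ], groups)
  })
  dplyr::bind_cols(calls, tt)
}
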
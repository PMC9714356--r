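#' Read a feature-by-sample TSV matrix
#'
#' The interchange dialect used throughout the package: tab-separated, a
#' header row of sample ids, the first column the feature id, rows =
#' features. Values are validated by `kind`: methylation and probe matrices
#' must lie in [0, 1] (or be missing), genotype matrices in `{0, 1, 2}`
#' (missing written as `NA`).
#'
#' @param path Path to the TSV file.
#' @param kind `"methylation"`, `"probes"` or `"genotypes"`.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, kind = c("methylation", "probes",
                                           "genotypes")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()  # first column: feature ids
  ), progress = FALSE, na = c("NA", ""))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("parse error in %s at line %d, column %d: %s",
                  path, prob$row[1] + 1, prob$col[1], prob$expected[1]),
          class = "meqtlscan_parse_error")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate feature ids in %s (e.g. '%s')",
                  path, ids[duplicated(ids)][1]),
          class = "meqtlscan_parse_error")
  }
  if (anyDuplicated(names(df)[-1])) {
    abort(sprintf("duplicate sample ids in %s", path),
          class = "meqtlscan_parse_error")
  }
  m <- as.matrix(df[-1])
  rownames(m) <- ids

  check <- if (kind == "genotypes") {
    !is.na(m) & !(m %in% c(0, 1, 2))
  } else {
    !is.na(m) & (m < 0 | m > 1)
  }
  if (any(check)) {
    idx <- which(check, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "out-of-range value %g in %s (feature '%s', sample '%s'): %s",
      m[idx[1], idx[2]], path, rownames(m)[idx[1]], colnames(m)[idx[2]],
      if (kind == "genotypes") "genotype codes must be 0/1/2"
      else "beta values must lie in [0, 1]"
    ), class = "meqtlscan_parse_error")
  }
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]: header row of sample ids, first column
#' the feature id, `NA` for missing, full precision.
#'
#' @param m Matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Header name of the feature id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' Tab-separated with header: `sample_id`, `group` (values `case` /
#' `control`), `age` (numeric).
#'
#' @param path Path to the TSV file.
#' @return Tibble with those three columns.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    age = readr::col_double()
  ), progress = FALSE)
  if (!all(c("sample_id", "group", "age") %in% names(df))) {
    abort(sprintf("%s must have columns sample_id, group, age", path),
          class = "meqtlscan_parse_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicate sample ids in %s", path),
          class = "meqtlscan_parse_error")
  }
  bad <- !df$group %in% c("case", "control")
  if (any(bad)) {
    abort(sprintf("invalid group '%s' in %s (line %d): must be case/control",
                  df$group[bad][1], path, which(bad)[1] + 1),
          class = "meqtlscan_parse_error")
  }
  df
}

#' Write a simulated dataset to a directory
#'
#' Writes every component of a [simulate_meqtl_dataset()] result in the
#' package's interchange formats: `probes.tsv`, `genotypes.tsv`,
#' `methylation.tsv` (feature x sample TSV), `samples.tsv`,
#' `snp_loci.bed` / `cpg_loci.bed` (0-based half-open BED), `truth.tsv`.
#'
#' @param sim A `meqtl_sim_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_meqtl_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "meqtl_sim_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$snp_probes, file.path(dir, "probes.tsv"), "snp_id")
  write_matrix_tsv(sim$genotype_truth$codes,
                   file.path(dir, "genotypes.tsv"), "snp_id")
  write_matrix_tsv(sim$methylation, file.path(dir, "methylation.tsv"),
                   "cpg_id")
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  write_locus_bed(sim$genotype_truth$snp_meta[c("snp_id", "chrom", "pos")],
                  file.path(dir, "snp_loci.bed"), "snp_id")
  write_locus_bed(sim$cpg_meta, file.path(dir, "cpg_loci.bed"), "cpg_id")
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Write scan records at full precision
#'
#' @param records Scan record tibble or `meqtl_scan` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(records, path) {
  if (inherits(records, "meqtl_scan")) records <- records$records
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}
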
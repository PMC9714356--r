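#' Classify SNP-CpG pairs as cis, long-distance cis, or trans
#'
#' A pair on the same chromosome with distance strictly below `window`
#' (default 1 Mb) is `cis`; on the same chromosome at or beyond `window` it
#' is `long_cis`; on different chromosomes it is `trans`. Chromosome labels
#' are compared case-insensitively after stripping an optional `"chr"`
#' prefix, so `"chr2"` and `"2"` match. Classification is symmetric in the
#' two loci; `distance_bp` is `NA` exactly when the pair is trans.
#'
#' @param pairs Data frame with columns `snp_chrom`, `snp_pos`, `cpg_chrom`,
#'   `cpg_pos` (positions 1-based).
#' @param window Distance threshold in bp (default 1e6).
#' @return The input tibble with `category` (`"cis"`, `"long_cis"`,
#'   `"trans"`) and `distance_bp` columns added.
#' @export
#' @examples
#' classify_pairs(data.frame(snp_chrom = "chr2", snp_pos = 100,
#'                           cpg_chrom = "2", cpg_pos = 500))
classify_pairs <- function(pairs, window = 1e6) {
  pairs <- tibble::as_tibble(pairs)
  needed <- c("snp_chrom", "snp_pos", "cpg_chrom", "cpg_pos")
  if (!all(needed %in% names(pairs))) {
    validation_error("pairs",
                     paste("must have columns", paste(needed, collapse = ", ")))
  }
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    validation_error("window", "must be a positive distance in bp")
  }
  same <- normalize_chrom(pairs$snp_chrom) == normalize_chrom(pairs$cpg_chrom)
  dist <- abs(pairs$snp_pos - pairs$cpg_pos)
  pairs$category <- dplyr::case_when(
    !same ~ "trans",
    dist < window ~ "cis",
    TRUE ~ "long_cis"
  )
  pairs$distance_bp <- ifelse(same, dist, NA_real_)
  pairs
}

normalize_chrom <- function(chrom) {
  if (any(is.na(chrom) | !nzchar(chrom))) {
    validation_error("chrom", "chromosome labels must be nonempty")
  }
  sub("^chr", "", tolower(as.character(chrom)))
}

#' Annotate scan records with genomic classification
#'
#' Joins SNP and CpG loci onto scan records and classifies each pair with
#' [classify_pairs()].
#'
#' @param records Scan record tibble (from [meqtl_scan()] / `tidy()`), or a
#'   `meqtl_scan` object.
#' @param snp_loci Tibble `snp_id`, `chrom`, `pos` (1-based).
#' @param cpg_loci Tibble `cpg_id`, `chrom`, `pos` (1-based).
#' @param window Distance threshold in bp.
#' @return The records with `snp_chrom`, `snp_pos`, `cpg_chrom`, `cpg_pos`,
#'   `category`, `distance_bp` columns added. Records whose loci are absent
#'   from the annotation get `NA` category.
#' @export
annotate_meqtls <- function(records, snp_loci, cpg_loci, window = 1e6) {
  if (inherits(records, "meqtl_scan")) records <- records$records
  records <- tibble::as_tibble(records)
  # keep a differential category out of the way of the genomic one
  if ("category" %in% names(records)) {
    names(records)[names(records) == "category"] <- "stratum_category"
  }
  snp_loci <- dplyr::rename(tibble::as_tibble(snp_loci)[c("snp_id", "chrom", "pos")],
                            snp_chrom = "chrom", snp_pos = "pos")
  cpg_loci <- dplyr::rename(tibble::as_tibble(cpg_loci)[c("cpg_id", "chrom", "pos")],
                            cpg_chrom = "chrom", cpg_pos = "pos")
  out <- dplyr::left_join(records, snp_loci, by = "snp_id")
  out <- dplyr::left_join(out, cpg_loci, by = "cpg_id")
  known <- !is.na(out$snp_chrom) & !is.na(out$cpg_chrom) &
    !is.na(out$snp_pos) & !is.na(out$cpg_pos)
  out$category <- NA_character_
  out$distance_bp <- NA_real_
  if (any(known)) {
    cls <- classify_pairs(out[known, c("snp_chrom", "snp_pos",
                                       "cpg_chrom", "cpg_pos")], window)
    out$category[known] <- cls$category
    out$distance_bp[known] <- cls$distance_bp
  }
  out
}

#' Read a BED-like locus annotation file
#'
#' Four tab-separated columns without header: chrom, start, end, feature_id,
#' with 0-based half-open coordinates. The internal 1-based position is
#' `start + 1`.
#'
#' @param path Path to the BED file.
#' @param id_col Name for the feature id column in the result (`"snp_id"` or
#'   `"cpg_id"`).
#' @return Tibble with the id column, `chrom`, `pos`.
#' @export
read_locus_bed <- function(path, id_col = "feature_id") {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "feature_id"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), feature_id = readr::col_character()
    ),
    progress = FALSE
  )
  if (any(bed$start < 0) || any(bed$end < bed$start)) {
    abort(sprintf("malformed BED intervals in %s", path),
          class = "meqtlscan_parse_error")
  }
  out <- tibble::tibble(id = bed$feature_id, chrom = bed$chrom,
                        pos = bed$start + 1)
  names(out)[1] <- id_col
  out
}

#' Write loci as a BED-like file
#'
#' @param loci Tibble with an id column, `chrom`, `pos` (1-based).
#' @param path Output path.
#' @param id_col Name of the id column in `loci`.
#' @return `path`, invisibly.
#' @export
write_locus_bed <- function(loci, path, id_col = names(loci)[1]) {
  bed <- tibble::tibble(
    chrom = loci$chrom,
    start = format(loci$pos - 1, scientific = FALSE, trim = TRUE),
    end = format(loci$pos, scientific = FALSE, trim = TRUE),
    feature_id = loci[[id_col]]
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
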
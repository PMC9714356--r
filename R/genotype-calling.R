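#' Genotype matrix container
#'
#' Bundles a SNPs x samples dosage matrix (entries 0/1/2 = copies of the
#' minor allele, `NA` = missing) with per-SNP metadata.
#'
#' @param codes Integer-valued matrix with entries in `{0, 1, 2, NA}`;
#'   rownames are SNP ids, colnames sample ids.
#' @param snp_meta Tibble with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `minor_allele`, `call_rate`.
#' @return An object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(codes, snp_meta) {
  stopifnot(is.matrix(codes))
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    validation_error("codes", "non-missing genotype codes must be 0, 1 or 2")
  }
  snp_meta <- tibble::as_tibble(snp_meta)
  if (nrow(snp_meta) != nrow(codes)) {
    validation_error("snp_meta", "must have one row per SNP")
  }
  if (is.null(rownames(codes)) && "snp_id" %in% names(snp_meta)) {
    rownames(codes) <- snp_meta$snp_id
  }
  structure(list(codes = codes, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d samples\n",
              nrow(x$codes), ncol(x$codes)))
  invisible(x)
}

#' Cluster a SNP probe's beta signal into genotype groups
#'
#' The beta signal of an array SNP probe forms three peaks near 0, 0.5 and 1,
#' corresponding to the two homozygotes and the heterozygote. Samples are
#' assigned to the three peaks by one-dimensional k-means with centers
#' initialized at 0.1, 0.5 and 0.9 and refined by Lloyd iteration until the
#' largest center shift is below 1e-6 (at most 100 iterations). Empty
#' clusters are allowed, so monomorphic and two-genotype SNPs are handled.
#' A sample further than `max_cluster_distance` from its nearest center is
#' set to missing.
#'
#' @param probe_signal Numeric vector of per-sample probe beta values in
#'   [0, 1]; `NA` allowed (stays missing). At least 10 non-missing values
#'   are required.
#' @param max_cluster_distance Distance beyond which a sample is not called
#'   (default 0.2, half the inter-peak spacing).
#' @return Character vector of per-sample cluster labels `"low"`, `"mid"`,
#'   `"high"`, with `NA` for missing or unassignable samples.
#' @export
#' @examples
#' call_genotypes(c(0.01, 0.02, 0.50, 0.51, 0.97, 0.98, rep(0.02, 6)))
call_genotypes <- function(probe_signal, max_cluster_distance = 0.2) {
  if (!is.numeric(probe_signal)) {
    validation_error("probe_signal", "must be numeric")
  }
  ok <- !is.na(probe_signal)
  if (any(probe_signal[ok] < 0 | probe_signal[ok] > 1)) {
    validation_error("probe_signal", "values must lie in [0, 1]")
  }
  if (sum(ok) < 10) {
    abort(sprintf("too few non-missing probe values (%d < 10) to call genotypes",
                  sum(ok)),
          class = "meqtlscan_low_data_error")
  }

  x <- probe_signal[ok]
  centers <- c(0.1, 0.5, 0.9)
  assign_nearest <- function(x, centers) {
    max.col(-abs(outer(x, centers, "-")), ties.method = "first")
  }
  for (iter in seq_len(100)) {
    cl <- assign_nearest(x, centers)
    new_centers <- centers
    for (k in 1:3) {
      if (any(cl == k)) new_centers[k] <- mean(x[cl == k])
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < 1e-6) break
  }
  cl <- assign_nearest(x, centers)
  dist <- abs(x - centers[cl])
  lab <- c("low", "mid", "high")[cl]
  lab[dist > max_cluster_distance] <- NA_character_

  out <- rep(NA_character_, length(probe_signal))
  out[ok] <- lab
  out
}

#' Orient cluster labels to minor-allele dosage codes
#'
#' Designates as minor the allele carried by the homozygote cluster with the
#' smaller implied allele count, then encodes every sample as its count of
#' minor-allele copies: minor-allele homozygote 2, heterozygote 1, other
#' homozygote 0. A tie (allele frequency exactly 0.5) keeps the high cluster
#' as the minor allele, deterministically.
#'
#' @param cluster_labels Character vector from [call_genotypes()].
#' @param allele_names Length-2 character: the alleles carried by the low and
#'   high signal clusters, in that order (defaults `c("A", "B")`).
#' @return A list: `codes` (integer 0/1/2 with `NA` missing), `maf`,
#'   `minor_allele` (allele name), `minor_cluster` (`"low"` or `"high"`),
#'   `call_rate`.
#' @export
#' @examples
#' labs <- c(rep("low", 90), rep("mid", 18), rep("high", 2))
#' orient_and_encode(labs)$maf  # 0.1
orient_and_encode <- function(cluster_labels, allele_names = c("A", "B")) {
  if (!all(cluster_labels %in% c("low", "mid", "high") | is.na(cluster_labels))) {
    validation_error("cluster_labels", "labels must be low/mid/high/NA")
  }
  n_low <- sum(cluster_labels == "low", na.rm = TRUE)
  n_mid <- sum(cluster_labels == "mid", na.rm = TRUE)
  n_high <- sum(cluster_labels == "high", na.rm = TRUE)
  n_called <- n_low + n_mid + n_high
  if (n_called == 0) {
    return(list(codes = rep(NA_integer_, length(cluster_labels)),
                maf = NA_real_, minor_allele = NA_character_,
                minor_cluster = NA_character_, call_rate = 0))
  }
  # frequency of the allele carried by the high cluster
  f_high <- (2 * n_high + n_mid) / (2 * n_called)
  minor_cluster <- if (f_high <= 0.5) "high" else "low"  # tie -> high
  dosage_map <- if (minor_cluster == "high") {
    c(low = 0L, mid = 1L, high = 2L)
  } else {
    c(low = 2L, mid = 1L, high = 0L)
  }
  codes <- unname(dosage_map[cluster_labels])
  maf <- min(f_high, 1 - f_high)
  list(
    codes = codes,
    maf = maf,
    minor_allele = if (minor_cluster == "high") allele_names[2] else allele_names[1],
    minor_cluster = minor_cluster,
    call_rate = n_called / length(cluster_labels)
  )
}

#' Call a genotype matrix from a SNP-probe signal matrix
#'
#' Applies [call_genotypes()] and [orient_and_encode()] to every row of a
#' probe-signal matrix, jointly across all samples.
#'
#' @param probe_matrix SNPs x samples matrix of probe beta values in [0, 1].
#' @param snp_meta Optional tibble with `snp_id`, `chrom`, `pos` (rownames of
#'   `probe_matrix` are used as ids otherwise).
#' @param max_cluster_distance Passed to [call_genotypes()].
#' @return A [new_genotype_matrix()] object whose `snp_meta` gains `maf` and
#'   `call_rate` columns.
#' @export
call_genotype_matrix <- function(probe_matrix, snp_meta = NULL,
                                 max_cluster_distance = 0.2) {
  stopifnot(is.matrix(probe_matrix))
  snp_ids <- rownames(probe_matrix) %||% sprintf("snp%03d", seq_len(nrow(probe_matrix)))
  calls <- purrr::map(seq_len(nrow(probe_matrix)), function(i) {
    labs <- call_genotypes(probe_matrix[i, ], max_cluster_distance)
    orient_and_encode(labs)
  })
  codes <- do.call(rbind, purrr::map(calls, "codes"))
  dimnames(codes) <- list(snp_ids, colnames(probe_matrix))
  if (is.null(snp_meta)) {
    snp_meta <- tibble::tibble(snp_id = snp_ids,
                               chrom = NA_character_, pos = NA_integer_)
  } else {
    snp_meta <- tibble::as_tibble(snp_meta)
  }
  snp_meta$minor_allele <- purrr::map_chr(calls, "minor_allele")
  snp_meta$maf <- purrr::map_dbl(calls, "maf")
  snp_meta$call_rate <- purrr::map_dbl(calls, "call_rate")
  new_genotype_matrix(codes, snp_meta)
}
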
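#' Fit one SNP-CpG association
#'
#' Ordinary least squares of the CpG methylation beta value on minor-allele
#' dosage with age as the covariate: `meth ~ intercept + dosage + age`.
#' `beta_hat` is the dosage coefficient — the change in methylation beta per
#' additional minor-allele copy — and the p-value is two-sided from a
#' t-distribution with `n_used - 3` degrees of freedom. Samples missing
#' either the methylation value or the dosage are dropped pairwise.
#'
#' Degenerate inputs do not error; they return a flagged record (`status`
#' other than `"ok"`) that downstream FDR adjustment excludes:
#' `"insufficient_data"` (fewer than 4 complete cases),
#' `"degenerate_dosage"` (constant dosage after dropping, including
#' dosage collinear with age), `"zero_residual_variance"` (standard error
#' exactly zero, e.g. constant methylation).
#'
#' @param methylation Per-sample methylation beta vector.
#' @param dosage Per-sample dosage codes (0/1/2, `NA` missing).
#' @param age Per-sample age covariate.
#' @return One-row tibble: `beta_hat`, `se`, `t_stat`, `p_value`, `n_used`,
#'   `status`.
#' @export
#' @examples
#' fit_pair(c(0.10, 0.10, 0.20, 0.20, 0.30, 0.30),
#'          c(0, 0, 1, 1, 2, 2), c(40, 50, 40, 50, 40, 50))
fit_pair <- function(methylation, dosage, age) {
  if (length(methylation) != length(dosage) ||
      length(methylation) != length(age)) {
    validation_error("methylation", "inputs must be aligned by sample")
  }
  ok <- !is.na(methylation) & !is.na(dosage) & !is.na(age)
  n <- sum(ok)
  flagged <- function(status, n_used = n) {
    tibble::tibble(beta_hat = NA_real_, se = NA_real_, t_stat = NA_real_,
                   p_value = NA_real_, n_used = n_used, status = status)
  }
  if (n < 4) return(flagged("insufficient_data"))

  y <- methylation[ok]; d <- dosage[ok]; a <- age[ok]
  X <- cbind(1, d, a)
  qx <- qr(X)
  if (qx$rank < 3) {
    # constant dosage, constant age, or dosage collinear with age
    return(flagged("degenerate_dosage"))
  }
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  beta_hat <- unname(coefs[2])
  # residuals at rounding-noise scale: the t statistic is undefined
  if (rss <= 1e-24 * max(sum(y^2), 1)) {
    return(tibble::tibble(beta_hat = beta_hat, se = 0, t_stat = NA_real_,
                          p_value = NA_real_, n_used = n,
                          status = "zero_residual_variance"))
  }
  sigma2 <- rss / (n - 3)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  t_stat <- beta_hat / se
  tibble::tibble(
    beta_hat = beta_hat, se = se, t_stat = t_stat,
    p_value = 2 * pt(-abs(t_stat), df = n - 3),
    n_used = n, status = "ok"
  )
}

#' Count the SNP-CpG pairs a scan will attempt
#'
#' Metadata-only: no model is fit. Every SNP is paired with every CpG, so a
#' scan of 62 SNPs against 485,512 CpGs attempts 30,101,744 pairs.
#'
#' @param n_snps,n_cpgs Feature counts, or a `genotype_matrix` /
#'   methylation matrix from which counts are taken.
#' @return One-row tibble: `n_snps`, `n_cpgs`, `pairs_attempted` (double, to
#'   stay exact beyond integer range).
#' @export
#' @examples
#' scan_plan(62, 485512)$pairs_attempted  # 30101744
scan_plan <- function(n_snps, n_cpgs) {
  if (inherits(n_snps, "genotype_matrix")) n_snps <- nrow(n_snps$codes)
  if (is.matrix(n_cpgs)) n_cpgs <- nrow(n_cpgs)
  tibble::tibble(
    n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
    pairs_attempted = as.double(n_snps) * as.double(n_cpgs)
  )
}

#' Scan all SNP-CpG pairs in a sample stratum
#'
#' Fits `meth ~ dosage + age` for every SNP-CpG pair among the samples of
#' the requested stratum and screens each SNP's family of CpG tests by
#' Benjamini-Hochberg FDR ([per_snp_fdr()]). The scan is vectorized per SNP
#' (the dosage is residualized against intercept and age, then all CpGs are
#' regressed at once); CpGs with missing methylation fall back to
#' [fit_pair()]. Both paths agree to numerical precision.
#'
#' @param methylation CpGs x samples matrix of beta values.
#' @param genotypes A `genotype_matrix`.
#' @param samples Sample table with `sample_id`, `group`, `age`.
#' @param stratum `"all"`, `"case"` or `"control"`.
#' @param alpha FDR significance level (strict: significant means
#'   `q_value < alpha`).
#' @param fdr_scope `"per_snp"` (each SNP's CpG tests form one BH family,
#'   the default) or `"global"` (one family across all pairs).
#' @return An object of class `meqtl_scan`: the record tibble is in
#'   `$records` (columns `snp_id`, `cpg_id`, `stratum`, `beta_hat`, `se`,
#'   `t_stat`, `p_value`, `q_value`, `significant`, `n_used`, `status`),
#'   with `$alpha`, `$stratum`, `$plan` alongside. Use [generics::tidy()]
#'   to get the tibble.
#' @export
meqtl_scan <- function(methylation, genotypes, samples,
                       stratum = c("all", "case", "control"),
                       alpha = 0.05, fdr_scope = c("per_snp", "global")) {
  stratum <- match.arg(stratum)
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(is.matrix(methylation))

  shared <- intersect(colnames(methylation), colnames(genotypes$codes))
  shared <- intersect(shared, samples$sample_id)
  if (length(shared) == 0) {
    abort("no shared sample ids across methylation, genotypes and samples",
          class = "meqtlscan_alignment_error")
  }
  samples <- samples[match(shared, samples$sample_id), ]
  if (stratum != "all") {
    shared <- shared[samples$group == stratum]
    samples <- samples[samples$group == stratum, ]
  }
  if (length(shared) == 0) {
    abort(sprintf("stratum '%s' is empty", stratum),
          class = "meqtlscan_alignment_error")
  }
  meth <- methylation[, shared, drop = FALSE]
  codes <- genotypes$codes[, shared, drop = FALSE]
  age <- samples$age

  records <- purrr::map_dfr(seq_len(nrow(codes)), function(i) {
    out <- scan_one_snp(meth, codes[i, ], age)
    out$snp_id <- genotypes$snp_meta$snp_id[i]
    out
  })
  records$stratum <- stratum
  records <- per_snp_fdr(records, alpha = alpha, fdr_scope = fdr_scope)
  records <- records[, c("snp_id", "cpg_id", "stratum", "beta_hat", "se",
                         "t_stat", "p_value", "q_value", "significant",
                         "n_used", "status")]

  structure(
    list(records = records, alpha = alpha, stratum = stratum,
         fdr_scope = fdr_scope,
         plan = scan_plan(nrow(codes), nrow(meth)),
         n_samples = length(shared)),
    class = "meqtl_scan"
  )
}

# vectorized per-SNP scan via Frisch-Waugh: residualize dosage and every
# complete-case CpG against (1, age), then slope = <y_perp, d_perp> / <d_perp, d_perp>
scan_one_snp <- function(meth, dosage, age) {
  cpg_ids <- rownames(meth) %||% sprintf("cpg%06d", seq_len(nrow(meth)))
  ok <- !is.na(dosage) & !is.na(age)
  n <- sum(ok)
  base <- tibble::tibble(
    cpg_id = cpg_ids, beta_hat = NA_real_, se = NA_real_, t_stat = NA_real_,
    p_value = NA_real_, n_used = n, status = "insufficient_data"
  )
  if (n < 4) return(base)

  d <- dosage[ok]; a <- age[ok]
  Y <- meth[, ok, drop = FALSE]
  X <- cbind(1, a)
  qx <- qr(X)
  d_perp <- qr.resid(qx, d)
  dpp <- sum(d_perp^2)
  if (qx$rank < 2 || dpp < n * 1e-24) {
    base$status <- "degenerate_dosage"
    return(base)
  }

  has_na <- apply(Y, 1, anyNA)
  out <- base
  if (any(!has_na)) {
    Yc <- t(Y[!has_na, , drop = FALSE])        # n x m
    Yp <- qr.resid(qx, Yc)
    beta <- colSums(Yp * d_perp) / dpp
    rss <- pmax(colSums(Yp^2) - beta^2 * dpp, 0)
    zero <- rss <= 1e-24 * pmax(colSums(Yc^2), 1)
    se <- sqrt(rss / (n - 3) / dpp)
    se[zero] <- 0
    t_stat <- ifelse(!zero, beta / se, NA_real_)
    idx <- which(!has_na)
    out$beta_hat[idx] <- beta
    out$se[idx] <- se
    out$t_stat[idx] <- t_stat
    out$p_value[idx] <- 2 * pt(-abs(t_stat), df = n - 3)
    out$status[idx] <- ifelse(!zero, "ok", "zero_residual_variance")
  }
  if (any(has_na)) {
    for (j in which(has_na)) {
      f <- fit_pair(Y[j, ], d, a)
      out$beta_hat[j] <- f$beta_hat; out$se[j] <- f$se
      out$t_stat[j] <- f$t_stat; out$p_value[j] <- f$p_value
      out$n_used[j] <- f$n_used; out$status[j] <- f$status
    }
  }
  out
}

#' Benjamini-Hochberg FDR within each SNP's family of CpG tests
#'
#' Adjusts p-values by the Benjamini-Hochberg step-up procedure within each
#' (SNP, stratum) family — every testable CpG for that SNP — and marks
#' records with `q_value < alpha` (strict) as significant. Flagged
#' (non-`"ok"`) records carry no test and are excluded from the family size.
#'
#' @param records Tibble of scan records with `snp_id`, `p_value`, `status`
#'   (and optionally `stratum`).
#' @param alpha Significance level.
#' @param fdr_scope `"per_snp"` or `"global"`.
#' @return The records with `q_value` and logical `significant` columns.
#' @export
per_snp_fdr <- function(records, alpha = 0.05,
                        fdr_scope = c("per_snp", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    validation_error("alpha", "must be a probability")
  }
  records$q_value <- NA_real_
  testable <- records$status == "ok" & !is.na(records$p_value)
  if (any(testable)) {
    if (fdr_scope == "global") {
      records$q_value[testable] <- p.adjust(records$p_value[testable], "BH")
    } else {
      fam <- records$snp_id[testable]
      if ("stratum" %in% names(records)) {
        fam <- paste(fam, records$stratum[testable])
      }
      q <- records$p_value[testable]
      for (f in unique(fam)) {
        sel <- fam == f
        q[sel] <- p.adjust(q[sel], "BH")
      }
      records$q_value[testable] <- q
    }
  }
  records$significant <- !is.na(records$q_value) & records$q_value < alpha
  records
}

#' @export
print.meqtl_scan <- function(x, ...) {
  cat(sprintf("<meqtl_scan> stratum '%s': %d SNPs x %d CpGs (%s pairs), %d samples\n",
              x$stratum, x$plan$n_snps, x$plan$n_cpgs,
              format(x$plan$pairs_attempted, big.mark = ","), x$n_samples))
  cat(sprintf("  significant at per-SNP FDR < %g: %d pairs\n",
              x$alpha, sum(x$records$significant)))
  invisible(x)
}

#' @rdname meqtl_scan
#' @param x A `meqtl_scan` object.
#' @param ... Unused.
#' @method tidy meqtl_scan
#' @export
tidy.meqtl_scan <- function(x, ...) x$records

#' @rdname meqtl_scan
#' @method glance meqtl_scan
#' @export
glance.meqtl_scan <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, n_samples = x$n_samples,
    n_snps = x$plan$n_snps, n_cpgs = x$plan$n_cpgs,
    pairs_attempted = x$plan$pairs_attempted,
    pairs_tested = sum(x$records$status == "ok"),
    pairs_significant = sum(x$records$significant),
    alpha = x$alpha, fdr_scope = x$fdr_scope
  )
}
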
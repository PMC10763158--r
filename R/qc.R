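#' Quality-control filtering of a genotype dataset
#'
#' Applies the three standard SNP-array filters in a fixed order:
#' \enumerate{
#'   \item SNPs with genotyping call rate below \code{snp_call_rate} removed;
#'   \item SNPs with minor allele frequency \eqn{\le} \code{maf_min} removed
#'     (MAF from non-missing calls over all retained samples);
#'   \item individuals with a missing-call fraction above
#'     \code{ind_max_missing} (computed on the retained SNPs) removed.
#' }
#'
#' @param ds an \code{\link{snp_dataset}}.
#' @param snp_call_rate minimum per-SNP call rate kept (default 0.90).
#' @param maf_min SNPs with MAF \eqn{\le} this are removed (default 0.05).
#' @param ind_max_missing maximum tolerated per-individual missing fraction
#'   (default 0.10).
#' @return a list with the filtered \code{dataset} and a \code{report} of
#'   class \code{qc_report} holding the three removal counts and thresholds.
#' @export
qc_filter <- function(ds, snp_call_rate = 0.90, maf_min = 0.05,
                      ind_max_missing = 0.10) {
  n0 <- nrow(ds$samples); m0 <- nrow(ds$variants)
  g <- ds$genotypes

  call_rate <- colMeans(!is.na(g))
  keep1 <- call_rate >= snp_call_rate
  n_callrate <- sum(!keep1)
  g <- g[, keep1, drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column: treated as monomorphic
  keep2 <- maf > maf_min
  n_maf <- sum(!keep2)
  g <- g[, keep2, drop = FALSE]

  miss_frac <- if (ncol(g) > 0) rowMeans(is.na(g)) else rep(0, nrow(g))
  keep_ind <- miss_frac <= ind_max_missing
  n_ind <- sum(!keep_ind)

  vi <- which(keep1)[keep2]
  out <- snp_dataset(ds$genotypes[keep_ind, vi, drop = FALSE],
                     ds$samples[keep_ind, , drop = FALSE],
                     ds$variants[vi, , drop = FALSE])
  report <- structure(list(
    n_snps_in = m0, n_samples_in = n0,
    n_snps_removed_callrate = n_callrate,
    n_snps_removed_maf = n_maf,
    n_samples_removed_missing = n_ind,
    n_snps_out = nrow(out$variants), n_samples_out = nrow(out$samples),
    thresholds = list(snp_call_rate = snp_call_rate, maf_min = maf_min,
                      ind_max_missing = ind_max_missing)
  ), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat(sprintf("  input: %d samples x %d SNPs\n", x$n_samples_in, x$n_snps_in))
  cat(sprintf("  SNPs removed, call rate < %.2f: %d\n",
              x$thresholds$snp_call_rate, x$n_snps_removed_callrate))
  cat(sprintf("  SNPs removed, MAF <= %.3f: %d\n",
              x$thresholds$maf_min, x$n_snps_removed_maf))
  cat(sprintf("  individuals removed, missing > %.2f: %d\n",
              x$thresholds$ind_max_missing, x$n_samples_removed_missing))
  cat(sprintf("  output: %d samples x %d SNPs\n",
              x$n_samples_out, x$n_snps_out))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a \code{qc_report}.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_snps_in", "n_samples_in", "n_snps_removed_callrate",
               "n_snps_removed_maf", "n_samples_removed_missing",
               "n_snps_out", "n_samples_out", "snp_call_rate", "maf_min",
               "ind_max_missing"),
    value = c(report$n_snps_in, report$n_samples_in,
              report$n_snps_removed_callrate, report$n_snps_removed_maf,
              report$n_samples_removed_missing, report$n_snps_out,
              report$n_samples_out, report$thresholds$snp_call_rate,
              report$thresholds$maf_min, report$thresholds$ind_max_missing)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
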
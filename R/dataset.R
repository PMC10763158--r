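#' Construct a SNP-array genotype dataset
#'
#' The container consumed by every stage of the pipeline: a diploid biallelic
#' genotype matrix (samples x variants, coded as the count of the A1 allele,
#' \code{NA} for missing) together with the variant map and per-sample
#' population / metapopulation labels.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param samples data frame with columns \code{sample_id}, \code{population}
#'   and optionally \code{group} (one of \code{"wet"}, \code{"dry"},
#'   \code{"none"}; defaults to \code{"none"}).
#' @param variants data frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{a1}, \code{a2}. Within each chromosome variants must
#'   be sortable by strictly increasing position; the constructor sorts them.
#' @return an object of class \code{snp_dataset}.
#' @export
snp_dataset <- function(genotypes, samples, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(samples$group)) samples$group <- "none"
  stopifnot(
    all(c("sample_id", "population") %in% names(samples)),
    all(c("snp_id", "chrom", "pos_bp", "a1", "a2") %in% names(variants)),
    nrow(genotypes) == nrow(samples),
    ncol(genotypes) == nrow(variants)
  )
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in dataset")
  if (anyDuplicated(variants$snp_id))
    stop("duplicated snp_id in dataset")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!all(samples$group %in% c("wet", "dry", "none")))
    stop("sample group must be one of 'wet', 'dry', 'none'")
  variants$pos_bp <- as.integer(variants$pos_bp)
  variants$chrom <- as.character(variants$chrom)
  # per-chromosome position sort, chromosomes kept in order of appearance
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  for (ch in unique(variants$chrom)) {
    p <- variants$pos_bp[variants$chrom == ch]
    if (anyDuplicated(p))
      stop("duplicated position on chromosome ", ch)
  }
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- variants$snp_id
  rownames(samples) <- NULL
  rownames(variants) <- NULL
  structure(
    list(genotypes = genotypes, samples = samples, variants = variants),
    class = "snp_dataset"
  )
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat("snp_dataset:", nrow(x$samples), "samples x", nrow(x$variants),
      "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.snp_dataset <- function(x) dim(x$genotypes)

n_samples <- function(ds) nrow(ds$samples)
n_variants <- function(ds) nrow(ds$variants)

#' Subset a dataset
#'
#' @param ds an \code{snp_dataset}.
#' @param samples logical/integer/character index into samples (optional).
#' @param variants logical/integer/character index into variants (optional).
#' @return the subsetted \code{snp_dataset}.
#' @export
subset_dataset <- function(ds, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(ds$samples)) else samples
  if (is.character(si)) si <- match(si, ds$samples$sample_id)
  vi <- if (is.null(variants)) seq_len(nrow(ds$variants)) else variants
  if (is.character(vi)) vi <- match(vi, ds$variants$snp_id)
  snp_dataset(ds$genotypes[si, vi, drop = FALSE],
              ds$samples[si, , drop = FALSE],
              ds$variants[vi, , drop = FALSE])
}

#' Assign metapopulation groups from a population map
#'
#' @param ds an \code{snp_dataset}.
#' @param group_map named character vector mapping population codes to
#'   \code{"wet"}, \code{"dry"} or \code{"none"}; unmapped populations get
#'   \code{"none"}.
#' @return the dataset with updated \code{group} labels.
#' @export
assign_groups <- function(ds, group_map) {
  g <- unname(group_map[ds$samples$population])
  g[is.na(g)] <- "none"
  ds$samples$group <- g
  ds
}

sample_idx_of <- function(ds, populations = NULL, group = NULL) {
  if (!is.null(populations))
    which(ds$samples$population %in% populations)
  else which(ds$samples$group == group)
}
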
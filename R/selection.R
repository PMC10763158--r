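#' Per-SNP ROH occurrence within one breed
#'
#' For every SNP, the fraction of the breed's animals whose detected ROH
#' cover the SNP (inclusive interval bounds on the same chromosome).
#'
#' @param segments ROH segments of the breed's animals
#'   (\code{\link{detect_roh}} output).
#' @param ds an \code{\link{snp_dataset}}.
#' @param population breed code; the denominator is the number of the
#'   breed's genotyped animals in \code{ds}.
#' @return data frame: population, snp_id, chrom, pos_bp, occurrence.
#' @export
snp_roh_frequency <- function(segments, ds, population) {
  idx <- sample_idx_of(ds, populations = population)
  if (length(idx) == 0L) stop("no samples for population ", population)
  ids <- ds$samples$sample_id[idx]
  segs <- segments[segments$sample_id %in% ids, , drop = FALSE]
  count <- integer(nrow(ds$variants))
  if (nrow(segs)) {
    for (ch in unique(segs$chrom)) {
      vi <- which(ds$variants$chrom == ch)
      pos <- ds$variants$pos_bp[vi]
      sc <- segs[segs$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(sc))) {
        hit <- vi[pos >= sc$start_bp[k] & pos <= sc$end_bp[k]]
        count[hit] <- count[hit] + 1L
      }
    }
  }
  data.frame(population = population,
             snp_id = ds$variants$snp_id,
             chrom = ds$variants$chrom,
             pos_bp = ds$variants$pos_bp,
             occurrence = count / length(idx),
             stringsAsFactors = FALSE)
}

#' Call ROH islands from per-SNP occurrence
#'
#' SNPs whose ROH occurrence reaches the breed's upper percentile threshold
#' (by default the 99.9th percentile, linear-interpolation definition; ties
#' at the threshold are all included) are retained, and maximal runs of
#' map-consecutive retained SNPs on one chromosome become islands.
#'
#' @param freqs one breed's \code{\link{snp_roh_frequency}} table over all
#'   retained SNPs, in map order.
#' @param top_fraction fraction selected (default 0.001, i.e. the 99.9th
#'   percentile).
#' @return data frame: population, chrom, start_bp, end_bp, n_snps,
#'   length_mb. A degenerate occurrence distribution (all values equal)
#'   yields a warning and no islands.
#' @export
roh_islands <- function(freqs, top_fraction = 0.001) {
  empty <- data.frame(population = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_mb = numeric(),
                      stringsAsFactors = FALSE)
  occ <- freqs$occurrence
  if (length(occ) == 0L) return(empty)
  if (max(occ) == min(occ)) {
    warning("degenerate occurrence distribution (all values equal); ",
            "no islands called")
    return(empty)
  }
  thr <- stats::quantile(occ, 1 - top_fraction, names = FALSE, type = 7)
  keep <- occ >= thr
  chrom_break <- c(TRUE, freqs$chrom[-1] != freqs$chrom[-nrow(freqs)])
  run_id <- cumsum(!keep | chrom_break)
  segs <- split(which(keep), run_id[keep])
  out <- lapply(segs, function(ix) {
    data.frame(population = freqs$population[ix[1]],
               chrom = freqs$chrom[ix[1]],
               start_bp = freqs$pos_bp[ix[1]],
               end_bp = freqs$pos_bp[ix[length(ix)]],
               n_snps = length(ix),
               length_mb = island_length_mb(freqs$pos_bp[ix[1]],
                                            freqs$pos_bp[ix[length(ix)]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Island length in Mb from its bp bounds
#'
#' @param start_bp,end_bp positions of the island's first and last SNP.
#' @return \code{(end_bp - start_bp) / 1e6}.
#' @export
island_length_mb <- function(start_bp, end_bp) (end_bp - start_bp) / 1e6

#' Weir-Cockerham variance components per locus
#'
#' The two-level diploid estimator of Weir & Cockerham (1984) for r = 2
#' populations: per biallelic locus the among-population (a),
#' among-individual (b) and within-individual (c) variance components are
#' computed from the sample sizes, allele frequencies and observed
#' heterozygote frequencies of the two populations; the per-SNP estimate is
#' \eqn{\hat\theta = a/(a+b+c)}.
#'
#' Loci monomorphic across both populations get components (0, 0, 0) and an
#' undefined \eqn{\hat\theta}; loci where either population has fewer than
#' two genotyped individuals are skipped (all components \code{NA}). Both
#' kinds are flagged \code{defined = FALSE} and excluded from window sums.
#'
#' @param ds an \code{\link{snp_dataset}}.
#' @param pop_a,pop_b character vectors of population codes; several codes
#'   are pooled into one (meta)population.
#' @return data frame: snp_id, chrom, pos_bp, a, b, c, theta, defined.
#' @export
wc_components <- function(ds, pop_a, pop_b) {
  ia <- sample_idx_of(ds, populations = pop_a)
  ib <- sample_idx_of(ds, populations = pop_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty population in FST contrast")
  ga <- ds$genotypes[ia, , drop = FALSE]
  gb <- ds$genotypes[ib, , drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(ga == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gb == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  mono <- pbar %in% c(0, 1) & s2 == 0
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  skipped <- n1 < 2 | n2 < 2
  a[skipped] <- NA_real_; b[skipped] <- NA_real_; cc[skipped] <- NA_real_
  defined <- !skipped & !mono
  denom <- a + b + cc
  theta <- ifelse(defined & denom != 0, a / denom, NA_real_)
  if (any(skipped))
    message(sum(skipped), " locus/loci skipped (<2 genotyped individuals ",
            "in a population)")
  data.frame(snp_id = ds$variants$snp_id, chrom = ds$variants$chrom,
             pos_bp = ds$variants$pos_bp, a = a, b = b, c = cc,
             theta = theta, defined = defined, stringsAsFactors = FALSE)
}

#' Weighted FST in sliding genomic windows
#'
#' Windows of \code{window_kb} advance in steps of \code{step_kb} from bp 1
#' on each chromosome (inclusive bounds; a SNP belongs to every window
#' containing its position). Per window the weighted (ratio-of-sums)
#' estimate is \eqn{\sum a / \sum (a+b+c)} over member SNPs with defined
#' components; windows whose component sum is zero (including empty windows)
#' are dropped. Windows are emitted while their start does not exceed the
#' chromosome's last SNP position.
#'
#' @param components \code{\link{wc_components}} output.
#' @param window_kb,step_kb window span and step in kb (defaults 500 / 250).
#' @param contrast label stored in the output (default \code{""}).
#' @return data frame: contrast, chrom, start_bp, end_bp, n_snps,
#'   weighted_fst.
#' @export
windowed_fst <- function(components, window_kb = 500, step_kb = 250,
                         contrast = "") {
  wbp <- window_kb * 1000
  sbp <- step_kb * 1000
  out <- list()
  for (ch in unique(components$chrom)) {
    cc <- components[components$chrom == ch & components$defined, ,
                     drop = FALSE]
    max_pos <- max(components$pos_bp[components$chrom == ch])
    starts <- seq(1, max_pos, by = sbp)
    for (s in starts) {
      e <- s + wbp - 1
      inw <- cc$pos_bp >= s & cc$pos_bp <= e
      denom <- sum(cc$a[inw] + cc$b[inw] + cc$c[inw])
      if (sum(inw) == 0L || denom == 0) next
      out[[length(out) + 1L]] <- data.frame(
        contrast = contrast, chrom = ch, start_bp = s, end_bp = e,
        n_snps = sum(inw), weighted_fst = sum(cc$a[inw]) / denom,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contrast = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), weighted_fst = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Significant FST windows by upper percentile
#'
#' The threshold is the \code{1 - top_fraction} quantile
#' (linear-interpolation definition) of the weighted FST over all defined
#' windows of one contrast; returned windows reach the threshold and contain
#' at least \code{min_snps} SNPs. By default the percentile is computed over
#' all windows and the SNP-count rule applied afterwards;
#' \code{filter_first = TRUE} restricts the percentile to windows already
#' satisfying the SNP-count rule.
#'
#' @param windows one contrast's \code{\link{windowed_fst}} table.
#' @param min_snps minimum member SNPs (default 5).
#' @param top_fraction fraction selected (default 0.0005, the 99.95th
#'   percentile).
#' @param filter_first apply the SNP-count rule before the percentile.
#' @return the significant subset of \code{windows}. A degenerate
#'   distribution (all values equal) yields a warning and no windows.
#' @export
significant_windows <- function(windows, min_snps = 5,
                                top_fraction = 0.0005,
                                filter_first = FALSE) {
  pool <- if (filter_first)
    windows[windows$n_snps >= min_snps, , drop = FALSE] else windows
  if (nrow(pool) == 0L) return(pool)
  v <- pool$weighted_fst
  if (max(v) == min(v)) {
    warning("degenerate weighted-FST distribution (all values equal); ",
            "no windows selected")
    return(windows[0, , drop = FALSE])
  }
  if (nrow(pool) < 1 / top_fraction)
    warning("fewer than ", format(1 / top_fraction), " windows; the ",
            "percentile threshold approaches the maximum")
  thr <- stats::quantile(v, 1 - top_fraction, names = FALSE, type = 7)
  out <- windows[windows$weighted_fst >= thr & windows$n_snps >= min_snps, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the environment-contrast design
#'
#' One metapopulation contrast pooling all wet breeds against all dry breeds,
#' followed by every pairwise wet-breed vs dry-breed comparison. Breeds with
#' group \code{"none"} are excluded.
#'
#' @param ds an \code{\link{snp_dataset}} with wet/dry group labels (see
#'   \code{\link{assign_groups}}).
#' @return list of contrasts, each \code{list(label, pop_a, pop_b)} with
#'   \code{pop_a} the wet side.
#' @export
build_contrasts <- function(ds) {
  tab <- unique(ds$samples[, c("population", "group")])
  wet <- tab$population[tab$group == "wet"]
  dry <- tab$population[tab$group == "dry"]
  if (length(wet) == 0L || length(dry) == 0L)
    stop("both a wet and a dry group are required to build contrasts")
  contrasts <- list(list(label = "Metapopulation", pop_a = wet, pop_b = dry))
  for (d in dry) for (w in wet)
    contrasts[[length(contrasts) + 1L]] <-
      list(label = paste(w, d, sep = "_"), pop_a = w, pop_b = d)
  contrasts
}
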
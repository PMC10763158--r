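#' Per-locus heterozygosity within one population
#'
#' For a single locus, observed heterozygosity is the fraction of
#' heterozygotes among non-missing calls; unbiased expected heterozygosity is
#' the Hardy-Weinberg expectation \eqn{1 - p^2 - q^2} with the small-sample
#' correction \eqn{2n/(2n-1)}.
#'
#' @param g integer vector of genotype codes (0/1/2/NA) for one locus,
#'   restricted to one population.
#' @return named numeric vector \code{c(ho, uhe, n_called)}; \code{NA}s when
#'   no call is present.
#' @export
per_locus_het <- function(g) {
  called <- !is.na(g)
  n <- sum(called)
  if (n == 0L) return(c(ho = NA_real_, uhe = NA_real_, n_called = 0))
  ho <- sum(g[called] == 1L) / n
  p <- sum(g[called]) / (2 * n)
  he <- 1 - p^2 - (1 - p)^2
  uhe <- he * 2 * n / (2 * n - 1)
  c(ho = ho, uhe = uhe, n_called = n)
}

# vectorized per-locus Ho/uHe over the columns of a genotype matrix
.het_stats <- function(g) {
  n_called <- colSums(!is.na(g))
  ho <- colSums(g == 1L, na.rm = TRUE) / n_called
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  he <- 2 * p * (1 - p)
  uhe <- he * 2 * n_called / (2 * n_called - 1)
  ho[n_called == 0] <- NA_real_
  uhe[n_called == 0] <- NA_real_
  list(ho = ho, uhe = uhe, n_called = n_called)
}

# across-locus SD with divisor N (population SD)
.sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' FIS from mean heterozygosities
#'
#' The within-population inbreeding coefficient used throughout the pipeline:
#' \eqn{F_{IS} = 1 - \bar{H}_o / \bar{uH}_e}.
#'
#' @param ho_mean,uhe_mean across-locus mean observed and unbiased expected
#'   heterozygosity.
#' @return FIS, or \code{NA} when \code{uhe_mean} is zero.
#' @export
fis_from_means <- function(ho_mean, uhe_mean) {
  ifelse(uhe_mean > 0, 1 - ho_mean / uhe_mean, NA_real_)
}

#' Per-breed diversity summary
#'
#' Computes across-locus means and standard deviations of the per-locus
#' observed (Ho) and unbiased expected (uHe) heterozygosities for one breed,
#' and FIS from the unrounded means. Loci with no call in the breed are
#' excluded; loci monomorphic within the breed contribute zeros by default.
#'
#' @param ds an \code{\link{snp_dataset}}.
#' @param population breed code present in \code{ds$samples$population}.
#' @param include_monomorphic keep within-breed monomorphic loci in the means
#'   (default \code{TRUE}).
#' @return one-row data frame: population, n, ho_mean, ho_sd, uhe_mean,
#'   uhe_sd, fis.
#' @export
breed_diversity <- function(ds, population, include_monomorphic = TRUE) {
  idx <- sample_idx_of(ds, populations = population)
  if (length(idx) == 0L) stop("no samples for population ", population)
  st <- .het_stats(ds$genotypes[idx, , drop = FALSE])
  keep <- st$n_called >= 1L
  if (!include_monomorphic) keep <- keep & st$uhe > 0
  ho <- st$ho[keep]; uhe <- st$uhe[keep]
  ho_mean <- mean(ho); uhe_mean <- mean(uhe)
  data.frame(
    population = population, n = length(idx),
    ho_mean = ho_mean, ho_sd = .sd_pop(ho),
    uhe_mean = uhe_mean, uhe_sd = .sd_pop(uhe),
    fis = fis_from_means(ho_mean, uhe_mean),
    stringsAsFactors = FALSE
  )
}

#' Diversity table over all breeds
#'
#' @param ds an \code{\link{snp_dataset}}.
#' @param include_monomorphic see \code{\link{breed_diversity}}.
#' @return data frame with one \code{\link{breed_diversity}} row per breed.
#' @export
diversity_table <- function(ds, include_monomorphic = TRUE) {
  pops <- unique(ds$samples$population)
  do.call(rbind, lapply(pops, function(p)
    breed_diversity(ds, p, include_monomorphic)))
}
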
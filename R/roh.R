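#' Parameters for scanning-window ROH detection
#'
#' Defaults are the PLINK-style criteria used throughout the pipeline: a
#' sliding window of 20 SNPs with no heterozygous call and at most two
#' missing genotypes, a per-SNP window-hit proportion of at least 0.05, a
#' minimum of 20 SNPs per run, a minimum run length of 2 Mb, at least one SNP
#' per 100 kb, and a maximum gap of 500 kb between consecutive SNPs of a run.
#'
#' @param window_snp sliding-window size in SNPs.
#' @param window_het maximum heterozygous calls per hit window.
#' @param window_missing maximum missing calls per hit window.
#' @param window_hit_frac minimum proportion of covering windows that are
#'   hits for a SNP to be a run candidate.
#' @param min_snp minimum SNPs per reported run.
#' @param min_kb minimum run length in kb.
#' @param min_density_kb_per_snp maximum kb per SNP within a run.
#' @param max_gap_kb maximum gap between consecutive run SNPs, kb.
#' @return a list of class \code{roh_params}.
#' @export
roh_params <- function(window_snp = 20L, window_het = 0L,
                       window_missing = 2L, window_hit_frac = 0.05,
                       min_snp = 20L, min_kb = 2000,
                       min_density_kb_per_snp = 100, max_gap_kb = 500) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            window_hit_frac = window_hit_frac,
            min_snp = as.integer(min_snp), min_kb = min_kb,
            min_density_kb_per_snp = min_density_kb_per_snp,
            max_gap_kb = max_gap_kb)
  stopifnot(p$window_snp > 0, p$window_het >= 0, p$window_het <= p$window_snp,
            p$window_missing >= 0, p$min_snp > 0, p$min_kb > 0,
            p$min_density_kb_per_snp > 0, p$max_gap_kb > 0)
  structure(p, class = "roh_params")
}

# windowed sums of a 0/1 vector, window w, step 1 (length(x) - w + 1 values)
.winsum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# core scan for one individual on one chromosome; returns index ranges
.roh_scan_chrom <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snp
  if (m < w) return(NULL)  # no windows fit: no segments on this chromosome
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hits <- .winsum(het, w) <= params$window_het &
    .winsum(mis, w) <= params$window_missing
  # SNP i is covered by windows max(1, i-w+1) .. min(n_win, i)
  n_win <- m - w + 1L
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(n_win, i)
  csh <- c(0, cumsum(hits))
  prop <- (csh[hi + 1L] - csh[lo]) / (hi - lo + 1L)
  cand <- prop >= params$window_hit_frac & !het
  if (!any(cand)) return(NULL)
  # maximal candidate runs, split where inter-SNP gap exceeds max_gap_kb
  gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
  run_id <- cumsum(!cand | gap_break)
  segs <- split(which(cand), run_id[cand])
  out <- lapply(segs, function(ix) {
    n_snps <- length(ix)
    length_kb <- (pos[ix[n_snps]] - pos[ix[1]]) / 1000
    if (n_snps < params$min_snp) return(NULL)
    if (length_kb < params$min_kb) return(NULL)
    if (length_kb / n_snps > params$min_density_kb_per_snp) return(NULL)
    c(start = ix[1], end = ix[n_snps], n_snps = n_snps,
      start_bp = pos[ix[1]], end_bp = pos[ix[n_snps]])
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Detect runs of homozygosity
#'
#' Scanning-window ROH detection per individual and chromosome: every
#' contiguous window of \code{window_snp} SNPs is a "hit" iff it contains at
#' most \code{window_het} heterozygous and \code{window_missing} missing
#' calls; each SNP's hit proportion is the fraction of its covering windows
#' (fewer near chromosome ends) that are hits; SNPs with proportion at least
#' \code{window_hit_frac} and a non-heterozygous call are run candidates;
#' maximal runs of consecutive candidates are split at inter-SNP gaps above
#' \code{max_gap_kb}; runs failing \code{min_snp}, \code{min_kb} or the SNP
#' density bound are discarded. Missing calls inside a run do not break it.
#'
#' @param ds an \code{\link{snp_dataset}}.
#' @param sample_id one sample id, a vector of ids, or \code{NULL} for all.
#' @param params a \code{\link{roh_params}} object.
#' @return data frame of segments: sample_id, chrom, start_bp, end_bp,
#'   n_snps, length_kb.
#' @export
detect_roh <- function(ds, sample_id = NULL, params = roh_params()) {
  ids <- if (is.null(sample_id)) ds$samples$sample_id else sample_id
  chroms <- unique(ds$variants$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(ds$variants$chrom == ch))
  names(chrom_idx) <- chroms
  res <- vector("list", length(ids) * length(chroms))
  k <- 0L
  for (id in ids) {
    row <- match(id, ds$samples$sample_id)
    if (is.na(row)) stop("unknown sample_id: ", id)
    for (ch in chroms) {
      vi <- chrom_idx[[ch]]
      segs <- .roh_scan_chrom(ds$genotypes[row, vi], ds$variants$pos_bp[vi],
                              params)
      if (length(segs)) {
        s <- do.call(rbind, segs)
        k <- k + 1L
        res[[k]] <- data.frame(
          sample_id = id, chrom = ch,
          start_bp = as.integer(s[, "start_bp"]),
          end_bp = as.integer(s[, "end_bp"]),
          n_snps = as.integer(s[, "n_snps"]),
          length_kb = (s[, "end_bp"] - s[, "start_bp"]) / 1000,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L)
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient FROH
#'
#' \eqn{F_{ROH} = L_{ROH} / L_{aut}}: total ROH length divided by the length
#' of the autosomal genome, per individual; breed values are means over the
#' breed's individuals.
#'
#' @param segments segment data frame from \code{\link{detect_roh}}.
#' @param ds an \code{\link{snp_dataset}} (supplies the individual and breed
#'   roster so that individuals without any ROH contribute zeros).
#' @param l_aut_mb autosomal genome length in Mb (default 2522).
#' @param by \code{"sample"} for per-individual records or
#'   \code{"population"} for breed means of individual FROH.
#' @return data frame with \code{l_roh_mb} and \code{f_roh} per unit.
#' @export
froh <- function(segments, ds, l_aut_mb = 2522,
                 by = c("sample", "population")) {
  by <- match.arg(by)
  ids <- ds$samples$sample_id
  l_mb <- numeric(length(ids))
  if (nrow(segments)) {
    agg <- tapply(segments$length_kb / 1000, segments$sample_id, sum)
    l_mb[match(names(agg), ids)] <- agg
  }
  per_ind <- data.frame(sample_id = ids,
                        population = ds$samples$population,
                        l_roh_mb = l_mb, f_roh = l_mb / l_aut_mb,
                        stringsAsFactors = FALSE)
  if (by == "sample") return(per_ind[, c("sample_id", "l_roh_mb", "f_roh")])
  pops <- unique(per_ind$population)
  data.frame(
    population = pops,
    l_roh_mb = vapply(pops, function(p)
      mean(per_ind$l_roh_mb[per_ind$population == p]), numeric(1)),
    f_roh = vapply(pops, function(p)
      mean(per_ind$f_roh[per_ind$population == p]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
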
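# Independent reference implementations used as oracles. These are written
# as plain loops, directly from the definitions, and share no code with the
# package internals.

# Weir & Cockerham (1984) two-population diploid variance components for a
# single locus, from sample sizes, allele frequencies and heterozygote
# frequencies.
oracle_wc <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cv <- hbar / 2
  c(a = a, b = b, c = cv)
}

# Brute-force scanning-window ROH caller for one individual on one
# chromosome; returns a list of c(start_idx, end_idx).
oracle_roh <- function(g, pos, p) {
  m <- length(g)
  w <- p$window_snp
  if (m < w) return(list())
  n_win <- m - w + 1L
  hit <- logical(n_win)
  for (s in seq_len(n_win)) {
    win <- g[s:(s + w - 1L)]
    hit[s] <- sum(win == 1L, na.rm = TRUE) <= p$window_het &&
      sum(is.na(win)) <= p$window_missing
  }
  cand <- logical(m)
  for (i in seq_len(m)) {
    cover <- max(1L, i - w + 1L):min(n_win, i)
    cand[i] <- mean(hit[cover]) >= p$window_hit_frac &&
      !isTRUE(g[i] == 1L)
  }
  runs <- list()
  start <- NA_integer_
  for (i in seq_len(m)) {
    if (!cand[i]) {
      if (!is.na(start)) { runs[[length(runs) + 1L]] <- c(start, i - 1L) }
      start <- NA_integer_
    } else {
      if (is.na(start)) {
        start <- i
      } else if (pos[i] - pos[i - 1L] > p$max_gap_kb * 1000) {
        runs[[length(runs) + 1L]] <- c(start, i - 1L)
        start <- i
      }
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1L]] <- c(start, m)
  keep <- list()
  for (rn in runs) {
    n_snps <- rn[2] - rn[1] + 1L
    length_kb <- (pos[rn[2]] - pos[rn[1]]) / 1000
    if (n_snps >= p$min_snp && length_kb >= p$min_kb &&
        length_kb / n_snps <= p$min_density_kb_per_snp)
      keep[[length(keep) + 1L]] <- rn
  }
  keep
}

# Two-pass population standard deviation (divisor N).
oracle_sd <- function(x) {
  x <- x[!is.na(x)]
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / length(x))
}

# Dataset builders ------------------------------------------------------

# Small dataset from an explicit genotype matrix.
make_ds <- function(geno, chrom = NULL, pos = NULL, pops = NULL,
                    groups = NULL, a1 = NULL, a2 = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos))
    pos <- if (m == 0) numeric(0)
           else stats::ave(seq_len(m), chrom, FUN = seq_along) * 1e5
  if (is.null(pops)) pops <- rep("P1", n)
  if (is.null(groups)) groups <- rep("none", n)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("B", m)
  snp_dataset(
    geno,
    data.frame(sample_id = paste0("s", seq_len(n)), population = pops,
               group = groups, stringsAsFactors = FALSE),
    data.frame(snp_id = sprintf("rs%d", seq_len(m)), chrom = chrom,
               pos_bp = pos, a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  )
}

# Random dataset with missingness, for property tests.
rand_ds <- function(n = 8, m = 30, n_chrom = 2, miss = 0.05) {
  chrom <- sort(sample(as.character(seq_len(n_chrom)), m, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch)
    sort(sample.int(1e6, sum(chrom == ch)))))
  g <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, miss)), nrow = n)
  make_ds(g, chrom = chrom, pos = pos,
          a1 = sample(c("A", "C", "G", "T"), m, replace = TRUE),
          a2 = sample(c("a", "c", "g", "t"), m, replace = TRUE))
}

# Flip allele labels / genotype orientation of selected variants.
flip_ds <- function(ds, which_v = seq_len(nrow(ds$variants))) {
  a1 <- ds$variants$a1[which_v]
  ds$variants$a1[which_v] <- ds$variants$a2[which_v]
  ds$variants$a2[which_v] <- a1
  ds$genotypes[, which_v] <- 2L - ds$genotypes[, which_v, drop = FALSE]
  ds
}
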
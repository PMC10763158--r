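#' Reynolds' genetic distance between populations
#'
#' The coancestry-based distance for pure drift, in its across-loci ratio
#' form: for two populations with per-locus allele frequency vectors
#' \eqn{x_1, x_2},
#' \deqn{D = \sqrt{ \sum_l \sum_u (x_{1u} - x_{2u})^2 /
#'   \left( 2 \sum_l (1 - \sum_u x_{1u} x_{2u}) \right) },}
#' summing over the two alleles of each biallelic locus. Only loci with
#' defined frequencies (at least one call) in both populations contribute.
#'
#' @param ds an \code{\link{snp_dataset}} with at least two populations.
#' @return symmetric matrix of distances with population dimnames.
#' @export
reynolds_distance <- function(ds) {
  pops <- unique(ds$samples$population)
  if (length(pops) < 2L) stop("need at least two populations")
  freq <- do.call(cbind, lapply(pops, function(p) {
    g <- ds$genotypes[sample_idx_of(ds, populations = p), , drop = FALSE]
    n <- colSums(!is.na(g))
    f <- colSums(g, na.rm = TRUE) / (2 * n)
    if (all(n == 0)) stop("population ", p, " has no called genotypes")
    f
  }))
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1L)) {
    p1 <- freq[, i]; p2 <- freq[, j]
    ok <- !is.na(p1) & !is.na(p2)
    p1 <- p1[ok]; p2 <- p2[ok]
    num <- sum((p1 - p2)^2 + ((1 - p1) - (1 - p2))^2)
    den <- 2 * sum(1 - p1 * p2 - (1 - p1) * (1 - p2))
    d[i, j] <- d[j, i] <- if (den > 0) sqrt(num / den) else 0
  }
  d
}

#' Identity-by-state distance between individuals
#'
#' For a pair of individuals over loci called in both, the IBS similarity is
#' the mean fraction of shared alleles (1, 0.5 or 0 per locus for genotype
#' code differences 0, 1, 2); the distance is one minus the similarity.
#'
#' @param ds an \code{\link{snp_dataset}} with at least two individuals.
#' @return symmetric matrix of distances with sample dimnames. A pair with
#'   no shared called locus is an error.
#' @export
ibs_distance <- function(ds) {
  g <- ds$genotypes
  called <- !is.na(g)
  gi <- g; gi[!called] <- 0L
  I0 <- (gi == 0L) & called
  I1 <- (gi == 1L) & called
  I2 <- (gi == 2L) & called
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  storage.mode(called) <- "double"
  full <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  half <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1)
  n_shared <- tcrossprod(called)
  if (any(n_shared == 0 & upper.tri(n_shared))) {
    bad <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)[1, ]
    stop("no shared called loci for pair ",
         ds$samples$sample_id[bad[1]], " / ", ds$samples$sample_id[bad[2]])
  }
  d <- 1 - (full + 0.5 * half) / n_shared
  diag(d) <- 0
  dimnames(d) <- list(ds$samples$sample_id, ds$samples$sample_id)
  d
}

#' Classical (principal-coordinate) multidimensional scaling
#'
#' Double-centers \eqn{-\frac{1}{2} D^2} and eigendecomposes it
#' (via \code{stats::cmdscale}); coordinates are the top-k eigenvectors
#' scaled by the square roots of their (non-negative) eigenvalues.
#' Variance explained is each eigenvalue's share of the sum of positive
#' eigenvalues; negative eigenvalues (non-Euclidean input) are dropped from
#' the denominator with a message.
#'
#' @param dm symmetric distance matrix with dimnames.
#' @param k number of dimensions (at most n - 1); silently truncated, with a
#'   warning, when it exceeds the number of positive eigenvalues.
#' @return list of class \code{mds_result}: labels, points (n x k),
#'   eigenvalues, var_explained.
#' @export
classical_mds <- function(dm, k = 2) {
  n <- nrow(dm)
  stopifnot(k <= n - 1)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > 1e-12)
  if (sum(eig < -1e-12))
    message(sum(eig < -1e-12), " negative eigenvalue(s) dropped from the ",
            "variance-explained denominator")
  if (k > n_pos) {
    warning("k exceeds the number of positive eigenvalues; truncated to ",
            n_pos)
    k <- n_pos
  }
  pts <- as.matrix(fit$points)[, seq_len(k), drop = FALSE]
  structure(list(
    labels = rownames(dm),
    points = pts,
    eigenvalues = eig[seq_len(k)],
    var_explained = eig[seq_len(k)] / sum(eig[eig > 0])
  ), class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("classical MDS:", length(x$labels), "points,",
      ncol(x$points), "dimension(s)\n")
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mds_result <- function(x, dims = c(1, 2), ...) {
  stopifnot(max(dims) <= ncol(x$points))
  lab <- sprintf("Dim %d (%.2f%%)", dims, 100 * x$var_explained[dims])
  graphics::plot(x$points[, dims[1]], x$points[, dims[2]],
                 xlab = lab[1], ylab = lab[2], ...)
  graphics::text(x$points[, dims[1]], x$points[, dims[2]],
                 labels = x$labels, pos = 3, cex = 0.7)
  invisible(x)
}

#' Export a distance matrix in PHYLIP square format
#'
#' @param dm symmetric matrix with dimnames.
#' @param path output file.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(formatC(rownames(dm)[i], width = -10),
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Export a distance matrix as a NEXUS DISTANCES block
#'
#' @param dm symmetric matrix with dimnames.
#' @param path output file.
#' @export
write_nexus_distances <- function(dm, path) {
  n <- nrow(dm)
  lines <- c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    paste0("  TAXLABELS ", paste(rownames(dm), collapse = " "), ";"),
    "END;", "",
    "BEGIN DISTANCES;",
    "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
    "  MATRIX"
  )
  for (i in seq_len(n))
    lines <- c(lines, paste("   ", rownames(dm)[i],
                            paste(sprintf("%.6f", dm[i, ]), collapse = " ")))
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
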
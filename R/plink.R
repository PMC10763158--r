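## PLINK input/output.
##
## Binary dialect: .bed (v1.0 SNP-major, magic 0x6c 0x1b 0x01) + .bim + .fam;
## genotypes are packed 4 per byte, 2 bits each, low bits first:
##   00 = A1/A1 (code 2), 10 = het (code 1), 11 = A2/A2 (code 0),
##   01 = missing (NA).
## Text dialect: .ped (6 leading columns + two allele columns per SNP,
## "0" = missing allele) + .map (chrom, snp_id, cM, pos).
## No installed R package provides this packing, so it is implemented here.

NON_AUTOSOMES <- c("0", "X", "Y", "XY", "MT", "M")

# lookup tables: byte value 0..255 -> 4 genotype codes, and back
.bed_decode_lut <- local({
  crumb2code <- c(2L, NA, 1L, 0L)  # 00, 01, 10, 11
  lut <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    lut[b + 1L, ] <- crumb2code[c(
      bitwAnd(b, 3L),
      bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L),
      bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }
  lut
})

.code_to_crumb <- function(g) {
  crumb <- integer(length(g))
  crumb[is.na(g)] <- 1L
  crumb[!is.na(g) & g == 2L] <- 0L
  crumb[!is.na(g) & g == 1L] <- 2L
  crumb[!is.na(g) & g == 0L] <- 3L
  crumb
}

#' Read a PLINK fileset
#'
#' Reads either the binary (.bed/.bim/.fam, SNP-major v1.0) or the text
#' (.ped/.map) PLINK dialect into an \code{\link{snp_dataset}}. Genotype codes
#' are the count of the A1 allele of the .bim/.ped; missing genotypes become
#' \code{NA}. Variants are sorted by position within each chromosome;
#' non-autosomal chromosome labels (0, X, Y, XY, MT) are dropped with a
#' message.
#'
#' @param prefix path stem of the fileset (without extension).
#' @param dialect \code{"binary"} or \code{"text"}.
#' @return an \code{snp_dataset}. The sample \code{population} is taken from
#'   the family ID column; \code{group} is \code{"none"} (see
#'   \code{\link{assign_groups}}).
#' @export
read_plink <- function(prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "binary") .read_bed(prefix) else .read_ped(prefix)
}

.read_fam_like <- function(path) {
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 6) stop("expected 6 columns in ", path)
  data.frame(sample_id = fam[[2]], population = fam[[1]],
             group = "none", stringsAsFactors = FALSE)
}

.read_bim_like <- function(path, has_cm) {
  if (!any(nzchar(readLines(path))))
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos_bp = integer(0), a1 = character(0),
                      a2 = character(0), stringsAsFactors = FALSE))
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (has_cm) {
    if (ncol(bim) != 6) stop("expected 6 columns in ", path)
    data.frame(snp_id = bim[[2]], chrom = bim[[1]],
               pos_bp = as.integer(bim[[4]]),
               a1 = bim[[5]], a2 = bim[[6]], stringsAsFactors = FALSE)
  } else {
    if (ncol(bim) != 4) stop("expected 4 columns in ", path)
    data.frame(snp_id = bim[[2]], chrom = bim[[1]],
               pos_bp = as.integer(bim[[4]]),
               a1 = NA_character_, a2 = NA_character_,
               stringsAsFactors = FALSE)
  }
}

.drop_non_autosomes <- function(variants, genotypes) {
  drop <- toupper(variants$chrom) %in% NON_AUTOSOMES
  if (any(drop)) {
    message(sum(drop), " non-autosomal variant(s) dropped")
    variants <- variants[!drop, , drop = FALSE]
    genotypes <- genotypes[, !drop, drop = FALSE]
  }
  list(variants = variants, genotypes = genotypes)
}

.read_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("missing file: ", f)
  samples <- .read_fam_like(paste0(prefix, ".fam"))
  variants <- .read_bim_like(paste0(prefix, ".bim"), has_cm = TRUE)
  if (anyDuplicated(variants$snp_id)) stop("duplicated snp_id in .bim")
  n <- nrow(samples)
  m <- nrow(variants)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic byte mismatch)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed (v1.0) is supported")
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) != 3 + bytes_per_snp * m)
    stop(".bed size inconsistent with .fam/.bim dimensions")
  body <- as.integer(raw[-(1:3)])
  # decode all bytes at once, then reshape: 4 codes per byte, column = SNP
  codes <- .bed_decode_lut[body + 1L, , drop = FALSE]
  codes <- matrix(t(codes), nrow = 4L * bytes_per_snp, ncol = m)
  geno <- codes[seq_len(n), , drop = FALSE]
  kept <- .drop_non_autosomes(variants, geno)
  snp_dataset(kept$genotypes, samples, kept$variants)
}

.read_ped <- function(prefix) {
  for (f in paste0(prefix, c(".ped", ".map")))
    if (!file.exists(f)) stop("missing file: ", f)
  variants <- .read_bim_like(paste0(prefix, ".map"), has_cm = FALSE)
  if (anyDuplicated(variants$snp_id)) stop("duplicated snp_id in .map")
  m <- nrow(variants)
  lines <- readLines(paste0(prefix, ".ped"))
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  a1 <- rep(NA_character_, m)
  a2 <- rep(NA_character_, m)
  samples <- data.frame(sample_id = character(n), population = character(n),
                        group = "none", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop(".ped line ", i, " has ", length(f), " fields, expected ",
           6 + 2 * m)
    samples$population[i] <- f[1]
    samples$sample_id[i] <- f[2]
    al <- matrix(f[-(1:6)], nrow = 2)
    for (j in seq_len(m)) {
      x <- al[, j]
      if (any(x == "0")) next
      for (a in x) {
        if (is.na(a1[j])) { a1[j] <- a }
        else if (a != a1[j] && is.na(a2[j])) { a2[j] <- a }
        else if (a != a1[j] && a != a2[j])
          stop("more than two alleles at ", variants$snp_id[j])
      }
      geno[i, j] <- sum(x == a1[j])
    }
  }
  # a monomorphic SNP never shows its second allele in a .ped; keep placeholder
  a2[is.na(a2) & !is.na(a1)] <- "0"
  variants$a1 <- a1
  variants$a2 <- a2
  kept <- .drop_non_autosomes(variants, geno)
  snp_dataset(kept$genotypes, samples, kept$variants)
}

#' Write a PLINK fileset
#'
#' Writes an \code{\link{snp_dataset}} in either PLINK dialect, such that
#' \code{read_plink(write_plink(ds))} reproduces the dataset (codes, order,
#' labels). The family ID column holds the population code.
#'
#' @param ds an \code{snp_dataset}.
#' @param prefix output path stem.
#' @param dialect \code{"binary"} or \code{"text"}.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(ds, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  n <- nrow(ds$samples)
  m <- nrow(ds$variants)
  fam <- data.frame(ds$samples$population, ds$samples$sample_id,
                    0, 0, 0, -9)
  if (dialect == "binary") {
    utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    bim <- data.frame(ds$variants$chrom, ds$variants$snp_id, rep(0L, m),
                      ds$variants$pos_bp, ds$variants$a1, ds$variants$a2)
    utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    bytes_per_snp <- ceiling(n / 4)
    pad <- 4L * bytes_per_snp - n
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    if (m > 0) {
      crumbs <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = m)
      crumbs[seq_len(n), ] <- .code_to_crumb(ds$genotypes)
      weights <- c(1L, 4L, 16L, 64L)
      idx <- matrix(seq_len(4L * bytes_per_snp), nrow = 4L)
      byte_vals <- weights[1] * crumbs[idx[1, ], , drop = FALSE] +
        weights[2] * crumbs[idx[2, ], , drop = FALSE] +
        weights[3] * crumbs[idx[3, ], , drop = FALSE] +
        weights[4] * crumbs[idx[4, ], , drop = FALSE]
      writeBin(as.raw(byte_vals), con)
    }
  } else {
    map <- data.frame(ds$variants$chrom, ds$variants$snp_id, rep(0L, m),
                      ds$variants$pos_bp)
    utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    a1 <- ds$variants$a1
    a2 <- ds$variants$a2
    lines <- character(n)
    for (i in seq_len(n)) {
      g <- ds$genotypes[i, ]
      first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
      second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
      lines[i] <- paste(c(unlist(fam[i, ]),
                          as.vector(rbind(first, second))), collapse = " ")
    }
    writeLines(lines, paste0(prefix, ".ped"))
  }
  invisible(prefix)
}

#' Merge two datasets on shared SNPs
#'
#' Intersects the variant sets on \code{snp_id}, harmonizes allele orientation
#' to the first dataset (an A1/A2 swap in \code{b} flips codes 0 and 2), drops
#' (and counts) SNPs whose allele pairs do not match even after the swap
#' check, and concatenates the samples.
#'
#' @param a,b \code{snp_dataset} objects.
#' @return the merged \code{snp_dataset}; attribute \code{"merge_report"}
#'   holds the counts of shared, flipped and dropped SNPs.
#' @export
merge_datasets <- function(a, b) {
  if (any(b$samples$sample_id %in% a$samples$sample_id))
    stop("duplicate sample_id across datasets")
  shared <- intersect(a$variants$snp_id, b$variants$snp_id)
  ia <- match(shared, a$variants$snp_id)
  ib <- match(shared, b$variants$snp_id)
  va <- a$variants[ia, , drop = FALSE]
  vb <- b$variants[ib, , drop = FALSE]
  same <- va$a1 == vb$a1 & va$a2 == vb$a2
  flip <- va$a1 == vb$a2 & va$a2 == vb$a1
  keep <- same | flip
  ia <- ia[keep]; ib <- ib[keep]
  flip <- flip[keep]
  ga <- a$genotypes[, ia, drop = FALSE]
  gb <- b$genotypes[, ib, drop = FALSE]
  if (any(flip)) gb[, flip] <- 2L - gb[, flip, drop = FALSE]
  ds <- snp_dataset(rbind(ga, gb),
                    rbind(a$samples, b$samples),
                    a$variants[ia, , drop = FALSE])
  attr(ds, "merge_report") <- list(
    n_shared = length(shared),
    n_flipped = sum(flip),
    n_allele_mismatch_dropped = length(shared) - length(ia)
  )
  ds
}
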
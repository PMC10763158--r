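test_that("hand-written .ped/.map decodes to the expected code matrix", {
  prefix <- file.path(withr::local_tempdir(), "toy")
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200", "1\trs3\t0\t300"),
             paste0(prefix, ".map"))
  writeLines(c("FAM1 ind1 0 0 0 -9 A A A C C C",
               "FAM2 ind2 0 0 0 -9 A A C C A A"),
             paste0(prefix, ".ped"))
  ds <- read_plink(prefix, "text")
  # A1 per SNP is the first allele seen: A, A, C
  expect_identical(unname(ds$genotypes),
                   matrix(c(2L, 2L, 1L, 0L, 2L, 0L), nrow = 2))
  expect_identical(ds$samples$sample_id, c("ind1", "ind2"))
  expect_identical(ds$samples$population, c("FAM1", "FAM2"))
  expect_identical(ds$variants$a1, c("A", "A", "C"))
})

test_that("binary fileset round-trips bit-exactly", {
  set.seed(42)
  for (rep in 1:5) {
    ds <- rand_ds(n = sample(2:9, 1), m = sample(5:40, 1))
    prefix <- file.path(withr::local_tempdir(), "rt")
    write_plink(ds, prefix, "binary")
    ds2 <- read_plink(prefix, "binary")
    expect_identical(ds2$genotypes, ds$genotypes)
    expect_identical(ds2$variants, ds$variants)
    expect_identical(ds2$samples, ds$samples)
  }
})

test_that("desk-scale binary round-trip is element-wise identical", {
  set.seed(7)
  ds <- simulate_dataset(sim_config(seed = 11, n_snps = 3000))$dataset
  prefix <- file.path(withr::local_tempdir(), "big")
  write_plink(ds, prefix, "binary")
  ds2 <- read_plink(prefix, "binary")
  expect_identical(ds2$genotypes, ds$genotypes)
})

test_that("text fileset round-trips up to allele orientation", {
  set.seed(43)
  ds <- rand_ds(n = 6, m = 25)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(ds, prefix, "text")
  ds2 <- read_plink(prefix, "text")
  # .ped carries no allele order; harmonize orientation, then codes match
  same <- ds2$variants$a1 == ds$variants$a1
  swap <- ds2$variants$a1 == ds$variants$a2 | ds$variants$a2 == "0"
  expect_true(all(same | swap | is.na(ds2$variants$a1)))
  fl <- which(!same & swap)
  ds2h <- if (length(fl)) flip_ds(ds2, fl) else ds2
  expect_identical(ds2h$genotypes, ds$genotypes)
  expect_identical(ds2$variants$pos_bp, ds$variants$pos_bp)
})

test_that("empty-variant dataset writes valid files and round-trips", {
  ds <- make_ds(matrix(integer(), nrow = 2, ncol = 0))
  prefix <- file.path(withr::local_tempdir(), "empty")
  write_plink(ds, prefix, "binary")
  ds2 <- read_plink(prefix, "binary")
  expect_identical(dim(ds2$genotypes), c(2L, 0L))
  expect_identical(ds2$samples$sample_id, ds$samples$sample_id)
})

test_that("the 2-bit .bed packing decodes missing and all codes", {
  prefix <- file.path(withr::local_tempdir(), "bits")
  # one SNP, four samples; crumbs low-to-high: 01 00 10 11
  # = missing, hom A1, het, hom A2  ->  byte 0b11100001 = 225
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 225)), paste0(prefix, ".bed"))
  writeLines("1\trs1\t0\t500\tA\tG", paste0(prefix, ".bim"))
  writeLines(sprintf("F%d i%d 0 0 0 -9", 1:4, 1:4), paste0(prefix, ".fam"))
  ds <- read_plink(prefix, "binary")
  expect_identical(unname(ds$genotypes[, 1]), c(NA, 2L, 1L, 0L))
})

test_that("malformed binary filesets are rejected", {
  prefix <- file.path(withr::local_tempdir(), "bad")
  writeLines("1\trs1\t0\t500\tA\tG", paste0(prefix, ".bim"))
  writeLines("F1 i1 0 0 0 -9", paste0(prefix, ".fam"))
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix, "binary"), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix, "binary"), "inconsistent")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00)), paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t500\tA\tG", "1\trs1\t0\t900\tA\tG"),
             paste0(prefix, ".bim"))
  expect_error(read_plink(prefix, "binary"), "duplicated snp_id")
})

test_that("variants are position-sorted per chromosome on read", {
  prefix <- file.path(withr::local_tempdir(), "sort")
  writeLines(c("2\trs1\t0\t900", "2\trs2\t0\t100", "1\trs3\t0\t500"),
             paste0(prefix, ".map"))
  writeLines("F1 i1 0 0 0 -9 A A C C G G", paste0(prefix, ".ped"))
  ds <- read_plink(prefix, "text")
  expect_identical(ds$variants$snp_id, c("rs2", "rs1", "rs3"))
  expect_identical(ds$variants$chrom, c("2", "2", "1"))
})

test_that("non-autosomal chromosomes are dropped with a message", {
  prefix <- file.path(withr::local_tempdir(), "sexchr")
  writeLines(c("1\trs1\t0\t100", "X\trs2\t0\t200", "MT\trs3\t0\t300"),
             paste0(prefix, ".map"))
  writeLines("F1 i1 0 0 0 -9 A A C C G G", paste0(prefix, ".ped"))
  expect_message(ds <- read_plink(prefix, "text"), "non-autosomal")
  expect_identical(ds$variants$snp_id, "rs1")
})

test_that("merging flips swapped alleles and drops mismatches", {
  set.seed(44)
  a <- rand_ds(n = 4, m = 12, miss = 0)
  # b: same variants, every A1/A2 swapped, renamed samples
  b <- flip_ds(a)
  b$samples$sample_id <- paste0("b_", b$samples$sample_id)
  m <- merge_datasets(a, b)
  expect_identical(nrow(m$variants), nrow(a$variants))
  expect_identical(m$genotypes[1:4, ], a$genotypes)
  expect_identical(unname(m$genotypes[5:8, ]), unname(a$genotypes))
  expect_identical(attr(m, "merge_report")$n_flipped, nrow(a$variants))

  # allele mismatch at one SNP: dropped and counted
  b2 <- b
  b2$variants$a1[3] <- "Z"
  m2 <- merge_datasets(a, b2)
  expect_identical(nrow(m2$variants), nrow(a$variants) - 1L)
  expect_identical(attr(m2, "merge_report")$n_allele_mismatch_dropped, 1L)

  # disjoint snp_id sets: zero variants, all samples
  b3 <- b
  b3$variants$snp_id <- paste0("other_", b3$variants$snp_id)
  m3 <- merge_datasets(a, b3)
  expect_identical(nrow(m3$variants), 0L)
  expect_identical(nrow(m3$samples), 8L)

  # duplicate sample ids across inputs
  expect_error(merge_datasets(a, a), "duplicate sample_id")
})

test_that("merge with a renamed copy keeps exactly the original variants", {
  set.seed(45)
  a <- rand_ds(n = 3, m = 10)
  b <- a
  b$samples$sample_id <- paste0("copy_", b$samples$sample_id)
  m <- merge_datasets(a, b)
  expect_identical(m$variants, a$variants)
})

test_that("QC removes low-call-rate then low-MAF SNPs then individuals", {
  # SNP3 has call rate 0.5 in 4 samples
  g <- matrix(1L, nrow = 4, ncol = 5)
  g[1:2, 3] <- NA
  r <- qc_filter(make_ds(g))$report
  expect_identical(r$n_snps_removed_callrate, 1L)

  # monomorphic SNP removed by the MAF filter
  g2 <- cbind(c(0L, 1L, 2L, 1L), c(2L, 2L, 2L, 2L))
  r2 <- qc_filter(make_ds(g2))$report
  expect_identical(r2$n_snps_removed_maf, 1L)

  # boundary: exactly 10% individual missingness is retained, 15% removed
  set.seed(46)
  g3 <- matrix(sample(0:2, 10 * 20, replace = TRUE, prob = c(.3, .4, .3)),
               nrow = 10)
  g3[1, 1:3] <- NA  # 15% of 20 SNPs
  g3[2, 1:2] <- NA  # 10%
  res <- qc_filter(make_ds(g3), snp_call_rate = 0.5, maf_min = -1)
  expect_identical(res$report$n_samples_removed_missing, 1L)
  expect_false("s1" %in% res$dataset$samples$sample_id)
  expect_true("s2" %in% res$dataset$samples$sample_id)
})

test_that("QC equals a brute-force three-pass reference on random data", {
  set.seed(47)
  for (rep in 1:10) {
    ds <- rand_ds(n = 12, m = 40, miss = 0.15)
    res <- qc_filter(ds, snp_call_rate = 0.8, maf_min = 0.1,
                     ind_max_missing = 0.2)
    g <- ds$genotypes
    keep_cr <- vapply(seq_len(ncol(g)), function(j)
      mean(!is.na(g[, j])) >= 0.8, logical(1))
    g <- g[, keep_cr, drop = FALSE]
    keep_maf <- vapply(seq_len(ncol(g)), function(j) {
      x <- g[, j][!is.na(g[, j])]
      p <- sum(x) / (2 * length(x))
      min(p, 1 - p) > 0.1
    }, logical(1))
    g <- g[, keep_maf, drop = FALSE]
    keep_ind <- vapply(seq_len(nrow(g)), function(i)
      mean(is.na(g[i, ])) <= 0.2, logical(1))
    g <- g[keep_ind, , drop = FALSE]
    expect_identical(unname(res$dataset$genotypes), unname(g))
  }
})
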
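test_that("per-SNP ROH occurrence counts covering segments inclusively", {
  ds <- make_ds(matrix(0L, nrow = 4, ncol = 5), chrom = rep("1", 5),
                pos = c(1e6, 2e6, 3e6, 4e6, 5e6),
                pops = rep("B", 4))
  segs <- data.frame(
    sample_id = c("s1", "s2", "s3"), chrom = "1",
    start_bp = c(1.5e6, 1.5e6, 2e6), end_bp = c(3e6, 3.5e6, 3e6),
    n_snps = 2L, length_kb = 1500, stringsAsFactors = FALSE)
  fq <- snp_roh_frequency(segs, ds, "B")
  # SNP at 2 Mb inside 3 segments of 4 animals; 3 Mb equals two end_bp
  # (inclusive) and one interior; 1, 4, 5 Mb outside all
  expect_equal(fq$occurrence, c(0, 0.75, 0.75, 0, 0))
})

test_that("islands are maximal runs above the interpolated percentile", {
  set.seed(56)
  n <- 10000
  pos <- sort(sample.int(1e8, n))
  occ <- rep(0, n)
  hot <- 4000:4011
  occ[hot] <- 0.9
  fq <- data.frame(population = "B", snp_id = paste0("rs", 1:n),
                   chrom = "1", pos_bp = pos, occurrence = occ,
                   stringsAsFactors = FALSE)
  # brute-force percentile check: 99.9th percentile of occ
  thr <- sort(occ)[ceiling(0.999 * (n - 1)) + 1]  # upper bound on type-7
  isl <- roh_islands(fq)
  expect_identical(nrow(isl), 1L)
  expect_identical(isl$n_snps, 12L)
  expect_identical(isl$start_bp, pos[4000])
  expect_identical(isl$end_bp, pos[4011])
  expect_equal(isl$length_mb, (pos[4011] - pos[4000]) / 1e6)
  expect_true(all(occ[occ >= thr] == 0.9))

  # the same hot SNPs split across a chromosome boundary: two islands
  fq2 <- fq
  fq2$chrom <- rep(c("1", "2"), each = n / 2)
  fq2$pos_bp <- c(pos[1:(n / 2)], pos[1:(n / 2)])
  fq2$occurrence <- 0
  fq2$occurrence[c(4995:5000, 5001:5006)] <- 0.9
  isl2 <- roh_islands(fq2)
  expect_identical(nrow(isl2), 2L)
  expect_identical(isl2$n_snps, c(6L, 6L))
})

test_that("a degenerate occurrence distribution yields no islands", {
  fq <- data.frame(population = "B", snp_id = paste0("rs", 1:100),
                   chrom = "1", pos_bp = (1:100) * 1e5,
                   occurrence = 0.5, stringsAsFactors = FALSE)
  expect_warning(isl <- roh_islands(fq), "degenerate")
  expect_identical(nrow(isl), 0L)
})

test_that("WC components match hand-evaluated two-population cases", {
  # fixed difference, no heterozygotes: a = 0.5, b = c = 0, theta = 1
  g <- rbind(matrix(2L, 10, 1), matrix(0L, 10, 1))
  ds <- make_ds(g, pops = rep(c("A", "B"), each = 10))
  comp <- wc_components(ds, "A", "B")
  expect_equal(comp$a, 0.5)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_equal(comp$theta, 1)

  # identical populations, each 2xAA + 2xBB + 6xAB: n1 = n2 = 10,
  # p1 = p2 = 0.5, h1 = h2 = 0.6. Hand evaluation of the estimator:
  # nbar = nc = 10, pbar = 0.5, s2 = 0, hbar = 0.6,
  # a = -(0.25 - 0.6/4)/9 = -1/90, b = (10/9)(0.25 - 0.6*19/40) = -0.035/0.9,
  # c = 0.3, theta = a/(a+b+c) = -0.044444 (negative estimates allowed)
  g4 <- rbind(cbind(c(2L, 2L, 0L, 0L, rep(1L, 6))),
              cbind(c(2L, 2L, 0L, 0L, rep(1L, 6))))
  ds4 <- make_ds(g4, pops = rep(c("A", "B"), each = 10))
  comp4 <- wc_components(ds4, "A", "B")
  expect_equal(comp4$a, -0.1 / 9)
  expect_equal(comp4$b, (10 / 9) * (0.25 - 0.285))
  expect_equal(comp4$c, 0.3)
  expect_equal(comp4$theta, (-0.1 / 9) / 0.25)

  # both populations fixed for the same allele: (0,0,0), undefined theta
  g5 <- matrix(2L, 20, 1)
  ds5 <- make_ds(g5, pops = rep(c("A", "B"), each = 10))
  comp5 <- wc_components(ds5, "A", "B")
  expect_equal(c(comp5$a, comp5$b, comp5$c), c(0, 0, 0))
  expect_true(is.na(comp5$theta))
  expect_false(comp5$defined)
})

test_that("WC components agree with the independent oracle on random loci", {
  set.seed(57)
  n1 <- 15L; n2 <- 9L
  m <- 2000
  g <- matrix(sample(0:2, (n1 + n2) * m, replace = TRUE), ncol = m)
  ds <- make_ds(g, chrom = rep("1", m), pos = (1:m) * 1e4,
                pops = rep(c("A", "B"), c(n1, n2)))
  comp <- wc_components(ds, "A", "B")
  for (j in sample(which(comp$defined), 200)) {
    x1 <- g[1:n1, j]; x2 <- g[(n1 + 1):(n1 + n2), j]
    ref <- oracle_wc(n1, n2, mean(x1) / 2, mean(x2) / 2,
                     mean(x1 == 1), mean(x2 == 1))
    expect_equal(comp$a[j], ref[["a"]], tolerance = 1e-12)
    expect_equal(comp$b[j], ref[["b"]], tolerance = 1e-12)
    expect_equal(comp$c[j], ref[["c"]], tolerance = 1e-12)
  }
})

test_that("windowed FST is the ratio of component sums", {
  comp <- data.frame(snp_id = c("a", "b"), chrom = "1",
                     pos_bp = c(100000, 400000),
                     a = c(0.5, -0.0139), b = c(0, 0.1),
                     c = c(0, 0.1639), theta = c(1, -0.0556),
                     defined = TRUE, stringsAsFactors = FALSE)
  win <- windowed_fst(comp)
  w1 <- win[win$start_bp == 1, ]
  expect_equal(w1$weighted_fst, (0.5 - 0.0139) / 0.75, tolerance = 1e-4)
  expect_identical(w1$n_snps, 2L)
  # SNP at 400 kb belongs to windows [1, 500000] and [250001, 750000]
  expect_identical(win$start_bp, c(1, 250001))
  expect_identical(win$n_snps, c(2L, 1L))
  # single-SNP window equals that SNP's theta
  w2 <- win[win$start_bp == 250001, ]
  expect_equal(w2$weighted_fst, -0.0139 / (-0.0139 + 0.1 + 0.1639))
})

test_that("equal-frequency populations give non-positive window FST", {
  set.seed(58)
  m <- 400
  p <- runif(m, 0.2, 0.8)
  g <- matrix(rbinom(40 * m, 2, rep(p, each = 40)), nrow = 40)
  ds <- make_ds(g, chrom = rep("1", m), pos = sort(sample.int(2e6, m)),
                pops = rep(c("A", "B"), each = 20))
  win <- windowed_fst(wc_components(ds, "A", "B"))
  # no true differentiation: ratio-of-sums estimates scatter around zero
  expect_lt(mean(win$weighted_fst), 0.02)
})

test_that("significant windows honor percentile and SNP-count rules", {
  set.seed(59)
  n <- 10000
  win <- data.frame(contrast = "X", chrom = "1",
                    start_bp = seq(1, by = 250000, length.out = n),
                    end_bp = seq(500000, by = 250000, length.out = n),
                    n_snps = rep(7L, n),
                    weighted_fst = runif(n, 0, 0.1),
                    stringsAsFactors = FALSE)
  hot <- sample(n, 5)
  win$weighted_fst[hot] <- 0.5
  sig <- significant_windows(win)
  expect_identical(sort(sig$start_bp), sort(win$start_bp[hot]))
  # brute-force percentile agrees
  thr <- stats::quantile(win$weighted_fst, 0.9995, type = 7)
  expect_true(all(sig$weighted_fst >= thr))

  # a top window with too few SNPs is excluded
  win$n_snps[hot[1]] <- 4L
  sig2 <- significant_windows(win)
  expect_identical(nrow(sig2), 4L)

  # degenerate distribution: warning, none returned
  win$weighted_fst <- 0.3
  expect_warning(sig3 <- significant_windows(win), "degenerate")
  expect_identical(nrow(sig3), 0L)
})

test_that("contrast design is one metapopulation plus wet-dry pairs", {
  ds <- make_ds(matrix(0L, 8, 2),
                pops = rep(c("MAJ", "PAL", "TIN", "TIS"), each = 2),
                groups = rep(c("dry", "wet", "wet", "dry"), each = 2))
  ct <- build_contrasts(ds)
  expect_length(ct, 5)
  expect_identical(ct[[1]]$label, "Metapopulation")
  expect_setequal(ct[[1]]$pop_a, c("PAL", "TIN"))
  expect_setequal(ct[[1]]$pop_b, c("MAJ", "TIS"))
  labels <- vapply(ct[-1], `[[`, "", "label")
  expect_setequal(labels, c("PAL_MAJ", "TIN_MAJ", "PAL_TIS", "TIN_TIS"))

  # two breeds, one per group: metapopulation and the single pair
  ds2 <- make_ds(matrix(0L, 4, 2), pops = rep(c("A", "B"), each = 2),
                 groups = rep(c("wet", "dry"), each = 2))
  expect_length(build_contrasts(ds2), 2)

  # breeds with group "none" are excluded everywhere
  ds3 <- make_ds(matrix(0L, 6, 2), pops = rep(c("A", "B", "C"), each = 2),
                 groups = rep(c("wet", "dry", "none"), each = 2))
  ct3 <- build_contrasts(ds3)
  expect_false("C" %in% unlist(lapply(ct3, function(x) c(x$pop_a, x$pop_b))))

  # missing group: error
  ds4 <- make_ds(matrix(0L, 4, 2), pops = rep(c("A", "B"), each = 2),
                 groups = rep("wet", 4))
  expect_error(build_contrasts(ds4), "wet and a dry")
})
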
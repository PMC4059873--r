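test_that("grid intervals split only around population breakpoints", {
  g <- genomeSpec(c(chr1 = 1e6))
  # no breakpoints: a single bin covering the chromosome
  bl0 <- data.frame(individual = "F2_0001", chrom = "chr1",
                    start = 1, end = 1e6, genotype = "AA")
  bm0 <- buildBinMap(bl0, g)
  expect_identical(nrow(bm0), 1L)
  expect_equal(binInfo(bm0)$start, 1)
  expect_equal(binInfo(bm0)$end, 1e6)
  # one breakpoint at 450 kb: [1,400k], [400k+1,500k], [500k+1,1Mb]
  bl1 <- data.frame(individual = "F2_0001", chrom = "chr1",
                    start = c(1, 450000), end = c(449999, 1e6),
                    genotype = c("AA", "AB"))
  bm1 <- buildBinMap(bl1, g)
  info <- binInfo(bm1)
  expect_equal(info$start, c(1, 400001, 500001))
  expect_equal(info$end, c(400000, 500000, 1e6))
  expect_identical(info$bin_id, c("Bin1_1", "Bin1_2", "Bin1_3"))
  # a second individual recombining in the same interval adds no bins
  bl2 <- rbind(bl1, data.frame(individual = "F2_0002", chrom = "chr1",
                               start = c(1, 420000), end = c(419999, 1e6),
                               genotype = c("BB", "AB")))
  expect_identical(nrow(buildBinMap(bl2, g)), 3L)
})

test_that("bin genotype is the larger block share; exact ties are NA", {
  g <- genomeSpec(c(chr1 = 1e6))
  bl <- data.frame(individual = "F2_0001", chrom = "chr1",
                   start = c(1, 450000), end = c(449999, 1e6),
                   genotype = c("AA", "AB"))
  geno <- binGenotypes(buildBinMap(bl, g), labels = TRUE)[, "F2_0001"]
  # middle bin [400001,500000]: AA covers 49,999 bp, AB covers 50,001 bp
  expect_identical(unname(geno), c("AA", "AB", "AB"))
  # breakpoint at 450001 splits the bin 50,000/50,000: tie -> NA
  blTie <- data.frame(individual = "F2_0001", chrom = "chr1",
                      start = c(1, 450001), end = c(450000, 1e6),
                      genotype = c("AA", "AB"))
  genoTie <- binGenotypes(buildBinMap(blTie, g), labels = TRUE)[, "F2_0001"]
  expect_identical(unname(genoTie), c("AA", NA, "AB"))
})

test_that("bins tile each chromosome on grid-unit boundaries", {
  g <- genomeSpec(c(chr1 = 1e7, chr2 = 7.25e6))  # chr2 end off-grid
  snps <- makeParentalSNPs(g, 1 / 1770, seed = 30)
  truth <- simulateF2(g, 1e-7, n = 30, seed = 31)
  obs <- observeAlleles(truth, snps, siteObsRate = 1, errorRate = 0, seed = 32)
  bm <- buildBinMap(callBlocks(obs, g), g)
  info <- binInfo(bm)
  for (ch in c("chr1", "chr2")) {
    b <- info[info$chrom == ch, ]
    expect_equal(b$start[1], 1)
    expect_equal(b$end[nrow(b)], unname(chromLengths(g)[ch]))
    expect_equal(b$start[-1], b$end[-nrow(b)] + 1)
    expect_true(all((b$start - 1) %% 1e5 == 0))
    expect_true(all(b$width >= 1e5 | b$end == chromLengths(g)[ch]))
  }
})

test_that("recombinant intervals localize true breakpoints to within one grid unit", {
  g <- genomeSpec(c(chr1 = 1e7))
  snps <- makeParentalSNPs(g, 1 / 1770, seed = 33)
  truth <- simulateF2(g, 2e-7, n = 40, seed = 34)   # ~0.4 CO per gamete
  obs <- observeAlleles(truth, snps, siteObsRate = 1, errorRate = 0, seed = 35)
  bm <- buildBinMap(callBlocks(obs, g), g)
  info <- binInfo(bm)
  recomb <- info[S4Vectors::mcols(SummarizedExperiment::rowRanges(bm))$recombinant, ]
  xo <- trueCrossovers(truth)
  xo <- xo[xo$pos > 2.5e6 & xo$pos < 7.5e6, ]  # away from detection edges
  hit <- vapply(xo$pos, function(p)
    any(p >= recomb$start - 1e5 & p <= recomb$end + 1e5), logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("crossover counts use transition weights with NA skipping", {
  g <- genomeSpec(c(chr1 = 3e5))
  geno <- cbind(F2_0001 = c(0L, 0L, 0L),        # no transition
                F2_0002 = c(0L, 1L, 2L),        # two single crossovers
                F2_0003 = c(0L, 2L, 2L),        # double crossover weight 2
                F2_0004 = c(0L, NA, 2L))        # NA skipped, still 2
  bins <- data.frame(chrom = "chr1", start = c(1, 1e5 + 1, 2e5 + 1),
                     end = c(1e5, 2e5, 3e5))
  bm <- makeBinMap(geno, bins, g)
  expect_identical(unname(countCrossovers(bm)), c(0L, 2L, 2L, 2L))
})

test_that("chi-squared segregation test matches its closed form", {
  perfect <- segregationTest(c(177, 354, 177))
  expect_equal(perfect$chisq, 0)
  expect_equal(perfect$p, 1)
  skewed <- segregationTest(c(708, 0, 0))
  expect_equal(skewed$chisq, 2124)   # (531^2/177) + 354 + 177
  expect_lt(skewed$p, 1e-10)
  expect_identical(segregationTest(c(3, 1), ratio = c(3, 1))$df, 1L)
})

test_that("marker filtering removes distorted, two-genotype and monomorphic bins", {
  g <- genomeSpec(c(chr1 = 4e5))
  geno <- rbind(rep(c(0L, 1L, 2L), c(3, 6, 3)),   # perfect 1:2:1, kept
                rep(0L, 12),                       # one class, p > 1e-10
                rep(c(0L, 1L), c(5, 7)))           # two classes, p > 1e-10
  colnames(geno) <- sprintf("F2_%04d", 1:12)
  bins <- data.frame(chrom = "chr1", start = (0:2) * 1e5 + 1,
                     end = (1:3) * 1e5)
  bm <- makeBinMap(geno, bins, g)
  f <- filterMarkers(bm)
  expect_identical(f$report$kept, c(TRUE, FALSE, FALSE))
  expect_identical(f$report$reason, c("", "monomorphic", "two-genotype"))
  expect_identical(nrow(f$binmap), 1L)
  # report retains counts and the chi-squared decision inputs
  expect_equal(f$report$n_AA[1], 3)
  expect_true(all(f$report$chisq >= 0))
  # a fully distorted large-n bin is removed as distorted (takes precedence)
  g708 <- matrix(rep(0L, 708), nrow = 1,
                 dimnames = list(NULL, sprintf("F2_%04d", 1:708)))
  bm708 <- makeBinMap(g708, data.frame(chrom = "chr1", start = 1, end = 1e5),
                      genomeSpec(c(chr1 = 1e5)))
  f708 <- filterMarkers(bm708)
  expect_identical(f708$report$reason, "distorted")
  expect_equal(f708$report$chisq, 2124)
  expect_identical(nrow(f708$binmap), 0L)
  # idempotence: a second pass removes nothing
  f2 <- filterMarkers(f$binmap)
  expect_identical(nrow(f2$binmap), nrow(f$binmap))
  expect_true(all(f2$report$kept))
})

test_that("nearly monomorphic bins fall below the minor-class frequency cutoff", {
  g <- genomeSpec(c(chr1 = 1e5))
  # 3 classes, minor class at 1/300 < 1%, but force p >= pCut via pCut = 0
  geno <- matrix(rep(c(0L, 1L, 2L), c(149, 150, 1)), nrow = 1)
  colnames(geno) <- sprintf("F2_%04d", 1:300)
  bm <- makeBinMap(geno, data.frame(chrom = "chr1", start = 1, end = 1e5), g)
  f <- filterMarkers(bm, pCut = 0)
  expect_identical(f$report$reason, "monomorphic")
})

test_that("bin length summaries are reported", {
  g <- genomeSpec(c(chr1 = 1e6))
  bl <- data.frame(individual = "F2_0001", chrom = "chr1",
                   start = c(1, 450000), end = c(449999, 1e6),
                   genotype = c("AA", "AB"))
  s <- binSummary(buildBinMap(bl, g))
  expect_identical(s$nBins, 3L)
  expect_equal(s$meanKb, 1e6 / 3 / 1e3)
  expect_equal(s$fracBelow0.5Mb, 2 / 3)
})
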
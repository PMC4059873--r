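test_that("window calls follow the 15-of-18 homozygosity rule", {
  pos <- seq(1e5, by = 1e5, length.out = 18)
  mkcall <- function(nA) c(rep("A", nA), rep("B", 18 - nA))
  expect_identical(callWindows(pos, mkcall(18))$genotype, "AA")
  expect_identical(callWindows(pos, mkcall(15))$genotype, "AA")
  expect_identical(callWindows(pos, mkcall(14))$genotype, "AB")
  expect_identical(callWindows(pos, mkcall(9))$genotype, "AB")   # exact tie
  expect_identical(callWindows(pos, mkcall(3))$genotype, "BB")
  w <- callWindows(pos, mkcall(15))
  expect_identical(w$nA + w$nB, 18L)
  expect_error(callWindows(pos, mkcall(15), window = 18, homMin = 9))
})

test_that("windows advance by the step size over observed SNPs", {
  pos <- seq_len(22) * 1e4
  call <- rep(c("A", "B"), 11)
  w <- callWindows(pos, call, window = 18, step = 2, homMin = 15)
  expect_identical(w$startIdx, c(1L, 3L, 5L))
  expect_identical(w$endIdx, c(18L, 20L, 22L))
  expect_true(all(w$genotype == "AB"))
})

test_that("short chromosomes get one window with a rescaled cutoff", {
  pos <- seq_len(10) * 1e5
  w <- callWindows(pos, c(rep("A", 9), "B"))   # ceil(15/18*10) = 9
  expect_identical(nrow(w), 1L)
  expect_identical(w$genotype, "AA")
  expect_identical(callWindows(pos, c(rep("A", 8), "B", "B"))$genotype, "AB")
  expect_warning(w0 <- callWindows(numeric(0), character(0)), "no observed")
  expect_identical(nrow(w0), 0L)
})

test_that("blocks merge window runs; breakpoint at the SNP midpoint", {
  # two AA windows then two BB windows (window 2, step 2): last AA-window
  # SNP at 400 kb, first BB-window SNP at 500 kb -> breakpoint 450 kb
  pos <- c(3e5, 4e5, 5e5, 6e5)
  call <- c("A", "A", "B", "B")
  w <- callWindows(pos, call, window = 2, step = 2, homMin = 2)
  expect_identical(w$genotype, c("AA", "BB"))
  for (refine in c(FALSE, TRUE)) {
    bl <- windowsToBlocks(w, pos, call, chromLength = 1e6,
                          window = 2, step = 2, refine = refine)
    expect_identical(bl$start, c(1, 450000))
    expect_identical(bl$end, c(449999, 1e6))
    expect_identical(bl$genotype, c("AA", "BB"))
  }
  # uniform calls: one block spanning the chromosome, zero breakpoints
  w1 <- callWindows(pos, rep("A", 4), window = 2, step = 2, homMin = 2)
  bl1 <- windowsToBlocks(w1, pos, rep("A", 4), 1e6, window = 2, step = 2)
  expect_identical(nrow(bl1), 1L)
  expect_identical(c(bl1$start, bl1$end), c(1, 1e6))
})

test_that("short dissenting runs are absorbed unless smoothing is off", {
  # 13 overlapping windows (window 18, step 2) over 42 SNPs with a 3-window
  # dissenting AB run in the middle; minRun = ceiling(18/2) = 9 absorbs it
  pos <- seq_len(42) * 1e5
  call <- rep("A", 42)
  w <- data.frame(startIdx = seq(1L, 25L, by = 2L),
                  endIdx = seq(18L, 42L, by = 2L),
                  nA = 18L, nB = 0L,
                  genotype = c(rep("AA", 5), rep("AB", 3), rep("AA", 5)))
  sm <- windowsToBlocks(w, pos, call, 5e6, window = 18, step = 2)
  expect_identical(sm$genotype, "AA")
  # with smoothing off the dissent remains; midpoint rule keeps its bounds
  raw <- windowsToBlocks(w, pos, call, 5e6, window = 18, step = 2,
                         smooth = FALSE, refine = FALSE)
  expect_identical(raw$genotype, c("AA", "AB", "AA"))
  # blocks tile contiguously and adjacent blocks always differ
  expect_identical(raw$start[-1], raw$end[-nrow(raw)] + 1)
  expect_true(all(raw$genotype[-1] != raw$genotype[-nrow(raw)]))
})

test_that("error-free non-recombinant chromosomes give exactly one block", {
  g <- genomeSpec(c(chr1 = 1e6))
  snps <- makeParentalSNPs(g, 1 / 1770, seed = 20)
  # controlled truth: two homozygous-A, two homozygous-B, two heterozygous
  mk <- function(s1, s2) list(chr1 = list(g1 = gamete(s1), g2 = gamete(s2)))
  truth <- makeTruth(g, list(F2_0001 = mk(0L, 0L), F2_0002 = mk(0L, 0L),
                             F2_0003 = mk(1L, 1L), F2_0004 = mk(1L, 1L),
                             F2_0005 = mk(0L, 1L), F2_0006 = mk(1L, 0L)))
  obs <- observeAlleles(truth, snps, siteObsRate = 1, errorRate = 0, seed = 22)
  bl <- callBlocks(obs, g)
  expect_true(all(table(bl$individual) == 1L))
  # and the single block matches the true genotype everywhere
  for (id in names(truth$individuals)) {
    blk <- bl[bl$individual == id, ]
    expect_identical(match(blk$genotype, c("AA", "AB", "BB")) - 1L,
                     trueGenotypeAt(truth, id, "chr1", 5e5))
  }
})

test_that("inferred genotypes match simulation truth on recombinant data", {
  g <- genomeSpec(c(chr1 = 2e7))
  snps <- makeParentalSNPs(g, 1 / 1770, seed = 23)
  truth <- simulateF2(g, 5e-8, n = 25, seed = 24)   # 1 cM/Mb
  obs <- observeAlleles(truth, snps, siteObsRate = 1, errorRate = 0, seed = 25)
  bl <- callBlocks(obs, g)
  set.seed(26)
  agree <- 0L; tot <- 0L
  for (id in unique(bl$individual)) {
    blk <- bl[bl$individual == id, ]
    ps <- sample.int(2e7, 80)
    inf <- match(genotypeAt(blk, ps), c("AA", "AB", "BB")) - 1L
    agree <- agree + sum(inf == trueGenotypeAt(truth, id, "chr1", ps))
    tot <- tot + 80L
  }
  expect_gt(agree / tot, 0.99)
  # breakpoint count invariant: blocks - 1 per individual x chromosome
  nb <- tapply(bl$start, bl$individual, length)
  expect_identical(sum(nb - 1L), sum(bl$start > 1))
})

test_that("positions at a breakpoint belong to the right block", {
  blocks <- data.frame(start = c(1, 450000), end = c(449999, 1e6),
                       genotype = c("AA", "AB"))
  expect_identical(genotypeAt(blocks, c(449999, 450000, 1e6)),
                   c("AA", "AB", "AB"))
  expect_error(genotypeAt(blocks, 1e6 + 1), "outside")
  expect_error(genotypeAt(blocks, 0), "outside")
})
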
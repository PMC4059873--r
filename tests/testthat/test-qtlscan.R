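test_that("marker-regression LOD equals the group-means likelihood-ratio oracle", {
  set.seed(50)
  geno <- matrix(sample(0:2, 20 * 40, TRUE), nrow = 20,
                 dimnames = list(NULL, sprintf("F2_%04d", 1:40)))
  geno[cbind(sample(20, 15, TRUE), sample(40, 15, TRUE))] <- NA  # sprinkle NAs
  y <- setNames(rnorm(40) + 0.6 * (1 - ifelse(is.na(geno[7, ]), 0, geno[7, ])),
                colnames(geno))
  prof <- scanOne(geno, y)
  oracle <- vapply(1:20, function(i) lodOracle(y, geno[i, ]), numeric(1))
  expect_lt(max(abs(prof$LOD - oracle)), 1e-6)
  expect_identical(prof$n, as.integer(rowSums(!is.na(geno))))
})

test_that("degenerate traits: constant gives LOD 0, exact genetic trait peaks hugely", {
  set.seed(51)
  geno <- matrix(sample(0:2, 15 * 30, TRUE), nrow = 15,
                 dimnames = list(NULL, sprintf("F2_%04d", 1:30)))
  flat <- scanOne(geno, setNames(rep(3.7, 30), colnames(geno)))
  expect_true(all(flat$LOD == 0))
  yExact <- setNames(1 - geno[4, ], colnames(geno))
  exact <- scanOne(geno, yExact)
  expect_identical(which.max(exact$LOD), 4L)
  expect_gt(max(exact$LOD), 50)
})

test_that("LOD is invariant to affine transformation of the phenotype", {
  set.seed(52)
  geno <- matrix(sample(0:2, 10 * 50, TRUE), nrow = 10,
                 dimnames = list(NULL, sprintf("F2_%04d", 1:50)))
  y <- setNames(rnorm(50), colnames(geno))
  expect_equal(scanOne(geno, y)$LOD, scanOne(geno, 3 * y + 7)$LOD,
               tolerance = 1e-8)
})

test_that("the permutation engine agrees with the per-marker regression scan", {
  set.seed(53)
  geno <- matrix(sample(0:2, 40 * 60, TRUE), nrow = 40,
                 dimnames = list(NULL, sprintf("F2_%04d", 1:60)))
  geno[sample(length(geno), 100)] <- NA
  y <- rnorm(60)
  fast <- BinMapQTL:::.maxLodMatrix(geno, matrix(y, ncol = 1))
  slow <- max(scanOne(geno, setNames(y, colnames(geno)), minN = 10)$LOD,
              na.rm = TRUE)
  expect_equal(unname(fast), slow, tolerance = 1e-8)
})

test_that("permutation threshold follows the order-statistic convention", {
  set.seed(54)
  geno <- matrix(sample(0:2, 25 * 80, TRUE), nrow = 25,
                 dimnames = list(NULL, sprintf("F2_%04d", 1:80)))
  y <- setNames(rnorm(80), colnames(geno))
  th <- permutationThreshold(geno, y, nPerm = 200, alpha = 0.05, seed = 55)
  expect_identical(th$threshold, sort(th$maxLod)[ceiling(0.95 * 200)])
  # reproducible under the same seed; monotone non-increasing in alpha
  th2 <- permutationThreshold(geno, y, nPerm = 200, alpha = 0.05, seed = 55)
  expect_identical(th$maxLod, th2$maxLod)
  th10 <- permutationThreshold(geno, y, nPerm = 200, alpha = 0.10, seed = 55)
  expect_lte(th10$threshold, th$threshold)
  expect_error(permutationThreshold(geno, y, nPerm = 200, alpha = 0.05),
               "seed")
})

test_that("support intervals apply the 1.5-LOD drop rule", {
  prof <- data.frame(bin_id = paste0("Bin1_", 1:5), chrom = "chr1",
                     start = (0:4) * 1e5 + 1, end = (1:5) * 1e5,
                     LOD = c(2, 8, 10, 8.4, 2))
  si <- supportInterval(prof)
  expect_identical(si$bins, "Bin1_3")       # 8 and 8.4 fall below 10 - 1.5
  expect_identical(si$startBp, 200001)
  expect_identical(si$endBp, 3e5)
  expect_false(si$tied)
  wide <- supportInterval(prof, drop = 3)
  expect_identical(wide$bins, paste0("Bin1_", 2:4))
  flat <- supportInterval(transform(prof, LOD = 5))
  expect_true(flat$tied)
  expect_identical(length(flat$bins), 5L)   # whole chromosome, flagged
})

test_that("effect decomposition follows a = (muAA - muBB)/2, d = muAB - midpoint", {
  g <- rep(c(0L, 1L, 2L), each = 4)
  y <- rep(c(12, 11, 8), each = 4)
  eff <- estimateEffects(y, g)
  expect_equal(eff$a, 2)
  expect_equal(eff$d, 1)
  expect_equal(eff$r2, 100)                 # no within-class variance
  flat <- estimateEffects(rep(5, 12) + rep(c(0, 1e-9, 0), each = 4), g)
  expect_equal(flat$a, 0, tolerance = 1e-8)
  expect_equal(flat$d, 0, tolerance = 1e-8)
  noBB <- estimateEffects(y[1:8], g[1:8])
  expect_true(is.na(noBB$a) && is.na(noBB$d))
  expect_error(estimateEffects(y[1:4], g[1:4]), "classes")
})

test_that("forward multi-QTL scan recovers two unlinked QTL with joint effects", {
  g <- genomeSpec(c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7))
  truth <- simulateF2(g, 7e-8, n = 400, seed = 56)
  posPer <- seq(5e5, by = 5e5, length.out = 39)
  geno <- genoAtMarkers(truth, posPer)
  bm <- makeBinMap(geno, markerBins(g, posPer, halfWidth = 2.5e5), g)
  ph <- simulatePhenotypes(truth, qtlSimSpec(
    loci = data.frame(chrom = c("chr1", "chr3"), pos = c(1e7, 5e6),
                      a = c(2, -1.5), d = c(0.5, 0)), sigma = 1.5), seed = 57)
  res <- scanMulti(bm, ph, threshold = 4, trait = "trait")
  expect_identical(sort(unique(res$chrom)), c("chr1", "chr3"))
  expect_identical(nrow(res), 2L)
  a1 <- res$additive[res$chrom == "chr1"]
  a3 <- res$additive[res$chrom == "chr3"]
  expect_lt(abs(a1 - 2), 0.5)
  expect_lt(abs(a3 + 1.5), 0.5)
  expect_true(all(res$LOD >= 4))
  expect_true(all(res$interval_start_bp <= res$pos_bp &
                  res$interval_end_bp >= res$pos_bp))
  expect_true(all(res$r2_pct > 0 & res$r2_pct < 100))
  # an unreachable threshold returns an empty table
  none <- scanMulti(bm, ph, threshold = 1e4, trait = "trait")
  expect_identical(nrow(none), 0L)
})

test_that("a dominant monogenic binary trait maps exactly to its causal bin", {
  g <- genomeSpec(c(chr1 = 2e7, chr2 = 2e7))
  posPer <- seq(5e5, by = 1e6, length.out = 20)
  causal <- posPer[13]
  hits <- 0L
  for (repl in 1:12) {
    truth <- simulateF2(g, 7e-8, n = 200, seed = 600 + repl)
    geno <- genoAtMarkers(truth, posPer)
    bm <- makeBinMap(geno, markerBins(g, posPer, halfWidth = 5e5), g)
    ph <- simulatePhenotypes(truth, qtlSimSpec(
      sigma = 1, binaryLocus = list(chrom = "chr2", pos = causal,
                                    dominant = "A")), seed = 700 + repl)
    prof <- scanOne(bm, ph, trait = "binary")
    pk <- prof[which.max(prof$LOD), ]
    hits <- hits + as.integer(pk$chrom == "chr2" &&
                                pk$start <= causal && pk$end >= causal)
  }
  expect_identical(hits, 12L)
})
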
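# Independent oracles and small fixture builders shared across tests.

# Joint F2 genotype distribution at two coupling-phase loci, derived by
# direct enumeration of the four F1 gamete types (independent of the
# closed-form class probabilities used inside the package).
rfJointOracle <- function(r) {
  gam <- expand.grid(l1 = 0:1, l2 = 0:1)   # 0 = A allele, 1 = B allele
  freq <- ifelse(gam$l1 == gam$l2, (1 - r) / 2, r / 2)
  p <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    a <- gam$l1[i] + gam$l1[j]
    b <- gam$l2[i] + gam$l2[j]
    p[a + 1, b + 1] <- p[a + 1, b + 1] + freq[i] * freq[j]
  }
  p
}

# Brute-force likelihood maximization over a 1e-4 grid of r.
rfGridOracle <- function(g1, g2, step = 1e-4) {
  ok <- !is.na(g1) & !is.na(g2)
  counts <- table(factor(g1[ok], 0:2), factor(g2[ok], 0:2))
  rs <- seq(step, 0.5 - step, by = step)
  ll <- vapply(rs, function(r) {
    p <- rfJointOracle(r)
    sum(counts[counts > 0] * log(p[counts > 0]))
  }, numeric(1))
  rs[which.max(ll)]
}

# Group-means likelihood-ratio LOD (saturated 3-class model), independent
# of the regression fit used in scanOne.
lodOracle <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  rss1 <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# Hand-built F2 ground truth for controlled observation tests.
gamete <- function(start, bp = numeric(0)) list(bp = bp, start = start)

makeTruth <- function(genome, individuals, mapLengthPerBp = 0) {
  structure(list(genome = genome, mapLengthPerBp = mapLengthPerBp,
                 individuals = individuals),
            class = "F2Truth")
}

# Complete genotype matrix of a simulated population at fixed marker
# positions (same positions on every chromosome).
genoAtMarkers <- function(truth, positions) {
  ids <- names(truth$individuals)
  chroms <- names(chromLengths(truth$genome))
  out <- do.call(rbind, lapply(chroms, function(ch)
    vapply(ids, function(id) trueGenotypeAt(truth, id, ch, positions),
           integer(length(positions)))))
  colnames(out) <- ids
  out
}

# One grid-interval bin per marker, clamped to the chromosome.
markerBins <- function(genome, positions, halfWidth = 5e4) {
  len <- chromLengths(genome)
  do.call(rbind, lapply(names(len), function(ch)
    data.frame(chrom = ch,
               start = pmax(1, positions - halfWidth + 1),
               end = pmin(len[[ch]], positions + halfWidth))))
}
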
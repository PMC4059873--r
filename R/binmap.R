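# Population-level bin construction: chromosomes are cut into grid
# intervals (default 100 kb); intervals containing at least one inferred
# breakpoint in the population are "recombinant"; maximal runs of
# non-recombinant intervals are joined into bins, and each bin becomes a
# single genetic marker genotyped across all individuals.

#' Build a recombination bin map from genotype blocks
#'
#' Internally coordinates are half-open and 0-based on multiples of
#' \code{gridUnit}; exported tables are 1-based inclusive.  A grid interval
#' is marked recombinant iff at least one individual's inferred breakpoint
#' falls in it; consecutive non-recombinant intervals merge into one bin,
#' so after construction no individual has a breakpoint strictly interior
#' to a multi-interval bin.  Each individual's genotype in a bin is the
#' genotype of the block covering the larger share of the bin (exact ties
#' give NA).
#'
#' @param blocks Population blocks from [callBlocks()] (columns
#'   \code{individual}, \code{chrom}, \code{start}, \code{end},
#'   \code{genotype}).
#' @param genome A [GenomeSpec-class].
#' @param gridUnit Grid interval width in bp (default: the genome's).
#' @return A [BinMap-class] with bins as row ranges (ids
#'   \code{Bin<chrom index>_<ordinal>}) and one integer \code{"genotype"}
#'   assay (0 = AA, 1 = AB, 2 = BB, NA).
#' @examples
#' bl <- data.frame(individual = "F2_0001", chrom = "chr1",
#'                  start = c(1, 450000), end = c(449999, 1e6),
#'                  genotype = c("AA", "AB"))
#' buildBinMap(bl, genomeSpec(c(chr1 = 1e6)))
#' @export
buildBinMap <- function(blocks, genome, gridUnit = NULL) {
  stopifnot(is(genome, "GenomeSpec"),
            all(c("individual", "chrom", "start", "end", "genotype")
                %in% names(blocks)))
  g <- if (is.null(gridUnit)) genome@gridUnit else gridUnit
  len <- chromLengths(genome)
  ids <- unique(blocks$individual)
  chroms <- names(len)
  blocks$gcode <- .genoCode(blocks$genotype)
  byChrom <- split(blocks, factor(blocks$chrom, levels = chroms))

  binRows <- list()
  genoRows <- list()
  warnedMissing <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- len[[ch]]
    nInt <- ceiling(L / g)
    bc <- byChrom[[ch]]
    # recombinant intervals: interval index (0-based) containing bp-1 for
    # each internal block boundary (a breakpoint at an exact grid boundary
    # marks the interval to its left, keeping it at a bin edge either way)
    recomb <- logical(nInt)
    if (!is.null(bc) && nrow(bc)) {
      bps <- bc$start[bc$start > 1]
      if (length(bps)) {
        idx <- pmin(floor((bps - 1) / g), nInt - 1) + 1L
        recomb[unique(idx)] <- TRUE
      }
    }
    # bin edges: a boundary stands between intervals i-1,i whenever either
    # side is recombinant; recombinant intervals thus stand alone
    if (nInt > 1L) {
      cut <- recomb[-nInt] | recomb[-1L]
      starts0 <- c(0, which(cut) * g)
    } else starts0 <- 0
    ends0 <- c(starts0[-1L], L)
    nb <- length(starts0)

    # per-individual genotype: largest block share of each bin
    ovl <- array(0, dim = c(nb, 3L))
    gm <- matrix(NA_integer_, nrow = nb, ncol = length(ids),
                 dimnames = list(NULL, ids))
    bcByInd <- if (!is.null(bc)) split(bc, factor(bc$individual, levels = ids))
    for (jj in seq_along(ids)) {
      bi <- bcByInd[[ids[jj]]]
      if (is.null(bi) || nrow(bi) == 0L) { warnedMissing <- warnedMissing + 1L; next }
      ovl[] <- 0
      for (kk in seq_len(nrow(bi))) {
        s <- bi$start[kk] - 1; e <- bi$end[kk]   # 0-based half-open
        o <- pmax(0, pmin(ends0, e) - pmax(starts0, s))
        ovl[, bi$gcode[kk] + 1L] <- ovl[, bi$gcode[kk] + 1L] + o
      }
      best <- max.col(ovl, ties.method = "first")
      top <- ovl[cbind(seq_len(nb), best)]
      nTop <- rowSums(ovl == top)
      gm[, jj] <- ifelse(top > 0 & nTop == 1L, best - 1L, NA_integer_)
    }
    binRows[[ci]] <- data.frame(
      chrom = ch, start = starts0 + 1, end = ends0,
      bin_id = sprintf("Bin%d_%d", ci, seq_len(nb)),
      recombinant = recomb[pmin(floor(starts0 / g), nInt - 1) + 1L] &
        (ends0 - starts0 <= g))
    genoRows[[ci]] <- gm
  }
  if (warnedMissing > 0L)
    warning(warnedMissing, " individual x chromosome combinations had no ",
            "blocks; coded NA across those bins")
  binDf <- do.call(rbind, binRows)
  geno <- do.call(rbind, genoRows)
  rr <- GenomicRanges::GRanges(
    seqnames = binDf$chrom,
    ranges = IRanges::IRanges(start = binDf$start, end = binDf$end),
    bin_id = binDf$bin_id, recombinant = binDf$recombinant,
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = len))
  rownames(geno) <- binDf$bin_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = geno), rowRanges = rr)
  S4Vectors::metadata(se)$gridUnit <- g
  new("BinMap", se)
}

#' Per-individual crossover counts from a bin map
#'
#' Counts genotype transitions along each chromosome over non-NA bins
#' (NA bins are skipped, counting across the gap).  Adjacent-bin
#' transitions AA<->AB and AB<->BB count 1 crossover, AA<->BB counts 2
#' (a double crossover between adjacent markers).
#'
#' @param binmap A [BinMap-class].
#' @return Named integer vector of crossover counts per individual.
#' @export
countCrossovers <- function(binmap) {
  stopifnot(is(binmap, "BinMap"))
  g <- binGenotypes(binmap)
  chrom <- as.character(GenomeInfoDb::seqnames(
    SummarizedExperiment::rowRanges(binmap)))
  counts <- setNames(integer(ncol(g)), colnames(g))
  for (ch in unique(chrom)) {
    gc <- g[chrom == ch, , drop = FALSE]
    counts <- counts + vapply(seq_len(ncol(gc)), function(j) {
      v <- gc[, j]; v <- v[!is.na(v)]
      if (length(v) < 2L) 0L else sum(abs(diff(v)))
    }, integer(1))
  }
  counts
}

#' Chi-squared goodness-of-fit test against a segregation ratio
#'
#' Pearson chi-squared without continuity correction, with
#' \code{length(counts) - 1} degrees of freedom.  Used with ratio 1:2:1
#' for F2 marker filtering and with 3:1 for dominant monogenic traits.
#'
#' @param counts Observed class counts.
#' @param ratio Expected ratio (default \code{c(1, 2, 1)}).
#' @return List with \code{chisq}, \code{df}, \code{p}.
#' @examples
#' segregationTest(c(484, 127), ratio = c(3, 1))   # dominant 3:1
#' @export
segregationTest <- function(counts, ratio = c(1, 2, 1)) {
  stopifnot(length(counts) == length(ratio), all(counts >= 0), sum(counts) > 0)
  expd <- sum(counts) * ratio / sum(ratio)
  chisq <- sum((counts - expd)^2 / expd)
  df <- length(counts) - 1L
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Filter bin markers on segregation and informativeness
#'
#' Removes bins whose genotype counts are highly distorted from the F2
#' expectation 1:2:1 (chi-squared, 2 df, p below \code{pCut}), bins with
#' fewer than three genotype classes ("two-genotype" if two classes,
#' "monomorphic" if one), and nearly monomorphic bins whose minor
#' genotype-class frequency is below \code{monoFreq}.
#'
#' @param binmap A [BinMap-class].
#' @param pCut Distortion p-value cutoff (default 1e-10).
#' @param monoFreq Minor-class frequency below which a bin is "nearly
#'   monomorphic" (default 0.01).
#' @return A list with \code{binmap} (the filtered [BinMap-class]) and
#'   \code{report}, a data.frame retaining every decision: per bin the
#'   genotype counts, chi-squared statistic and p-value vs 1:2:1,
#'   \code{kept} flag and removal \code{reason} ("distorted",
#'   "monomorphic" or "two-genotype").  Filtering is idempotent.
#' @export
filterMarkers <- function(binmap, pCut = 1e-10, monoFreq = 0.01) {
  stopifnot(is(binmap, "BinMap"), nrow(binmap) >= 1L)
  g <- binGenotypes(binmap)
  nAA <- rowSums(g == 0L, na.rm = TRUE)
  nAB <- rowSums(g == 1L, na.rm = TRUE)
  nBB <- rowSums(g == 2L, na.rm = TRUE)
  n <- nAA + nAB + nBB
  expAA <- n / 4; expAB <- n / 2
  chisq <- (nAA - expAA)^2 / expAA + (nAB - expAB)^2 / expAB +
    (nBB - expAA)^2 / expAA
  chisq[n == 0] <- NA_real_
  p <- pchisq(chisq, df = 2, lower.tail = FALSE)
  nClasses <- (nAA > 0) + (nAB > 0) + (nBB > 0)
  minFreq <- pmin(nAA, nAB, nBB) / pmax(n, 1L)
  reason <- rep(NA_character_, nrow(g))
  reason[!is.na(p) & p < pCut] <- "distorted"
  reason[is.na(reason) & nClasses == 2L] <- "two-genotype"
  reason[is.na(reason) & (nClasses < 2L | minFreq < monoFreq)] <- "monomorphic"
  kept <- is.na(reason)
  info <- binInfo(binmap)
  report <- data.frame(
    bin_id = info$bin_id, chrom = info$chrom, start = info$start,
    end = info$end, n_AA = nAA, n_AB = nAB, n_BB = nBB,
    chisq = chisq, p = p, kept = kept,
    reason = ifelse(kept, "", reason), stringsAsFactors = FALSE)
  list(binmap = binmap[kept, ], report = report)
}

#' Bin-length summary statistics
#'
#' @param binmap A [BinMap-class].
#' @return List with \code{nBins}, \code{meanKb}, \code{medianKb},
#'   \code{fracBelow0.5Mb}, \code{minKb}, \code{maxKb}.
#' @export
binSummary <- function(binmap) {
  w <- binInfo(binmap)$width
  list(nBins = length(w), meanKb = mean(w) / 1e3, medianKb = median(w) / 1e3,
       fracBelow0.5Mb = mean(w < 5e5), minKb = min(w) / 1e3,
       maxKb = max(w) / 1e3)
}
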
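# Per-individual sliding-window genotype calling.  Observed parental-allele
# calls are scanned in windows of `window` SNPs advancing by `step`; a
# window with >= homMin alleles from one parent is called homozygous for
# that parent, otherwise heterozygous.  Runs of identically-called windows
# become genotype blocks whose boundaries are the inferred recombination
# breakpoints.

#' Sliding-window genotype calls for one individual and chromosome
#'
#' @param pos Sorted vector of observed SNP positions (bp, 1-based).
#' @param call Parallel vector of allele calls, "A"/"B" (or 0/1).
#' @param window Window size in SNPs (default 18).
#' @param step Step size in SNPs (default 2).
#' @param homMin Minimum count of one parental allele for a homozygous
#'   call (default 15); windows below it are heterozygous.
#' @return A data.frame with one row per window: \code{startIdx},
#'   \code{endIdx} (SNP indices), \code{nA}, \code{nB} and \code{genotype}
#'   ("AA"/"AB"/"BB").  If fewer than \code{window} SNPs are observed, a
#'   single short window over all of them is called with the homozygosity
#'   cutoff rescaled to \code{ceiling(homMin/window * k)} for \code{k}
#'   observed SNPs.  Zero observations give an empty result with a warning.
#' @examples
#' callWindows(seq(1e5, 18e5, by = 1e5), rep(c("A","B"), 9))
#' @export
callWindows <- function(pos, call, window = 18, step = 2, homMin = 15) {
  window <- as.integer(window); step <- as.integer(step)
  homMin <- as.integer(homMin)
  stopifnot(window >= homMin, homMin >= ceiling(window / 2) + 1, step >= 1)
  m <- length(pos)
  stopifnot(length(call) == m)
  if (m == 0L) {
    warning("no observed SNPs; returning zero windows")
    return(data.frame(startIdx = integer(), endIdx = integer(),
                      nA = integer(), nB = integer(), genotype = character()))
  }
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be sorted and unique")
  b <- if (is.numeric(call)) as.integer(call) else
    as.integer(match(as.character(call), c("A", "B")) - 1L)
  if (anyNA(b)) stop("allele calls must be 'A' or 'B'")
  if (m < window) {
    hm <- ceiling(homMin / window * m)
    nB <- sum(b); nA <- m - nB
    g <- if (nA >= hm) "AA" else if (nB >= hm) "BB" else "AB"
    return(data.frame(startIdx = 1L, endIdx = m, nA = nA, nB = nB,
                      genotype = g))
  }
  starts <- seq.int(1L, m - window + 1L, by = step)
  cs <- c(0L, cumsum(b))
  nB <- cs[starts + window] - cs[starts]
  nA <- window - nB
  g <- ifelse(nA >= homMin, "AA", ifelse(nB >= homMin, "BB", "AB"))
  data.frame(startIdx = starts, endIdx = starts + window - 1L,
             nA = nA, nB = nB, genotype = g)
}

# run-length segmentation of window calls with optional absorption of
# short dissenting runs (< minRun windows) flanked by identical calls
.windowRuns <- function(g, minRun, smooth) {
  r <- rle(g)
  if (smooth) {
    repeat {
      k <- length(r$lengths)
      if (k < 3L) break
      short <- which(r$lengths[-c(1L, k)] < minRun) + 1L
      short <- short[r$values[short - 1L] == r$values[short + 1L]]
      if (!length(short)) break
      i <- short[1L]
      r$values[i] <- r$values[i - 1L]
      r <- rle(inverse.rle(r))
    }
  }
  r
}

# ML changepoint for the boundary between two blocks: choose the split of
# the SNPs spanning the two boundary windows that maximizes the emission
# likelihood (left SNPs under the left genotype, right under the right).
# Emission model: P(B | AA) = e, P(B | AB) = 1/2, P(B | BB) = 1 - e.
.refineSplit <- function(b, idx, gL, gR, e) {
  e <- min(max(e, 1e-6), 0.49)
  pB <- c(e, 0.5, 1 - e)
  x <- b[idx]
  llL <- ifelse(x == 1L, log(pB[gL + 1L]), log(1 - pB[gL + 1L]))
  llR <- ifelse(x == 1L, log(pB[gR + 1L]), log(1 - pB[gR + 1L]))
  n <- length(idx)
  score <- cumsum(llL)[-n] + rev(cumsum(rev(llR)))[-1L]
  idx[which.max(score)]
}

#' Merge window calls into genotype blocks with inferred breakpoints
#'
#' Maximal runs of identically-called windows become blocks.  By default a
#' short dissenting run (fewer than \code{ceiling(window/step)} windows,
#' i.e. less than one full window of fresh SNPs) flanked by two runs of one
#' identical call is absorbed into that call, since a real genotype segment
#' must span at least one full window; this suppresses error-driven
#' spurious double crossovers (\code{smooth = FALSE} disables it).
#'
#' The breakpoint between two adjacent blocks is localized within the SNPs
#' spanning the two boundary windows.  With \code{refine = TRUE} (default)
#' the split maximizing the per-SNP emission likelihood of the two flanking
#' genotypes is used and the breakpoint is the midpoint of the two SNPs
#' straddling that split; with \code{refine = FALSE} the breakpoint is the
#' midpoint between the last SNP of the left run's final window and the
#' first SNP of the right run's first window.
#'
#' @param windows Window calls from [callWindows()].
#' @param pos,call The observed SNP positions and allele calls the windows
#'   were computed from.
#' @param chromLength Chromosome length in bp; blocks extend to
#'   \code{[1, chromLength]}.
#' @param window,step The window parameters used in [callWindows()].
#' @param smooth Absorb short dissenting runs (default TRUE).
#' @param refine Use likelihood changepoint refinement (default TRUE).
#' @param errorRate Allele error rate assumed by the refinement emission
#'   model.
#' @return A data.frame of blocks: \code{start}, \code{end} (1-based
#'   inclusive, contiguous, tiling the chromosome) and \code{genotype}
#'   ("AA"/"AB"/"BB"); adjacent blocks always differ in genotype, so the
#'   number of inferred breakpoints is \code{nrow - 1}.
#' @export
windowsToBlocks <- function(windows, pos, call, chromLength,
                            window = 18, step = 2,
                            smooth = TRUE, refine = TRUE, errorRate = 0.01) {
  if (nrow(windows) == 0L)
    return(data.frame(start = numeric(), end = numeric(),
                      genotype = character()))
  b <- if (is.numeric(call)) as.integer(call) else
    as.integer(match(as.character(call), c("A", "B")) - 1L)
  minRun <- ceiling(window / step)
  r <- .windowRuns(windows$genotype, minRun, smooth)
  k <- length(r$values)
  if (k == 1L)
    return(data.frame(start = 1, end = chromLength, genotype = r$values))
  ends <- cumsum(r$lengths)
  bp <- numeric(k - 1L)
  for (j in seq_len(k - 1L)) {
    iL <- ends[j]                 # last window of left run
    iR <- iL + 1L                 # first window of right run
    lastL <- windows$endIdx[iL]
    firstR <- windows$startIdx[iR]
    if (refine) {
      lo <- min(windows$startIdx[iL], firstR)
      hi <- max(lastL, windows$endIdx[iR])
      gL <- .genoCode(r$values[j]); gR <- .genoCode(r$values[j + 1L])
      s <- .refineSplit(b, lo:hi, gL, gR, errorRate)
      bp[j] <- round((pos[s] + pos[s + 1L]) / 2)
    } else {
      bp[j] <- round((pos[lastL] + pos[firstR]) / 2)
    }
  }
  bp <- pmin(pmax(bp, 2), chromLength)
  bp <- cummax(bp)  # guard: keep boundaries ordered
  df <- data.frame(start = c(1, bp), end = c(bp - 1, chromLength),
                   genotype = r$values)
  df <- df[df$end >= df$start, , drop = FALSE]
  if (nrow(df) > 1L) {  # re-merge identical neighbours after degenerate drops
    grp <- cumsum(c(TRUE, df$genotype[-1L] != df$genotype[-nrow(df)]))
    grp <- factor(grp, levels = unique(grp))
    df <- data.frame(
      start = as.numeric(vapply(split(df$start, grp), min, numeric(1))),
      end = as.numeric(vapply(split(df$end, grp), max, numeric(1))),
      genotype = vapply(split(df$genotype, grp), `[`, character(1), 1L))
  }
  rownames(df) <- NULL
  df
}

#' Call genotype blocks for a whole population
#'
#' Convenience wrapper running [callWindows()] and [windowsToBlocks()] for
#' every individual and chromosome of a sparse allele-observation table.
#'
#' @param obs Observations with columns \code{individual}, \code{chrom},
#'   \code{pos}, \code{call} (as from [observeAlleles()] or
#'   [readObservations()]).
#' @param genome A [GenomeSpec-class].
#' @inheritParams windowsToBlocks
#' @param homMin Homozygosity cutoff per window.
#' @return A data.frame of blocks with columns \code{individual},
#'   \code{chrom}, \code{start}, \code{end}, \code{genotype}.  Individuals
#'   with no observations on some chromosome get no blocks there (a single
#'   warning reports how many such cases occurred).
#' @export
callBlocks <- function(obs, genome, window = 18, step = 2, homMin = 15,
                       smooth = TRUE, refine = TRUE, errorRate = 0.01) {
  stopifnot(is(genome, "GenomeSpec"),
            all(c("individual", "chrom", "pos", "call") %in% names(obs)))
  len <- chromLengths(genome)
  ids <- unique(obs$individual)
  missing <- 0L
  out <- list()
  byInd <- split(obs, obs$individual)
  for (id in ids) {
    oi <- byInd[[id]]
    byChrom <- split(oi, oi$chrom)
    for (ch in names(len)) {
      oc <- byChrom[[ch]]
      if (is.null(oc) || nrow(oc) == 0L) { missing <- missing + 1L; next }
      o <- order(oc$pos)
      w <- callWindows(oc$pos[o], oc$call[o], window, step, homMin)
      bl <- windowsToBlocks(w, oc$pos[o], oc$call[o], len[[ch]],
                            window, step, smooth, refine, errorRate)
      if (nrow(bl))
        out[[length(out) + 1L]] <-
          cbind(individual = id, chrom = ch, bl, stringsAsFactors = FALSE)
    }
  }
  if (missing > 0L)
    warning(missing, " individual x chromosome combinations had no ",
            "observations; their bins will be NA")
  do.call(rbind, out)
}

#' Genotype of a block tiling at a physical position
#'
#' @param blocks Blocks of a single individual and chromosome (data.frame
#'   with \code{start}, \code{end}, \code{genotype}).
#' @param pos Vector of 1-based positions; each must lie within
#'   \code{[1, max(blocks$end)]}.
#' @return Character genotypes at \code{pos}.  A position equal to a block
#'   boundary (breakpoint) belongs to the right block.
#' @export
genotypeAt <- function(blocks, pos) {
  stopifnot(nrow(blocks) >= 1L)
  if (any(pos < 1 | pos > max(blocks$end)))
    stop("position outside chromosome")
  i <- findInterval(pos, blocks$start)
  blocks$genotype[i]
}
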
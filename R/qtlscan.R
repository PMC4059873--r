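# Single- and multiple-QTL genome scans on bin markers.  The single-QTL
# model is marker regression of the trait on additive and dominance
# codings (equivalent to Haley-Knott regression at fully genotyped
# markers): x_a = +1 (AA), 0 (AB), -1 (BB); x_d = 1 (AB), 0 otherwise.
# LOD = (n/2) log10(RSS0/RSS1).  Genome-wide significance comes from
# phenotype permutations; support intervals use the 1.5-LOD drop rule.

.phenoVector <- function(pheno, trait = NULL, individuals = NULL) {
  if (is.data.frame(pheno)) {
    stopifnot("individual" %in% names(pheno))
    if (is.null(trait)) {
      num <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                     "individual")
      trait <- num[1L]
    }
    y <- setNames(pheno[[trait]], pheno$individual)
  } else {
    y <- pheno
    if (is.null(names(y)) && !is.null(individuals) &&
        length(y) == length(individuals)) names(y) <- individuals
  }
  if (!is.null(individuals)) y <- y[individuals]
  y
}

.genoMatrix <- function(x) {
  if (is(x, "BinMap"))
    list(geno = binGenotypes(x), info = binInfo(x))
  else {
    stopifnot(is.matrix(x))
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("M%d", seq_len(nrow(x)))
    list(geno = x, info = data.frame(bin_id = ids, chrom = NA_character_,
                                     start = NA_real_, end = NA_real_,
                                     width = NA_real_))
  }
}

#' Build a BinMap directly from a genotype matrix
#'
#' Wraps a complete markers-by-individuals genotype matrix (e.g. true
#' genotypes sampled at marker positions in a simulation) into a
#' [BinMap-class], with each marker as one grid-interval bin.
#'
#' @param geno Integer matrix (markers x individuals) of codes 0/1/2/NA.
#' @param bins data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), one row per marker.
#' @param genome A [GenomeSpec-class] (for chromosome lengths).
#' @return A [BinMap-class].
#' @export
makeBinMap <- function(geno, bins, genome) {
  stopifnot(nrow(geno) == nrow(bins), is(genome, "GenomeSpec"))
  len <- chromLengths(genome)
  chroms <- names(len)
  ci <- match(bins$chrom, chroms)
  ord <- order(ci, bins$start)
  bins <- bins[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  ids <- unlist(lapply(split(seq_along(ord), bins$chrom)[unique(bins$chrom)],
                       seq_along), use.names = FALSE)
  bin_id <- sprintf("Bin%d_%d", match(bins$chrom, chroms), ids)
  rr <- GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start, end = bins$end),
    bin_id = bin_id, recombinant = FALSE,
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = len))
  rownames(geno) <- bin_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = geno), rowRanges = rr)
  S4Vectors::metadata(se)$gridUnit <- gridUnit(genome)
  new("BinMap", se)
}

#' Single-QTL genome scan by marker regression
#'
#' At each bin marker the trait is regressed on the additive and dominance
#' codings over individuals with a non-missing genotype there; LOD =
#' (n/2) log10(RSS0/RSS1) against the intercept-only fit on the same
#' individuals.  Markers with fewer than three genotype classes are fitted
#' with the estimable reduced model and flagged.
#'
#' @param x A [BinMap-class] or a markers-by-individuals genotype matrix
#'   of codes 0/1/2/NA.
#' @param pheno Named numeric vector of trait values (names = individual
#'   ids) or a phenotype data.frame with an \code{individual} column.
#' @param trait Column to use when \code{pheno} is a data.frame.
#' @param minN Minimum individuals per marker for a fit (default 10).
#' @return A LOD-profile data.frame: \code{bin_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{LOD}, \code{n}, \code{nClasses}.
#' @export
scanOne <- function(x, pheno, trait = NULL, minN = 10) {
  gm <- .genoMatrix(x)
  y <- .phenoVector(pheno, trait, colnames(gm$geno))
  keep <- !is.na(y)
  if (sum(keep) < minN) stop("fewer than ", minN, " phenotyped individuals")
  y <- y[keep]
  geno <- gm$geno[, keep, drop = FALSE]
  nm <- nrow(geno)
  LOD <- rep(NA_real_, nm); nUsed <- integer(nm); nCl <- integer(nm)
  for (i in seq_len(nm)) {
    g <- geno[i, ]
    ok <- !is.na(g)
    n <- sum(ok)
    nUsed[i] <- n
    if (n < 3L) next
    gi <- g[ok]; yi <- y[ok]
    nCl[i] <- length(unique(gi))
    X <- cbind(1, 1 - gi, as.numeric(gi == 1L))
    fit <- lm.fit(X, yi)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((yi - mean(yi))^2)
    LOD[i] <- max(0, n / 2 * log10(rss0 / max(rss1, rss0 * 1e-12,
                                              .Machine$double.xmin)))
  }
  out <- gm$info
  out$LOD <- LOD; out$n <- nUsed; out$nClasses <- nCl
  out
}

# Fast group-sum engine: genome-wide max LOD of the 3-genotype-class model
# for many phenotype vectors at once.  Algebraically identical to the
# marker regression in scanOne (the additive+dominance design saturates
# the genotype classes); used for permutations and replicate null scans.
.maxLodMatrix <- function(geno, Y) {
  n <- ncol(geno)
  stopifnot(nrow(Y) == n)
  I0 <- (geno == 0L); I1 <- (geno == 1L); I2 <- (geno == 2L)
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  n0 <- rowSums(I0); n1 <- rowSums(I1); n2 <- rowSums(I2)
  nt <- n0 + n1 + n2
  Y2 <- Y * Y
  S0 <- I0 %*% Y; S1 <- I1 %*% Y; S2 <- I2 %*% Y
  Q0 <- I0 %*% Y2; Q1 <- I1 %*% Y2; Q2 <- I2 %*% Y2
  div <- function(S, ng) { out <- S^2 / ng; out[ng == 0, ] <- 0; out }
  rss1 <- (Q0 + Q1 + Q2) - div(S0, n0) - div(S1, n1) - div(S2, n2)
  St <- S0 + S1 + S2; Qt <- Q0 + Q1 + Q2
  rss0 <- Qt - St^2 / nt
  lod <- nt / 2 * log10(pmax(rss0, .Machine$double.xmin) /
                          pmax(rss1, rss0 * 1e-12, .Machine$double.xmin))
  lod[lod < 0] <- 0
  apply(lod, 2, max)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype over individuals, recomputes the genome-wide
#' maximum LOD for each permutation, and returns the empirical
#' (1 - alpha) quantile as the order statistic
#' \code{ceiling((1 - alpha) * nPerm)} of the sorted maxima.
#'
#' @inheritParams scanOne
#' @param nPerm Number of permutations (default 1000).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Integer seed (required).
#' @param blockSize Permutations evaluated per matrix block.
#' @return List with \code{threshold}, \code{maxLod} (the nPerm maxima),
#'   \code{nPerm} and \code{alpha}.
#' @export
permutationThreshold <- function(x, pheno, nPerm = 1000, alpha = 0.05, seed,
                                 trait = NULL, blockSize = 250) {
  stopifnot(nPerm >= 100)
  gm <- .genoMatrix(x)
  y <- .phenoVector(pheno, trait, colnames(gm$geno))
  keep <- !is.na(y)
  y <- y[keep]
  geno <- gm$geno[, keep, drop = FALSE]
  n <- length(y)
  .withSeed(seed, {
    maxLod <- numeric(nPerm)
    done <- 0L
    while (done < nPerm) {
      b <- min(blockSize, nPerm - done)
      Y <- vapply(seq_len(b), function(i) y[sample.int(n)], numeric(n))
      maxLod[done + seq_len(b)] <- .maxLodMatrix(geno, Y)
      done <- done + b
    }
    ord <- sort(maxLod)
    list(threshold = ord[ceiling((1 - alpha) * nPerm)], maxLod = maxLod,
         nPerm = nPerm, alpha = alpha)
  })
}

#' 1.5-LOD support interval around a scan peak
#'
#' The maximal contiguous run of markers on the peak's chromosome that
#' contains the peak and keeps LOD >= peak - drop.  The peak is the
#' genome-wide maximum (leftmost on ties, which are flagged).
#'
#' @param profile LOD profile from [scanOne()].
#' @param drop LOD drop defining the interval (default 1.5).
#' @param map Optional genetic map from [buildGeneticMap()] to report cM
#'   bounds.
#' @return List with \code{chrom}, \code{peakBin}, \code{peakLOD},
#'   \code{bins} (bin_ids in the interval), \code{startBp}, \code{endBp}
#'   (physical bounds of the terminal bins), \code{startCM}, \code{endCM},
#'   \code{peakCM} (NA without a map) and \code{tied} (TRUE if the maximum
#'   was not unique).
#' @export
supportInterval <- function(profile, drop = 1.5, map = NULL) {
  lod <- profile$LOD
  stopifnot(any(is.finite(lod)))
  pk <- which(lod == max(lod, na.rm = TRUE))
  tied <- length(pk) > 1L
  pk <- pk[1L]
  onChr <- which(profile$chrom %in% profile$chrom[pk])
  rel <- match(pk, onChr)
  ok <- !is.na(lod[onChr]) & lod[onChr] >= lod[pk] - drop
  lo <- rel; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- rel; while (hi < length(onChr) && ok[hi + 1L]) hi <- hi + 1L
  idx <- onChr[lo:hi]
  cm <- function(i) {
    if (is.null(map)) return(NA_real_)
    m <- match(profile$bin_id[i], map$bin_id)
    if (is.na(m)) NA_real_ else map$cM[m]
  }
  list(chrom = profile$chrom[pk], peakBin = profile$bin_id[pk],
       peakLOD = lod[pk], bins = profile$bin_id[idx],
       startBp = profile$start[idx[1L]], endBp = profile$end[idx[length(idx)]],
       startCM = cm(idx[1L]), endCM = cm(idx[length(idx)]), peakCM = cm(pk),
       tied = tied)
}

#' Additive and dominance effects and variance explained at a marker
#'
#' With genotype class means \eqn{\mu_{AA}, \mu_{AB}, \mu_{BB}}:
#' a = (mu_AA - mu_BB)/2 (positive when the first-parent allele increases
#' the trait), d = mu_AB - (mu_AA + mu_BB)/2, and R2 (%) is
#' 100 (1 - RSS1/RSS0) from the marker fit.  A missing genotype class
#' makes the effects needing it NA.
#'
#' @param y Trait values.
#' @param g Genotype codes (0/1/2/NA) of the same individuals.
#' @return List with \code{a}, \code{d}, \code{r2}, \code{means},
#'   \code{n}.
#' @export
estimateEffects <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  if (length(unique(g)) < 2L) stop("fewer than 2 genotype classes present")
  mu <- vapply(0:2, function(k) if (any(g == k)) mean(y[g == k]) else NA_real_,
               numeric(1))
  a <- (mu[1L] - mu[3L]) / 2
  d <- mu[2L] - (mu[1L] + mu[3L]) / 2
  fitted <- mu[g + 1L]
  rss1 <- sum((y - fitted)^2)
  rss0 <- sum((y - mean(y))^2)
  list(a = a, d = d, r2 = 100 * (1 - rss1 / rss0),
       means = setNames(mu, .GENO_LEVELS), n = length(y))
}

# covariate-adjusted LOD profile: full model adds (xa, xd) of the scanned
# marker to the covariate columns; both models drop individuals with any
# missing value involved
.scanWithCovariates <- function(geno, y, C) {
  nm <- nrow(geno)
  lod <- rep(NA_real_, nm)
  baseOk <- !is.na(y) & stats::complete.cases(C)
  for (i in seq_len(nm)) {
    ok <- baseOk & !is.na(geno[i, ])
    n <- sum(ok)
    if (n < 5L) next
    gi <- geno[i, ok]
    X0 <- cbind(1, C[ok, , drop = FALSE])
    X1 <- cbind(X0, 1 - gi, as.numeric(gi == 1L))
    r0 <- sum(lm.fit(X0, y[ok])$residuals^2)
    r1 <- sum(lm.fit(X1, y[ok])$residuals^2)
    lod[i] <- max(0, n / 2 * log10(r0 / max(r1, r0 * 1e-12,
                                            .Machine$double.xmin)))
  }
  lod
}

#' Forward-selection multiple-QTL scan
#'
#' Approximates multiple-QTL mapping by forward cofactor selection: take
#' the genome-wide peak if its LOD reaches \code{threshold}, add its
#' additive and dominance codings as covariates, rescan, and repeat until
#' no marker passes or \code{maxQtl} QTL are accepted.  Each accepted QTL
#' is then re-profiled with the other QTL as cofactors to obtain its
#' conditional LOD and support interval; effects come from the joint
#' final model, and each QTL's R2 (%) is the drop in explained sum of
#' squares when it is removed from the joint model, relative to the total
#' sum of squares.
#'
#' A minimum-separation guard keeps the forward search from accepting
#' markers tightly linked to an already-accepted QTL: after conditioning,
#' sporadic genotype miscalls at neighbouring bins can leave formally
#' significant residual signal that is not a separate locus.  Candidate
#' peaks closer than \code{minSeparationCM} (genetic, when a map is given)
#' or \code{minSeparationBp} (physical, otherwise) to an accepted QTL on
#' the same chromosome are excluded.
#'
#' @inheritParams scanOne
#' @param threshold LOD acceptance threshold (> 0), e.g. from
#'   [permutationThreshold()].
#' @param maxQtl Maximum number of QTL (default 10).
#' @param drop LOD drop for support intervals.
#' @param map Optional genetic map for cM positions.
#' @param minSeparationCM Minimum genetic distance between accepted QTL on
#'   one chromosome (default 15 cM; used when \code{map} is supplied).
#' @param minSeparationBp Minimum physical distance between accepted QTL
#'   on one chromosome (default 10 Mb; used without a map).
#' @return A data.frame with one row per accepted QTL: \code{bin_id},
#'   \code{chrom}, \code{pos_bp} (bin midpoint), \code{pos_cM},
#'   \code{interval_start_bp}, \code{interval_end_bp},
#'   \code{interval_start_cM}, \code{interval_end_cM}, \code{LOD}
#'   (conditional on the other QTL), \code{additive}, \code{dominance},
#'   \code{r2_pct}.  Zero rows when nothing passes the threshold.
#' @export
scanMulti <- function(x, pheno, threshold, maxQtl = 10, trait = NULL,
                      drop = 1.5, map = NULL, minSeparationCM = 15,
                      minSeparationBp = 1e7) {
  stopifnot(threshold > 0)
  gm <- .genoMatrix(x)
  y <- .phenoVector(pheno, trait, colnames(gm$geno))
  keep <- !is.na(y)
  y <- y[keep]
  geno <- gm$geno[, keep, drop = FALSE]
  n <- length(y)
  emptyRes <- data.frame(bin_id = character(), chrom = character(),
                         pos_bp = numeric(), pos_cM = numeric(),
                         interval_start_bp = numeric(),
                         interval_end_bp = numeric(),
                         interval_start_cM = numeric(),
                         interval_end_cM = numeric(), LOD = numeric(),
                         additive = numeric(), dominance = numeric(),
                         r2_pct = numeric())
  info <- gm$info
  markerCM <- if (!is.null(map)) map$cM[match(info$bin_id, map$bin_id)]
  markerMid <- (info$start + info$end) / 2
  nearAccepted <- function(i, accepted) {
    same <- !is.na(info$chrom[i]) & info$chrom[accepted] %in% info$chrom[i]
    if (!any(same)) return(FALSE)
    acc <- accepted[same]
    if (!is.null(markerCM) && !is.na(markerCM[i]) &&
        all(!is.na(markerCM[acc])))
      any(abs(markerCM[acc] - markerCM[i]) < minSeparationCM)
    else
      any(abs(markerMid[acc] - markerMid[i]) < minSeparationBp)
  }
  qtl <- integer(0)
  C <- matrix(numeric(0), nrow = n, ncol = 0)
  repeat {
    lod <- .scanWithCovariates(geno, y, C)
    if (length(qtl))
      lod[vapply(seq_along(lod), nearAccepted, logical(1),
                 accepted = qtl)] <- NA_real_
    if (all(is.na(lod)) || max(lod, na.rm = TRUE) < threshold ||
        length(qtl) >= maxQtl) break
    pk <- which.max(lod)
    qtl <- c(qtl, pk)
    gk <- geno[pk, ]
    C <- cbind(C, 1 - gk, as.numeric(gk == 1L))
    if (length(qtl) >= maxQtl) break
  }
  if (!length(qtl)) return(emptyRes)

  # joint final model on individuals complete at all accepted QTL
  ok <- !is.na(y) & colSums(is.na(geno[qtl, , drop = FALSE])) == 0L
  yj <- y[ok]
  Xj <- matrix(1, nrow = sum(ok), ncol = 1 + 2 * length(qtl))
  for (k in seq_along(qtl)) {
    gk <- geno[qtl[k], ok]
    Xj[, 2 * k] <- 1 - gk
    Xj[, 2 * k + 1] <- as.numeric(gk == 1L)
  }
  fitJ <- lm.fit(Xj, yj)
  rssJ <- sum(fitJ$residuals^2)
  tss <- sum((yj - mean(yj))^2)

  rows <- vector("list", length(qtl))
  for (k in seq_along(qtl)) {
    others <- qtl[-k]
    Ck <- if (length(others)) {
      Co <- matrix(0, nrow = n, ncol = 2 * length(others))
      for (m in seq_along(others)) {
        go <- geno[others[m], ]
        Co[, 2 * m - 1] <- 1 - go
        Co[, 2 * m] <- as.numeric(go == 1L)
      }
      Co
    } else matrix(numeric(0), nrow = n, ncol = 0)
    lodK <- .scanWithCovariates(geno, y, Ck)
    prof <- gm$info
    prof$LOD <- lodK
    # interval around this QTL: restrict the peak search to its chromosome
    # neighbourhood by masking other chromosomes' higher peaks
    mask <- prof$chrom %in% prof$chrom[qtl[k]]
    prof2 <- prof[mask, , drop = FALSE]
    prof2$LOD[is.na(prof2$LOD)] <- 0
    # re-centre: force the accepted marker to be the peak row for interval
    pkRow <- match(gm$info$bin_id[qtl[k]], prof2$bin_id)
    si <- {
      p3 <- prof2
      p3$LOD[p3$LOD > p3$LOD[pkRow]] <- p3$LOD[pkRow]  # guard drifted peaks
      supportInterval(p3, drop = drop, map = map)
    }
    rssDrop <- sum(lm.fit(Xj[, -c(2 * k, 2 * k + 1), drop = FALSE],
                          yj)$residuals^2)
    infoK <- gm$info[qtl[k], ]
    rows[[k]] <- data.frame(
      bin_id = infoK$bin_id, chrom = infoK$chrom,
      pos_bp = (infoK$start + infoK$end) / 2, pos_cM = si$peakCM,
      interval_start_bp = si$startBp, interval_end_bp = si$endBp,
      interval_start_cM = si$startCM, interval_end_cM = si$endCM,
      LOD = lodK[qtl[k]],
      additive = fitJ$coefficients[2 * k],
      dominance = fitJ$coefficients[2 * k + 1],
      r2_pct = 100 * (rssDrop - rssJ) / tss,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
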
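# Genetic map construction: recombination fractions between adjacent bin
# markers are estimated by two-point maximum likelihood for an F2
# intercross (EM over the ambiguous double-heterozygote class) and
# converted to map distances with Haldane's map function.

#' Haldane map function and its inverse
#'
#' \code{haldaneCM} converts a recombination fraction r to map distance
#' d = -50 ln(1 - 2r) cM, assuming crossovers without interference;
#' \code{haldaneR} inverts it, r = (1 - exp(-d/50))/2.
#'
#' @param r Recombination fraction(s) in \code{[0, 0.5]}; r = 0.5 maps to
#'   \code{maxCM}.
#' @param d Map distance(s) in cM, >= 0.
#' @param maxCM Distance returned for r = 0.5 (default \code{Inf}).
#' @return Map distance in cM, or recombination fraction.
#' @examples
#' haldaneCM(0.25)            # 34.657 cM
#' haldaneR(haldaneCM(0.1))   # 0.1
#' @export
haldaneCM <- function(r, maxCM = Inf) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE))
    stop("recombination fraction must be in [0, 0.5]")
  d <- -50 * log1p(-2 * r)
  d[!is.na(r) & r == 0.5] <- maxCM
  d
}

#' @rdname haldaneCM
#' @export
haldaneR <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be >= 0")
  (1 - exp(-d / 50)) / 2
}

# Joint F2 genotype class probabilities at two coupling-phase markers with
# recombinant-gamete probability r.  3x3 matrix indexed by code+1 of
# (marker1, marker2); codes count B alleles.
.f2JointProbs <- function(r) {
  q <- 1 - r
  matrix(c(q^2, 2 * q * r, r^2,
           2 * q * r, 2 * (q^2 + r^2), 2 * q * r,
           r^2, 2 * q * r, q^2) / 4,
         nrow = 3, byrow = TRUE)
}

# multinomial log-likelihood of a 3x3 joint genotype count table at r
.rfLoglik <- function(counts, r) {
  p <- .f2JointProbs(r)
  sum(counts[counts > 0] * log(p[counts > 0]))
}

#' Two-point recombination fraction between F2 markers (EM)
#'
#' Maximum-likelihood estimate of the recombination fraction r between two
#' coupling-phase codominant markers in an F2 intercross.  Joint genotype
#' class probabilities derive from two independent gametes, each
#' recombinant with probability r; the double-heterozygote class is a
#' mixture of the 0- and 2-recombinant-gamete configurations with weights
#' \eqn{(1-r)^2} and \eqn{r^2} (normalized).  The E-step assigns each class
#' its expected number of recombinant gametes; the M-step sets r to
#' expected recombinant gametes over 2n; iteration stops at |dr| < tol.
#'
#' @param g1,g2 Integer genotype codes (0/1/2, NA allowed) of the two
#'   markers across the same individuals; only pairwise-complete
#'   individuals are used.
#' @param tol Convergence tolerance on r (default 1e-8).
#' @param maxit Maximum EM iterations.
#' @param rMax Upper clamp for the estimate, just below 0.5 (default
#'   0.4999) so Haldane distances stay finite.
#' @return List with \code{rf} (the estimate, clamped to
#'   \code{[0, rMax]}), \code{se} (from the observed information, NA at the
#'   boundary), \code{n} (pairs used) and \code{iterations}.  A warning is
#'   issued when the estimate is driven to the clamp (repulsion-phase or
#'   unlinked-beyond-free columns).
#' @export
estimateRF <- function(g1, g2, tol = 1e-8, maxit = 1000, rMax = 0.4999) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) stop("fewer than 2 pairwise-complete individuals")
  counts <- matrix(tabulate(3L * g1[ok] + g2[ok] + 1L, nbins = 9L),
                   nrow = 3, byrow = TRUE)
  n <- sum(counts)
  # fixed recombinant-gamete counts per class; double het handled in E-step
  recFixed <- matrix(c(0, 1, 2, 1, NA, 1, 2, 1, 0), nrow = 3, byrow = TRUE)
  r <- 0.25
  it <- 0L
  repeat {
    it <- it + 1L
    q <- 1 - r
    eHet <- 2 * r^2 / (q^2 + r^2)    # E[recombinant gametes | double het]
    rec <- recFixed; rec[2, 2] <- eHet
    rNew <- sum(rec * counts) / (2 * n)
    rNew <- min(max(rNew, 0), 0.5)
    if (abs(rNew - r) < tol || it >= maxit) { r <- rNew; break }
    r <- rNew
  }
  clamped <- r > rMax
  if (clamped) {
    warning("recombination fraction at upper clamp (", rMax,
            "); markers look unlinked or in repulsion")
    r <- rMax
  }
  se <- NA_real_
  if (r > 1e-6 && !clamped) {
    h <- 1e-5
    d2 <- (.rfLoglik(counts, min(r + h, 0.49999)) - 2 * .rfLoglik(counts, r) +
             .rfLoglik(counts, r - h)) / h^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }
  list(rf = r, se = se, n = n, iterations = it)
}

#' Build the genetic map from a bin map
#'
#' Estimates the recombination fraction between each pair of physically
#' adjacent bin markers with [estimateRF()] and accumulates Haldane
#' distances within chromosomes, the first marker of each chromosome at
#' 0 cM.  Physical marker order is taken as given.
#'
#' @param binmap A (filtered) [BinMap-class].
#' @param rMax Upper clamp on adjacent-pair r before the Haldane transform.
#' @return A data.frame with one row per bin marker: \code{bin_id},
#'   \code{chrom}, \code{cM} (cumulative within chromosome) and
#'   \code{adjacent_r} (r to the previous marker; NA for the first marker
#'   of a chromosome), with attribute \code{"totalCM"} (sum of chromosome
#'   lengths in cM).  Chromosomes with a single marker get a 0-length map
#'   with a warning.
#' @export
buildGeneticMap <- function(binmap, rMax = 0.4999) {
  stopifnot(is(binmap, "BinMap"))
  g <- binGenotypes(binmap)
  info <- binInfo(binmap)
  out <- list()
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    nb <- length(idx)
    if (nb < 2L)
      warning("chromosome ", ch, " has fewer than 2 markers; 0-length map")
    rf <- rep(NA_real_, nb)
    if (nb >= 2L)
      for (j in 2:nb) {
        est <- suppressWarnings(
          estimateRF(g[idx[j - 1L], ], g[idx[j], ], rMax = rMax))
        rf[j] <- est$rf
      }
    gaps <- ifelse(is.na(rf), 0, haldaneCM(pmin(rf, rMax)))
    out[[ch]] <- data.frame(bin_id = info$bin_id[idx], chrom = ch,
                            cM = cumsum(gaps), adjacent_r = rf,
                            stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  attr(map, "totalCM") <- sum(vapply(out, function(x) max(x$cM), numeric(1)))
  map
}

#' Total genetic length of a map
#'
#' @param map A map from [buildGeneticMap()].
#' @return Total length in cM (sum over chromosomes of the last marker's
#'   position).
#' @export
totalMapLength <- function(map) {
  if (!is.null(attr(map, "totalCM"))) return(attr(map, "totalCM"))
  sum(vapply(split(map$cM, map$chrom), max, numeric(1)))
}
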
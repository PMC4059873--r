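# Synthetic F2 populations with the statistical structure of ultra-low-
# coverage genotyping-by-sequencing: a dense parental SNP catalogue, meiosis
# without crossover interference (Poisson crossovers, consistent with the
# Haldane map function used downstream), sparse single-read allele
# observation, and phenotypes with additive/dominance QTL.  Ground truth
# (segments, crossovers) is retained for recovery tests.

.checkSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an explicit integer 'seed' is required for stochastic operations")
  as.integer(seed)
}

.withSeed <- function(seed, expr) {
  seed <- .checkSeed(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate a parental SNP catalogue
#'
#' Draws SNP positions uniformly along each chromosome at a given expected
#' density, then sorts and deduplicates them.  Every catalogue position is
#' implicitly biallelic with an A allele (first parent, Chang7-2-type) and a
#' B allele (second parent, 787-type).
#'
#' @param genome A [GenomeSpec-class].
#' @param density Expected SNPs per bp (default 1/1770, i.e. ~1 SNP per
#'   1.77 kb as between two diverged maize inbreds).
#' @param seed Integer seed (required).
#' @return A data.frame with columns \code{chrom} and \code{pos}
#'   (1-based, sorted, unique within chromosome).
#' @examples
#' snps <- makeParentalSNPs(deskGenome(2, 1e6), density = 1/1770, seed = 1)
#' head(snps)
#' @export
makeParentalSNPs <- function(genome, density = 1 / 1770, seed) {
  stopifnot(is(genome, "GenomeSpec"), density > 0)
  len <- chromLengths(genome)
  if (any(density * len > len))  # more expected SNPs than integer positions
    stop("SNP density too high: positions cannot be unique")
  if (density > 0.5)
    stop("SNP density too high: positions cannot be unique")
  .withSeed(seed, {
    out <- lapply(names(len), function(ch) {
      n <- rpois(1L, density * len[[ch]])
      if (n > len[[ch]]) stop("SNP density too high: positions cannot be unique")
      pos <- sort(unique(ceiling(runif(n) * len[[ch]])))
      if (length(pos)) data.frame(chrom = ch, pos = pos) else NULL
    })
    do.call(rbind, out)
  })
}

# One gamete of an F1 meiosis on one chromosome: crossover count is
# Poisson(length in Morgans), positions uniform; parent-of-origin of the
# leftmost segment is a fair coin.  Returned as the breakpoint vector plus
# the starting parent (0 = A, 1 = B).
.simGamete <- function(len, morgans) {
  k <- rpois(1L, morgans)
  bp <- if (k > 0) sort(runif(k, min = 1, max = len)) else numeric(0)
  list(bp = bp, start = rbinom(1L, 1L, 0.5))
}

# parent-of-origin (0/1) of a gamete at physical positions
.gameteAt <- function(g, pos) {
  (g$start + findInterval(pos, g$bp)) %% 2L
}

#' Simulate true F2 genomes
#'
#' Each F2 individual is formed from two independent F1 gametes.  Per
#' gamete and chromosome, the crossover count is Poisson with mean equal to
#' the chromosome length in Morgans and crossover positions are uniform
#' (no interference, matching the Haldane map function used for map
#' construction).  The full segment structure and all crossover positions
#' are retained as ground truth.
#'
#' @param genome A [GenomeSpec-class].
#' @param mapLengthPerBp Morgans per bp (e.g. 6.8e-9 for ~0.68 cM/Mb).
#' @param n Number of F2 individuals.
#' @param seed Integer seed (required).
#' @return An object of class \code{"F2Truth"}: a list with elements
#'   \code{genome}, \code{mapLengthPerBp} and \code{individuals} (a named
#'   list, one entry per individual, each a per-chromosome list of the two
#'   gametes).  Use [trueGenotypeAt()] and [trueCrossovers()] to query it.
#' @examples
#' truth <- simulateF2(deskGenome(1, 1e6), 1e-8, n = 5, seed = 1)
#' trueGenotypeAt(truth, "F2_0001", "chr1", c(1, 5e5))
#' @export
simulateF2 <- function(genome, mapLengthPerBp, n, seed) {
  stopifnot(is(genome, "GenomeSpec"), n >= 1, mapLengthPerBp >= 0)
  len <- chromLengths(genome)
  ids <- sprintf("F2_%04d", seq_len(n))
  .withSeed(seed, {
    inds <- lapply(ids, function(id) {
      lapply(len, function(L) {
        list(g1 = .simGamete(L, L * mapLengthPerBp),
             g2 = .simGamete(L, L * mapLengthPerBp))
      })
    })
    names(inds) <- ids
    structure(list(genome = genome, mapLengthPerBp = mapLengthPerBp,
                   individuals = inds),
              class = "F2Truth")
  })
}

#' @export
print.F2Truth <- function(x, ...) {
  cat("F2Truth:", length(x$individuals), "individuals,",
      length(chromLengths(x$genome)), "chromosomes,",
      sprintf("total map %.1f cM\n",
              100 * sum(chromLengths(x$genome)) * x$mapLengthPerBp))
  invisible(x)
}

#' True genotype of a simulated individual at physical positions
#'
#' @param truth An \code{"F2Truth"} object from [simulateF2()].
#' @param individual Individual id (e.g. "F2_0001").
#' @param chrom Chromosome name.
#' @param pos Vector of 1-based positions.
#' @return Integer vector of genotype codes: 0 = AA, 1 = AB, 2 = BB
#'   (number of B alleles).
#' @export
trueGenotypeAt <- function(truth, individual, chrom, pos) {
  stopifnot(inherits(truth, "F2Truth"))
  ind <- truth$individuals[[individual]]
  if (is.null(ind)) stop("unknown individual: ", individual)
  chr <- ind[[chrom]]
  if (is.null(chr)) stop("unknown chromosome: ", chrom)
  L <- chromLengths(truth$genome)[[chrom]]
  if (any(pos < 1 | pos > L)) stop("position outside chromosome")
  as.integer(.gameteAt(chr$g1, pos) + .gameteAt(chr$g2, pos))
}

#' True crossover positions of a simulated population
#'
#' @param truth An \code{"F2Truth"} object.
#' @return A data.frame with columns \code{individual}, \code{chrom},
#'   \code{gamete} (1 or 2) and \code{pos} (bp).
#' @export
trueCrossovers <- function(truth) {
  stopifnot(inherits(truth, "F2Truth"))
  rows <- list()
  for (id in names(truth$individuals)) {
    ind <- truth$individuals[[id]]
    for (ch in names(ind)) {
      for (g in 1:2) {
        bp <- ind[[ch]][[g]]$bp
        if (length(bp))
          rows[[length(rows) + 1L]] <-
            data.frame(individual = id, chrom = ch, gamete = g, pos = bp)
      }
    }
  }
  if (!length(rows))
    return(data.frame(individual = character(), chrom = character(),
                      gamete = integer(), pos = numeric()))
  do.call(rbind, rows)
}

#' True genotype-block boundaries of one individual
#'
#' Positions (bp) on each chromosome where the diplotype of a simulated
#' individual changes, i.e. the union of both gametes' crossover positions.
#' These are the events that breakpoint inference tries to localize.
#'
#' @param truth An \code{"F2Truth"} object.
#' @param individual Individual id.
#' @return Named list (per chromosome) of sorted breakpoint positions.
#' @export
trueBreakpoints <- function(truth, individual) {
  ind <- truth$individuals[[individual]]
  if (is.null(ind)) stop("unknown individual: ", individual)
  lapply(ind, function(chr) sort(c(chr$g1$bp, chr$g2$bp)))
}

#' Observe alleles under the low-coverage single-read model
#'
#' Each catalogue SNP is observed independently with probability
#' \code{siteObsRate}.  At an observed homozygous site the parental allele
#' is emitted; at an observed heterozygous site a single read is modelled,
#' emitting A or B with probability 1/2 each.  The emitted allele is then
#' flipped with probability \code{errorRate}.
#'
#' @param truth An \code{"F2Truth"} object from [simulateF2()].
#' @param snps SNP catalogue from [makeParentalSNPs()].
#' @param siteObsRate Per-site observation probability.  The default
#'   1770/130300 thins a 1 SNP/1.77 kb catalogue to the study-like
#'   per-individual density of ~1 observed SNP per 130.3 kb (~0.04x
#'   coverage).
#' @param errorRate Allele error probability (default 0.01).
#' @param seed Integer seed (required).
#' @return A data.frame of sparse allele observations with columns
#'   \code{individual}, \code{chrom}, \code{pos}, \code{call} ("A" or "B").
#' @export
observeAlleles <- function(truth, snps, siteObsRate = 1770 / 130300,
                           errorRate = 0.01, seed) {
  stopifnot(inherits(truth, "F2Truth"),
            siteObsRate >= 0, siteObsRate <= 1,
            errorRate >= 0, errorRate <= 1)
  posByChrom <- split(snps$pos, snps$chrom)
  .withSeed(seed, {
    out <- vector("list", length(truth$individuals) * length(posByChrom))
    k <- 0L
    for (id in names(truth$individuals)) {
      for (ch in names(posByChrom)) {
        p <- posByChrom[[ch]]
        obs <- p[runif(length(p)) < siteObsRate]
        if (!length(obs)) next
        g <- trueGenotypeAt(truth, id, ch, obs)
        allele <- integer(length(obs))          # 0 = A, 1 = B
        allele[g == 2L] <- 1L
        het <- g == 1L
        if (any(het)) allele[het] <- rbinom(sum(het), 1L, 0.5)
        if (errorRate > 0) {
          flip <- runif(length(obs)) < errorRate
          allele[flip] <- 1L - allele[flip]
        }
        k <- k + 1L
        out[[k]] <- data.frame(individual = id, chrom = ch, pos = obs,
                               call = c("A", "B")[allele + 1L])
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
}

#' Specification of simulated QTL
#'
#' @param loci A data.frame with columns \code{chrom}, \code{pos} (bp),
#'   \code{a} (additive effect, trait units: half the difference between
#'   homozygote means, positive when the A/first-parent allele increases
#'   the trait) and \code{d} (dominance effect: heterozygote deviation from
#'   the homozygote midpoint).  May have zero rows.
#' @param sigma Residual standard deviation (>= 0).
#' @param binaryLocus Optional list \code{list(chrom=, pos=, dominant=)}
#'   describing a monogenic binary trait; \code{dominant} is "A" or "B",
#'   the parent carrying the dominant allele.
#' @return A \code{"QTLSimSpec"} list.
#' @export
qtlSimSpec <- function(loci = NULL, sigma = 1, binaryLocus = NULL) {
  if (is.null(loci))
    loci <- data.frame(chrom = character(), pos = numeric(),
                       a = numeric(), d = numeric())
  stopifnot(all(c("chrom", "pos", "a", "d") %in% names(loci)), sigma >= 0)
  if (!is.null(binaryLocus))
    stopifnot(all(c("chrom", "pos", "dominant") %in% names(binaryLocus)),
              binaryLocus$dominant %in% c("A", "B"))
  structure(list(loci = loci, sigma = sigma, binaryLocus = binaryLocus),
            class = "QTLSimSpec")
}

#' Simulate phenotypes on a true F2 population
#'
#' The quantitative trait is the sum over QTL of \eqn{a x_a + d x_d} plus
#' Gaussian noise, with \eqn{x_a = +1} (AA), 0 (AB), \eqn{-1} (BB) and
#' \eqn{x_d = 1} (AB), 0 otherwise.  The optional binary trait is 1 iff the
#' individual carries at least one dominant allele at the binary locus
#' (expected 3:1 segregation in an F2).
#'
#' @param truth An \code{"F2Truth"} object.
#' @param spec A [qtlSimSpec()] object.
#' @param seed Integer seed (required).
#' @param traitName Column name for the quantitative trait.
#' @return A data.frame with columns \code{individual}, the quantitative
#'   trait, and (if a binary locus is specified) \code{binary}.
#' @export
simulatePhenotypes <- function(truth, spec, seed, traitName = "trait") {
  stopifnot(inherits(truth, "F2Truth"), inherits(spec, "QTLSimSpec"))
  ids <- names(truth$individuals)
  n <- length(ids)
  len <- chromLengths(truth$genome)
  if (nrow(spec$loci))
    stopifnot(all(spec$loci$chrom %in% names(len)),
              all(spec$loci$pos >= 1 & spec$loci$pos <= len[spec$loci$chrom]))
  .withSeed(seed, {
    y <- rnorm(n, 0, spec$sigma)
    if (nrow(spec$loci)) {
      for (j in seq_len(nrow(spec$loci))) {
        g <- vapply(ids, function(id)
          trueGenotypeAt(truth, id, spec$loci$chrom[j], spec$loci$pos[j]),
          integer(1))
        xa <- 1 - g
        xd <- as.numeric(g == 1L)
        y <- y + spec$loci$a[j] * xa + spec$loci$d[j] * xd
      }
    }
    out <- data.frame(individual = ids, stringsAsFactors = FALSE)
    out[[traitName]] <- y
    if (!is.null(spec$binaryLocus)) {
      bl <- spec$binaryLocus
      g <- vapply(ids, function(id)
        trueGenotypeAt(truth, id, bl$chrom, bl$pos), integer(1))
      out$binary <- if (bl$dominant == "A") as.integer(g < 2L)
                    else as.integer(g > 0L)
    }
    rownames(out) <- NULL
    out
  })
}
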
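#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowRanges
#' @importFrom stats pchisq rbinom rnorm rpois runif setNames lm.fit quantile
#'   median complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

# Internal genotype coding used throughout: integer number of B (second
# parent) alleles -- 0 = AA, 1 = AB, 2 = BB, NA = missing.  "A" labels the
# first (Chang7-2-type) parent, "B" the second (787-type) parent.
.GENO_LEVELS <- c("AA", "AB", "BB")

.genoCode <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(as.character(x), .GENO_LEVELS) - 1L
  m
}

.genoLabel <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  out[ok] <- .GENO_LEVELS[code[ok] + 1L]
  out
}

#' Genome specification for an F2 mapping experiment
#'
#' Holds the ordered chromosome lengths (bp) that define the physical
#' coordinate frame of the analysis, together with the grid unit used for
#' bin construction.  The genome is user-configurable; [deskGenome()]
#' returns the default desk-scale genome of 10 chromosomes of 20 Mb.
#'
#' @slot chromLengths Named numeric vector of chromosome lengths in bp,
#'   in chromosome order.
#' @slot gridUnit Width in bp of the grid interval used when building bins
#'   (default 100,000).
#'
#' @seealso [genomeSpec()], [deskGenome()], [buildBinMap()]
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(chromLengths = "numeric", gridUnit = "numeric"))

setValidity("GenomeSpec", function(object) {
  len <- object@chromLengths
  msg <- character()
  if (length(len) == 0L) msg <- c(msg, "at least one chromosome is required")
  if (is.null(names(len)) || anyNA(names(len)) || any(names(len) == ""))
    msg <- c(msg, "chromosomes must be named")
  if (anyDuplicated(names(len))) msg <- c(msg, "chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0))
    msg <- c(msg, "chromosome lengths must be positive and finite")
  if (length(object@gridUnit) != 1L || !is.finite(object@gridUnit) ||
      object@gridUnit <= 0)
    msg <- c(msg, "gridUnit must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param gridUnit Grid interval width in bp used for bin construction.
#' @return A [GenomeSpec-class] object.
#' @examples
#' genomeSpec(c(chr1 = 2e6, chr2 = 1.5e6))
#' @export
genomeSpec <- function(chromLengths, gridUnit = 1e5) {
  new("GenomeSpec", chromLengths = chromLengths, gridUnit = gridUnit)
}

#' Default desk-scale genome
#'
#' Ten chromosomes of 20 Mb each, a scaled-down stand-in for a maize-sized
#' genome that keeps simulation studies fast while preserving the
#' per-base-pair statistical structure (SNP density, observation rate,
#' recombination rate) of the full-scale setting.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Length of each chromosome in bp.
#' @param gridUnit Grid interval width in bp.
#' @return A [GenomeSpec-class] object with chromosomes named "chr1"...
#' @export
deskGenome <- function(nChrom = 10, chromLength = 2e7, gridUnit = 1e5) {
  genomeSpec(setNames(rep(chromLength, nChrom), paste0("chr", seq_len(nChrom))),
             gridUnit = gridUnit)
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", length(object@chromLengths), "chromosomes, total",
      sprintf("%.1f Mb", sum(object@chromLengths) / 1e6),
      "| grid unit", object@gridUnit, "bp\n")
})

#' Chromosome lengths of a GenomeSpec
#' @param x A [GenomeSpec-class].
#' @return Named numeric vector of lengths in bp.
#' @export
chromLengths <- function(x) {
  stopifnot(is(x, "GenomeSpec"))
  x@chromLengths
}

#' Grid unit of a GenomeSpec or BinMap
#' @param x A [GenomeSpec-class] or [BinMap-class].
#' @return Grid interval width in bp.
#' @export
gridUnit <- function(x) {
  if (is(x, "GenomeSpec")) return(x@gridUnit)
  if (is(x, "BinMap")) return(S4Vectors::metadata(x)$gridUnit)
  stop("gridUnit() expects a GenomeSpec or BinMap")
}

#' Recombination bin map of an F2 population
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are recombination
#' bins (maximal genomic intervals within which no recombination event was
#' detected in the whole population, on a fixed grid) and whose columns are
#' F2 individuals.  The single assay \code{"genotype"} holds integer codes
#' 0 (AA, homozygous first parent), 1 (AB, heterozygous), 2 (BB, homozygous
#' second parent) or NA.  Row ranges carry \code{bin_id} identifiers of the
#' form \code{Bin<chrom index>_<ordinal>}.
#'
#' Create with [buildBinMap()]; access the genotype matrix with
#' [binGenotypes()] and bin coordinates with [binInfo()].
#'
#' @seealso [buildBinMap()], [filterMarkers()], [countCrossovers()],
#'   [buildGeneticMap()], [scanOne()]
#' @exportClass BinMap
setClass("BinMap", contains = "RangedSummarizedExperiment")

setValidity("BinMap", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- SummarizedExperiment::assay(object, "genotype")
    if (!all(g[!is.na(g)] %in% 0:2))
      msg <- c(msg, "genotype codes must be 0 (AA), 1 (AB), 2 (BB) or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (!"bin_id" %in% names(S4Vectors::mcols(rr)))
    msg <- c(msg, "rowRanges must carry a 'bin_id' column")
  if (is.null(S4Vectors::metadata(object)$gridUnit))
    msg <- c(msg, "metadata must record the gridUnit")
  if (length(msg)) msg else TRUE
})

#' Genotype matrix of a BinMap
#'
#' @param x A [BinMap-class].
#' @param labels If \code{TRUE}, return character codes "AA"/"AB"/"BB"
#'   instead of the integer coding 0/1/2 (number of second-parent alleles).
#' @return A bins-by-individuals matrix.
#' @export
binGenotypes <- function(x, labels = FALSE) {
  stopifnot(is(x, "BinMap"))
  g <- SummarizedExperiment::assay(x, "genotype")
  if (labels) {
    lab <- matrix(.genoLabel(g), nrow = nrow(g), dimnames = dimnames(g))
    return(lab)
  }
  g
}

#' Bin coordinates of a BinMap
#'
#' @param x A [BinMap-class].
#' @return A data.frame with columns \code{bin_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive bp) and \code{width}.
#' @export
binInfo <- function(x) {
  stopifnot(is(x, "BinMap"))
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    bin_id = S4Vectors::mcols(rr)$bin_id,
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    start = BiocGenerics::start(rr),
    end = BiocGenerics::end(rr),
    width = BiocGenerics::width(rr),
    stringsAsFactors = FALSE)
}

setMethod("show", "BinMap", function(object) {
  g <- SummarizedExperiment::assay(object, "genotype")
  cat("BinMap:", nrow(object), "bins x", ncol(object), "individuals\n")
  cat("  chromosomes:",
      length(unique(as.character(GenomeInfoDb::seqnames(
        SummarizedExperiment::rowRanges(object))))),
      "| grid unit:", S4Vectors::metadata(object)$gridUnit, "bp",
      "| missing genotypes:",
      sprintf("%.2f%%", 100 * mean(is.na(g))), "\n")
})
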
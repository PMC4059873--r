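# Tabular interfaces and the end-to-end pipeline.  All emitted tables are
# TSV with a single '#'-prefixed header comment stating the coordinate
# convention (1-based inclusive bp); re-reading any emitted table
# reproduces the in-memory object.

.writeTSV <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read sparse allele observations
#'
#' Reads a long-format TSV with header columns \code{individual_id},
#' \code{chrom}, \code{pos} (1-based), \code{call} ("A"/"B").  Malformed
#' calls or positions raise an error naming the offending line; positions
#' absent from the SNP catalogue (when given) are excluded with a message
#' reporting the count.
#'
#' @param path TSV file path.
#' @param snps Optional SNP catalogue from [makeParentalSNPs()] used to
#'   reject out-of-catalogue positions.
#' @return A data.frame with columns \code{individual}, \code{chrom},
#'   \code{pos}, \code{call}, sorted by individual, chromosome, position.
#' @export
readObservations <- function(path, snps = NULL) {
  df <- .readTSV(path)
  if (nrow(df) == 0L) stop("empty observation file: ", path)
  need <- c("individual_id", "chrom", "pos", "call")
  if (!all(need %in% names(df)))
    stop("observation file must have columns: ", paste(need, collapse = ", "))
  # line numbers in the file: header + optional comment line offset
  nComment <- sum(startsWith(readLines(path, n = 25L), "#"))
  lineOf <- function(i) i + 1L + nComment
  bad <- which(!df$call %in% c("A", "B"))
  if (length(bad))
    stop("invalid allele call '", df$call[bad[1L]], "' at line ",
         lineOf(bad[1L]))
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(!is.finite(pos) | pos < 1 | pos != round(pos))
  if (length(bad))
    stop("invalid position '", df$pos[bad[1L]], "' at line ", lineOf(bad[1L]))
  out <- data.frame(individual = as.character(df$individual_id),
                    chrom = as.character(df$chrom), pos = pos,
                    call = df$call, stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    key <- paste(out$chrom, out$pos)
    inCat <- key %in% paste(snps$chrom, snps$pos)
    if (any(!inCat))
      message(sum(!inCat), " observations at positions absent from the SNP ",
              "catalogue were excluded")
    out <- out[inCat, , drop = FALSE]
    if (nrow(out) == 0L) stop("no in-catalogue observations remain")
  }
  out <- out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
  dup <- duplicated(out[c("individual", "chrom", "pos")])
  if (any(dup)) {
    warning(sum(dup), " duplicate individual x position observations dropped")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write sparse allele observations
#' @param obs Observations (columns \code{individual}, \code{chrom},
#'   \code{pos}, \code{call}).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeObservations <- function(obs, path) {
  df <- data.frame(individual_id = obs$individual, chrom = obs$chrom,
                   pos = obs$pos, call = obs$call)
  .writeTSV(df, path, "positions 1-based")
}

#' Write / read genotype blocks
#' @param blocks Blocks from [callBlocks()].
#' @param path TSV path.
#' @return \code{writeBlocks}: the path, invisibly; \code{readBlocks}: the
#'   blocks data.frame.
#' @export
writeBlocks <- function(blocks, path) {
  df <- data.frame(individual_id = blocks$individual, chrom = blocks$chrom,
                   start = blocks$start, end = blocks$end,
                   genotype = blocks$genotype)
  .writeTSV(df, path, "start/end 1-based inclusive bp")
}

#' @rdname writeBlocks
#' @export
readBlocks <- function(path) {
  df <- .readTSV(path)
  data.frame(individual = as.character(df$individual_id),
             chrom = as.character(df$chrom), start = as.numeric(df$start),
             end = as.numeric(df$end), genotype = df$genotype,
             stringsAsFactors = FALSE)
}

#' Write / read a bin-map genotype matrix
#'
#' Rows are bins (\code{bin_id}, \code{chrom}, \code{start}, \code{end},
#' 1-based inclusive), remaining columns one per individual with codes
#' AA/AB/BB/NA.  The grid unit and chromosome lengths are recorded in the
#' header comment so that reading reproduces the [BinMap-class].
#'
#' @param binmap A [BinMap-class].
#' @param path TSV path.
#' @return \code{writeBinMap}: the path, invisibly; \code{readBinMap}: a
#'   [BinMap-class].
#' @export
writeBinMap <- function(binmap, path) {
  info <- binInfo(binmap)
  geno <- binGenotypes(binmap, labels = TRUE)
  rr <- SummarizedExperiment::rowRanges(binmap)
  sl <- GenomeInfoDb::seqlengths(rr)
  hdr <- paste0("coordinates 1-based inclusive bp; grid_unit=",
                gridUnit(binmap), "; chrom_lengths=",
                paste(names(sl), sl, sep = ":", collapse = ","))
  df <- cbind(info[c("bin_id", "chrom", "start", "end")],
              as.data.frame(geno, stringsAsFactors = FALSE))
  .writeTSV(df, path, hdr)
}

#' @rdname writeBinMap
#' @export
readBinMap <- function(path) {
  hdr <- readLines(path, n = 1L)
  gu <- as.numeric(sub(".*grid_unit=([0-9.e+]+).*", "\\1", hdr))
  clStr <- sub(".*chrom_lengths=([^;]+).*", "\\1", hdr)
  parts <- strsplit(strsplit(clStr, ",")[[1L]], ":")
  len <- setNames(as.numeric(vapply(parts, `[`, character(1), 2L)),
                  vapply(parts, `[`, character(1), 1L))
  df <- .readTSV(path)
  meta <- c("bin_id", "chrom", "start", "end")
  geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  geno <- matrix(.genoCode(geno), nrow = nrow(geno), dimnames = dimnames(geno))
  rr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    bin_id = df$bin_id, recombinant = NA,
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(len), seqlengths = len))
  rownames(geno) <- df$bin_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = geno), rowRanges = rr)
  S4Vectors::metadata(se)$gridUnit <- gu
  new("BinMap", se)
}

#' Write a genetic map / segregation report / QTL table
#' @param map,report,qtl Objects from [buildGeneticMap()],
#'   [filterMarkers()], [scanMulti()].
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
  .writeTSV(map, path, "cM cumulative within chromosome")
}

#' @rdname writeGeneticMap
#' @export
writeSegregationReport <- function(report, path) {
  .writeTSV(report, path, "chi-squared vs 1:2:1, 2 df; start/end 1-based")
}

#' @rdname writeGeneticMap
#' @export
writeQTLTable <- function(qtl, path) {
  .writeTSV(qtl, path, "positions bp/cM; interval = 1.5-LOD support")
}

#' Pipeline configuration
#'
#' Assembles the parameter set of the end-to-end run with the study-like
#' defaults: SNP density 1/1770 bp, per-site observation rate 1770/130300
#' (one observed SNP per ~130.3 kb per individual), 1% allele error,
#' recombination 6.8e-9 Morgan/bp (~0.68 cM/Mb), sliding window 18/2/15,
#' 100-kb grid, distortion cutoff 1e-10, 1000 permutations at alpha 0.05.
#'
#' @param ... Named overrides of any default listed above, plus
#'   \code{nIndividuals}, \code{genome} (a [GenomeSpec-class]), \code{qtl}
#'   (a [qtlSimSpec()]) and \code{seed}.
#' @return A \code{"PipelineConfig"} list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    genome = deskGenome(),
    nIndividuals = 708,
    snpDensity = 1 / 1770,
    siteObsRate = 1770 / 130300,
    errorRate = 0.01,
    mapLengthPerBp = 6.8e-9,
    window = 18, step = 2, homMin = 15,
    smooth = TRUE, refine = TRUE,
    gridUnit = 1e5,
    pCut = 1e-10, monoFreq = 0.01,
    nPerm = 1000, alpha = 0.05,
    maxQtl = 10,
    qtl = qtlSimSpec(
      loci = data.frame(chrom = "chr4", pos = 12e6, a = -2.1, d = -0.2),
      sigma = 5.8,
      binaryLocus = list(chrom = "chr10", pos = 15e6, dominant = "A")),
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config fields: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$nIndividuals >= 1, cfg$snpDensity > 0,
            cfg$siteObsRate >= 0, cfg$siteObsRate <= 1,
            cfg$errorRate >= 0, cfg$errorRate <= 1,
            cfg$window >= cfg$homMin,
            cfg$homMin >= ceiling(cfg$window / 2) + 1,
            cfg$gridUnit > 0, cfg$pCut > 0, cfg$nPerm >= 100,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "PipelineConfig")
}

#' Write / read a pipeline configuration as flat YAML
#'
#' The genome is serialized as named chromosome lengths and the QTL
#' specification as flat lists, so the file is a plain-text key-value
#' record of the run.
#'
#' @param config A \code{"PipelineConfig"}.
#' @param path YAML file path.
#' @return \code{writePipelineConfig}: the path, invisibly;
#'   \code{readPipelineConfig}: a \code{"PipelineConfig"}.
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  x$genome <- list(chromLengths = as.list(chromLengths(config$genome)),
                   gridUnit = gridUnit(config$genome))
  x$qtl <- list(loci = lapply(seq_len(nrow(config$qtl$loci)), function(i)
                  as.list(config$qtl$loci[i, ])),
                sigma = config$qtl$sigma,
                binaryLocus = config$qtl$binaryLocus)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$genome <- genomeSpec(unlist(x$genome$chromLengths),
                         gridUnit = x$genome$gridUnit)
  loci <- if (length(x$qtl$loci))
    do.call(rbind, lapply(x$qtl$loci, as.data.frame)) else NULL
  x$qtl <- qtlSimSpec(loci = loci, sigma = x$qtl$sigma,
                      binaryLocus = x$qtl$binaryLocus)
  do.call(pipelineConfig, x)
}

#' Run the end-to-end pipeline
#'
#' Simulates (or loads) sparse allele observations, calls windows and
#' blocks, builds and filters the bin map, estimates the genetic map, and
#' scans all phenotype columns for QTL with a per-trait permutation
#' threshold.  Every stage's output is written to \code{outDir} as TSV and
#' summary statistics are logged; runs are deterministic given
#' \code{config$seed}.
#'
#' @param config A [pipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param observations Optional observations data.frame (e.g. from
#'   [readObservations()]); when given, the simulation stage is skipped
#'   and \code{phenotypes} must be supplied too.
#' @param phenotypes Optional phenotype data.frame with an
#'   \code{individual} column.
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with the in-memory stage results:
#'   \code{observations}, \code{blocks}, \code{binmap} (filtered),
#'   \code{report}, \code{map}, \code{thresholds}, \code{qtl}, and
#'   \code{summary}.
#' @export
runPipeline <- function(config, outDir, observations = NULL,
                        phenotypes = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "[%H:%M:%S] "), ...)
    writeLines(msg, logCon)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  say("parameters: n=", config$nIndividuals,
      " snpDensity=", signif(config$snpDensity, 4),
      " siteObsRate=", signif(config$siteObsRate, 4),
      " errorRate=", config$errorRate,
      " mapLengthPerBp=", config$mapLengthPerBp,
      " window=", config$window, "/", config$step, "/", config$homMin,
      " gridUnit=", config$gridUnit, " pCut=", config$pCut,
      " nPerm=", config$nPerm, " alpha=", config$alpha,
      " seed=", config$seed)
  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  seed <- as.integer(config$seed)

  truth <- NULL
  if (is.null(observations)) {
    snps <- stage("simulate-snps",
      makeParentalSNPs(config$genome, config$snpDensity, seed = seed))
    .writeTSV(data.frame(chrom = snps$chrom, pos = snps$pos,
                         allele_A_base = "A", allele_B_base = "B"),
              file.path(outDir, "parental_snps.tsv"), "positions 1-based")
    truth <- stage("simulate-f2",
      simulateF2(config$genome, config$mapLengthPerBp,
                 config$nIndividuals, seed = seed + 1L))
    .writeTSV(trueCrossovers(truth), file.path(outDir, "true_crossovers.tsv"),
              "ground truth; positions bp")
    observations <- stage("observe-alleles",
      observeAlleles(truth, snps, config$siteObsRate, config$errorRate,
                     seed = seed + 2L))
    phenotypes <- stage("simulate-phenotypes",
      simulatePhenotypes(truth, config$qtl, seed = seed + 3L))
    writeObservations(observations, file.path(outDir, "observations.tsv"))
    .writeTSV(phenotypes, file.path(outDir, "phenotypes.tsv"))
  } else if (is.null(phenotypes)) {
    stop("phenotypes must be supplied with externally provided observations")
  }
  say(nrow(observations), " allele observations, ",
      length(unique(observations$individual)), " individuals")

  blocks <- stage("call-blocks",
    callBlocks(observations, config$genome, config$window, config$step,
               config$homMin, config$smooth, config$refine, config$errorRate))
  writeBlocks(blocks, file.path(outDir, "blocks.tsv"))

  binmap <- stage("build-binmap",
    buildBinMap(blocks, config$genome, config$gridUnit))
  filt <- stage("filter-markers",
    filterMarkers(binmap, config$pCut, config$monoFreq))
  writeSegregationReport(filt$report, file.path(outDir, "segregation.tsv"))
  writeBinMap(filt$binmap, file.path(outDir, "binmap.tsv"))
  bs <- binSummary(filt$binmap)
  xo <- countCrossovers(filt$binmap)
  say("bins: ", nrow(binmap), " built, ", nrow(filt$binmap), " kept; ",
      "mean length ", round(bs$meanKb, 1), " kb, median ",
      round(bs$medianKb, 1), " kb, ", round(100 * bs$fracBelow0.5Mb, 1),
      "% < 0.5 Mb")
  say("crossovers per individual: mean ", round(mean(xo), 2), ", median ",
      median(xo), ", range ", min(xo), "-", max(xo))

  map <- stage("genetic-map", buildGeneticMap(filt$binmap))
  writeGeneticMap(map, file.path(outDir, "genetic_map.tsv"))
  say("genetic map: ", round(totalMapLength(map), 1), " cM total")

  traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric,
                                             logical(1))], "individual")
  thresholds <- list()
  qtlRows <- list()
  for (tr in traits) {
    prof <- stage(paste0("scan-", tr),
      scanOne(filt$binmap, phenotypes, trait = tr))
    .writeTSV(prof, file.path(outDir, paste0("lod_", tr, ".tsv")),
              "marker-regression LOD, additive+dominance, 2 df")
    th <- stage(paste0("permutations-", tr),
      permutationThreshold(filt$binmap, phenotypes, nPerm = config$nPerm,
                           alpha = config$alpha, seed = seed + 4L,
                           trait = tr))
    thresholds[[tr]] <- th$threshold
    say("trait ", tr, ": max LOD ", round(max(prof$LOD, na.rm = TRUE), 2),
        ", permutation threshold ", round(th$threshold, 2))
    res <- stage(paste0("qtl-", tr),
      scanMulti(filt$binmap, phenotypes, threshold = th$threshold,
                maxQtl = config$maxQtl, trait = tr, map = map))
    if (nrow(res)) qtlRows[[tr]] <- cbind(trait = tr, res)
  }
  qtl <- if (length(qtlRows)) do.call(rbind, qtlRows) else
    data.frame(trait = character())
  rownames(qtl) <- NULL
  writeQTLTable(qtl, file.path(outDir, "qtl_table.tsv"))
  say("QTL detected: ", nrow(qtl))

  invisible(list(observations = observations, truth = truth,
                 blocks = blocks, binmapFull = binmap,
                 binmap = filt$binmap, report = filt$report, map = map,
                 thresholds = thresholds, qtl = qtl,
                 summary = list(bins = bs, crossovers = xo,
                                totalCM = totalMapLength(map))))
}
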
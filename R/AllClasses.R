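#' @import methods
#' @import BiocGenerics
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end width strand resize
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny countOverlaps findOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

DNA_BASES <- c("A", "C", "G", "T")

TIMEPOINTS <- c(0, 1, 2, 5, 20)

#' Position weight matrix for a DNA-binding motif
#'
#' A per-position base-probability model of a transcription-factor binding
#' site (here, the calcineurin-dependent response element bound by Crz1),
#' scored as log2-odds against a background base composition.
#'
#' @slot probs numeric matrix, one row per motif position, columns A, C, G, T;
#'   each row sums to 1.
#' @slot background numeric length-4 background base probabilities (A,C,G,T),
#'   summing to 1.
#' @slot pseudocount pseudocount per base used when the matrix was built from
#'   aligned sites (informational; 0 for matrices given directly as
#'   probabilities).
#'
#' @seealso [motifPWM()], [defaultCrz1PWM()], [buildPwm()], [scanRegions()]
#' @export
setClass("MotifPWM",
  representation(
    probs = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("MotifPWM", function(object) {
  p <- object@probs
  msgs <- character()
  if (!is.numeric(p) || ncol(p) != 4L || nrow(p) < 1L)
    msgs <- c(msgs, "probs must be a numeric matrix with 4 columns (A,C,G,T)")
  else {
    if (!identical(colnames(p), DNA_BASES))
      msgs <- c(msgs, "probs columns must be named A, C, G, T")
    if (any(p < 0))
      msgs <- c(msgs, "probs must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      msgs <- c(msgs, "each probs row must sum to 1 (within 1e-6)")
  }
  if (length(object@background) != 4L || any(object@background <= 0) ||
      abs(sum(object@background) - 1) > 1e-6)
    msgs <- c(msgs, "background must be 4 positive probabilities summing to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msgs <- c(msgs, "pseudocount must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MotifPWM
#'
#' @param probs matrix of base probabilities, one row per position. Columns
#'   are taken in A, C, G, T order; column names are set accordingly.
#' @param background background base probabilities (A,C,G,T). Default uniform.
#' @param pseudocount pseudocount recorded with the matrix (see
#'   [buildPwm()]). Default 0.
#' @return a [MotifPWM-class] object.
#' @examples
#' motifPWM(matrix(0.25, nrow = 9, ncol = 4))
#' @export
motifPWM <- function(probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA_BASES
  rownames(probs) <- NULL
  new("MotifPWM", probs = probs, background = as.numeric(background),
      pseudocount = as.numeric(pseudocount))
}

#' @describeIn motifPWM number of positions in the motif
#' @param pwm a [MotifPWM-class]
#' @export
pwmWidth <- function(pwm) nrow(pwm@probs)

#' @describeIn motifPWM the probability matrix (positions x A,C,G,T)
#' @export
pwmProbs <- function(pwm) pwm@probs

#' @describeIn motifPWM the background base probabilities
#' @export
pwmBackground <- function(pwm) pwm@background

setMethod("show", "MotifPWM", function(object) {
  cat(sprintf("MotifPWM of width %d (pseudocount %.3g)\n",
              pwmWidth(object), object@pseudocount))
  cat("consensus:", pwmConsensus(object), "\n")
  print(round(object@probs, 3))
})

#' Per-bin, per-time-point read counts over intergenic regions
#'
#' A \linkS4class{RangedSummarizedExperiment} subclass holding deduplicated
#' read counts over the 50-nt bin grid for the five time points of an
#' alkaline-stress ChIP time course. Rows are bins (ranges carry
#' \code{region_id} and \code{bin_index} metadata columns), columns are time
#' points. Two assays are kept: \code{raw} (deduplicated counts) and
#' \code{norm} (depth-normalized counts, raw times the per-time-point scale
#' factor). The normalization metadata lives in \code{metadata()}:
#' \code{totals} (deduplicated reads per time point), \code{scale_factors}
#' (largest total divided by each total, so the deepest library has factor 1),
#' and \code{genome_average} (mean normalized count per bin, per time point --
#' the enrichment denominator of the peak caller).
#'
#' @seealso [countBins()], [scaleFactors()], [genomeAverage()], [callPeaks()]
#' @export
setClass("BinCounts", contains = "RangedSummarizedExperiment")

setValidity("BinCounts", function(object) {
  msgs <- character()
  if (!all(c("raw", "norm") %in% names(assays(object))))
    msgs <- c(msgs, "assays 'raw' and 'norm' are required")
  md <- metadata(object)
  for (nm in c("totals", "scale_factors", "genome_average"))
    if (is.null(md[[nm]]) || length(md[[nm]]) != ncol(object))
      msgs <- c(msgs, sprintf("metadata '%s' must have one value per time point", nm))
  if (!all(c("region_id", "bin_index") %in% names(mcols(rowRanges(object)))))
    msgs <- c(msgs, "row ranges need region_id and bin_index columns")
  if (length(msgs) == 0) {
    sf <- md$scale_factors
    if (any(sf < 1 - 1e-9) || min(abs(sf - 1)) > 1e-9)
      msgs <- c(msgs, "scale factors must be >= 1 with at least one equal to 1")
    if (any(assay(object, "raw") < 0))
      msgs <- c(msgs, "counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BinCounts per-time-point scale factors (largest total / total)
#' @param x a \code{BinCounts} object
#' @export
scaleFactors <- function(x) metadata(x)$scale_factors

#' @describeIn BinCounts per-time-point mean normalized count per bin
#' @export
genomeAverage <- function(x) metadata(x)$genome_average

#' @describeIn BinCounts per-time-point deduplicated read totals
#' @export
totalReads <- function(x) metadata(x)$totals

#' @describeIn BinCounts normalized count matrix (bins x time points)
#' @export
normCounts <- function(x) assay(x, "norm")

#' @describeIn BinCounts raw deduplicated count matrix (bins x time points)
#' @export
rawCounts <- function(x) assay(x, "raw")

setMethod("show", "BinCounts", function(object) {
  cat(sprintf("BinCounts: %d bins x %d time points (%s min)\n",
              nrow(object), ncol(object),
              paste(colData(object)$timepoint, collapse = ", ")))
  cat(sprintf("  regions: %d, totals: %s\n",
              length(unique(rowRanges(object)$region_id)),
              paste(totalReads(object), collapse = ", ")))
  cat(sprintf("  genome average per bin: %s\n",
              paste(sprintf("%.2f", genomeAverage(object)), collapse = ", ")))
})

#' Configuration of the synthetic ChIP time-course generator
#'
#' Bundles every tunable of the synthetic-data module: a miniature genome of
#' gene/intergenic blocks, planted recruitment peaks of configurable strength
#' and kinetic class, planted CDRE motif instances, chromatin annotation
#' tracks with a configurable early-peak/NFR association, and five read sets
#' (0, 1, 2, 5 and 20 min) of paired 150-nt fragment-end reads.
#'
#' Defaults emulate the study conditions of the alkaline-stress Crz1 time
#' course at desk scale: 300 intergenic regions, 12/18/30 planted
#' strong/moderate/weak peaks, sonication fragments of at most 500 bp
#' (default 100--300 bp), ~150-nt reads, and a background depth giving a mean
#' bin count of about 10. See the methods vignette for the rationale behind
#' each default.
#'
#' @slot seed integer RNG seed; every generator output is deterministic given
#'   the seed.
#' @slot nChrom number of chromosomes.
#' @slot nIntergenic number of intergenic regions (spread over chromosomes).
#' @slot regionLenRange intergenic length range in bp; lengths are drawn as
#'   multiples of the 50-nt bin so bin grids exactly partition regions.
#' @slot geneLenRange flanking-gene length range (bp).
#' @slot spacerLen genic spacer between consecutive gene/region blocks (bp).
#' @slot divergentFraction fraction of regions arranged as divergent promoters.
#' @slot convergentFraction fraction of regions with convergent flanks (no
#'   assignable promoter; never planted).
#' @slot nPlanted named integer vector: planted peaks per strength class
#'   (strong, moderate, weak).
#' @slot foldRanges list of length-2 fold ranges per strength class from which
#'   target folds are drawn (strong > 10, moderate 5--10, weak 2--5).
#' @slot kineticMix named fractions of planted peaks whose recruitment peaks
#'   at 1, 2, 5 or 20 min; must sum to 1. Class counts are assigned by
#'   largest remainder, so the realized mix is exact up to rounding.
#' @slot kineticProfiles 4x4 matrix of enrichment multipliers, rows = kinetic
#'   class (peak at 1, 2, 5, 20 min), columns = time points 1, 2, 5, 20 min;
#'   each row has maximum 1 at its class time and keeps at least 0.6 at 2 or
#'   5 min so every planted profile can pass the kinetic filter.
#' @slot backgroundRate expected background reads per bp per time point.
#' @slot fragmentLenRange sonication fragment length range (bp), max <= 500.
#' @slot readLen read length (nt, default 150); each fragment yields its two
#'   ends as a + and a - strand read.
#' @slot enrichmentSd standard deviation (bp) of enriched fragment centers
#'   around the planted summit.
#' @slot summitTssOffset if not NA, summits are planted in the bin starting
#'   this many bp upstream of the assigned gene's TSS; if NA (default),
#'   summits fall on a random interior bin.
#' @slot nfrEarlyProb,nfrLateProb probability that a planted CDRE lies inside
#'   a nucleosome-free region, for early (peak at 1 or 2 min) and late (5 or
#'   20 min) kinetic classes.
#' @slot markProbs named probabilities of H3K4me3/H3K4ac enrichment at planted
#'   peaks by kinetic class (h3k4me3_early, h3k4me3_late, h3k4ac_early,
#'   h3k4ac_late).
#' @slot backgroundNfrProb probability an unplanted region carries an NFR.
#' @slot backgroundMarkProbs named probabilities (h3k4me3, h3k4ac) that an
#'   unplanted region carries each mark.
#' @slot pwm reference [MotifPWM-class] from which planted CDREs are sampled.
#' @slot cdrePvalue scan p-value cutoff used when rejection-sampling planted
#'   CDREs so that every planted site is recoverable by the matrix scan.
#'
#' @seealso [simConfig()], [buildGenome()], [simulateReads()]
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nChrom = "integer",
    nIntergenic = "integer",
    regionLenRange = "numeric",
    geneLenRange = "numeric",
    spacerLen = "numeric",
    divergentFraction = "numeric",
    convergentFraction = "numeric",
    nPlanted = "integer",
    foldRanges = "list",
    kineticMix = "numeric",
    kineticProfiles = "matrix",
    backgroundRate = "numeric",
    fragmentLenRange = "numeric",
    readLen = "integer",
    enrichmentSd = "numeric",
    summitTssOffset = "numeric",
    nfrEarlyProb = "numeric",
    nfrLateProb = "numeric",
    markProbs = "numeric",
    backgroundNfrProb = "numeric",
    backgroundMarkProbs = "numeric",
    pwm = "MotifPWM",
    cdrePvalue = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (abs(sum(object@kineticMix) - 1) > 1e-9)
    msgs <- c(msgs, "kineticMix must sum to 1")
  if (!identical(names(object@kineticMix), c("1", "2", "5", "20")))
    msgs <- c(msgs, "kineticMix must be named '1','2','5','20'")
  if (max(object@fragmentLenRange) > 500)
    msgs <- c(msgs, "fragment lengths must be <= 500 bp")
  if (object@fragmentLenRange[1] < object@readLen / 3)
    msgs <- c(msgs, "fragments much shorter than a read are not supported")
  if (!identical(names(object@nPlanted), c("strong", "moderate", "weak")))
    msgs <- c(msgs, "nPlanted must be named strong, moderate, weak")
  if (!identical(sort(names(object@foldRanges)), sort(c("strong", "moderate", "weak"))))
    msgs <- c(msgs, "foldRanges must cover strong, moderate, weak")
  if (!identical(dim(object@kineticProfiles), c(4L, 4L)))
    msgs <- c(msgs, "kineticProfiles must be a 4x4 matrix (class x time)")
  else if (any(abs(diag(object@kineticProfiles) - 1) > 1e-9))
    msgs <- c(msgs, "each kinetic class must have multiplier 1 at its own time")
  if (object@divergentFraction + object@convergentFraction > 1)
    msgs <- c(msgs, "divergent + convergent fractions exceed 1")
  if (sum(object@nPlanted) > object@nIntergenic)
    msgs <- c(msgs, "more planted peaks than intergenic regions")
  if (any(object@regionLenRange %% 50 != 0))
    msgs <- c(msgs, "regionLenRange must be multiples of the 50-nt bin")
  if (object@regionLenRange[1] < 600)
    msgs <- c(msgs, "regions shorter than 600 bp leave no room for summits")
  if (length(msgs)) msgs else TRUE
})

#' Create a synthetic-data configuration
#'
#' All arguments default to the study conditions described in
#' \linkS4class{SimConfig}; pass overrides by name.
#'
#' @param seed integer seed.
#' @param nChrom,nIntergenic,regionLenRange,geneLenRange,spacerLen genome
#'   layout; see \linkS4class{SimConfig}.
#' @param divergentFraction,convergentFraction promoter orientation mix.
#' @param nPlanted named counts of planted peaks per strength class.
#' @param foldRanges list of target-fold ranges per strength class.
#' @param kineticMix fractions of planted peaks peaking at 1/2/5/20 min.
#' @param kineticProfiles class-by-time enrichment multiplier matrix.
#' @param backgroundRate expected background reads per bp per time point.
#' @param fragmentLenRange,readLen,enrichmentSd read geometry.
#' @param summitTssOffset fixed summit placement upstream of the TSS (bp), or
#'   NA for random interior summits.
#' @param nfrEarlyProb,nfrLateProb,markProbs,backgroundNfrProb,backgroundMarkProbs
#'   chromatin-track planting probabilities.
#' @param pwm reference [MotifPWM-class] for planted CDREs.
#' @param cdrePvalue scan p-value cutoff planted sites must beat.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nIntergenic = 50,
#'                  nPlanted = c(strong = 2, moderate = 3, weak = 5))
#' @export
simConfig <- function(seed = 1L,
                      nChrom = 2L,
                      nIntergenic = 300L,
                      regionLenRange = c(1000, 1600),
                      geneLenRange = c(400, 900),
                      spacerLen = 200,
                      divergentFraction = 0.3,
                      convergentFraction = 0.05,
                      nPlanted = c(strong = 12L, moderate = 18L, weak = 30L),
                      foldRanges = list(strong = c(12, 20),
                                        moderate = c(6, 9),
                                        weak = c(3, 4.5)),
                      kineticMix = c("1" = 0.30, "2" = 0.30, "5" = 0.25, "20" = 0.15),
                      kineticProfiles = defaultKineticProfiles(),
                      backgroundRate = 0.05,
                      fragmentLenRange = c(100, 300),
                      readLen = 150L,
                      enrichmentSd = 60,
                      summitTssOffset = NA_real_,
                      nfrEarlyProb = 0.70,
                      nfrLateProb = 0.40,
                      markProbs = c(h3k4me3_early = 0.84, h3k4me3_late = 0.78,
                                    h3k4ac_early = 0.82, h3k4ac_late = 0.64),
                      backgroundNfrProb = 0.5,
                      backgroundMarkProbs = c(h3k4me3 = 0.87, h3k4ac = 0.72),
                      pwm = defaultCrz1PWM(),
                      cdrePvalue = 1e-3) {
  new("SimConfig",
      seed = as.integer(seed), nChrom = as.integer(nChrom),
      nIntergenic = as.integer(nIntergenic),
      regionLenRange = regionLenRange, geneLenRange = geneLenRange,
      spacerLen = spacerLen,
      divergentFraction = divergentFraction,
      convergentFraction = convergentFraction,
      nPlanted = stats::setNames(as.integer(nPlanted), names(nPlanted)),
      foldRanges = foldRanges,
      kineticMix = kineticMix, kineticProfiles = kineticProfiles,
      backgroundRate = backgroundRate,
      fragmentLenRange = fragmentLenRange, readLen = as.integer(readLen),
      enrichmentSd = enrichmentSd, summitTssOffset = summitTssOffset,
      nfrEarlyProb = nfrEarlyProb, nfrLateProb = nfrLateProb,
      markProbs = markProbs, backgroundNfrProb = backgroundNfrProb,
      backgroundMarkProbs = backgroundMarkProbs,
      pwm = pwm, cdrePvalue = cdrePvalue)
}

#' Default kinetic enrichment profiles
#'
#' Piecewise multipliers describing how a planted peak's enrichment rises and
#' falls across 1, 2, 5 and 20 min for each kinetic class (the class is the
#' time of maximum). Rows are classes, columns time points; each row peaks at
#' 1 at its own time and keeps at least a 0.6 multiplier at 2 or 5 min, so a
#' planted profile above twofold at its peak remains compatible with the
#' kinetic filter.
#'
#' @return 4x4 numeric matrix with dimnames class ("1","2","5","20") x time.
#' @export
defaultKineticProfiles <- function() {
  m <- rbind(
    "1"  = c(1.00, 0.70, 0.40, 0.15),
    "2"  = c(0.60, 1.00, 0.70, 0.30),
    "5"  = c(0.30, 0.60, 1.00, 0.50),
    "20" = c(0.15, 0.30, 0.60, 1.00)
  )
  colnames(m) <- c("1", "2", "5", "20")
  m
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  seed %d | %d chrom, %d intergenic regions\n",
              object@seed, object@nChrom, object@nIntergenic))
  cat(sprintf("  planted: %s\n",
              paste(names(object@nPlanted), object@nPlanted,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  kinetic mix (1/2/5/20 min): %s\n",
              paste(object@kineticMix, collapse = "/")))
  cat(sprintf("  background %.3g reads/bp/time, fragments %d-%d bp, reads %d nt\n",
              object@backgroundRate, object@fragmentLenRange[1],
              object@fragmentLenRange[2], object@readLen))
})
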